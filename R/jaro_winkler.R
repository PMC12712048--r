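# Jaro-Winkler string distance.
#
# The record-linkage rule matches fires whose standardized names have a
# Jaro-Winkler distance <= 0.25 with prefix factor 0.1, so this primitive is
# implemented here rather than delegated.  Variant: common-prefix length
# capped at 4 and no boost threshold (the prefix bonus applies regardless of
# the Jaro value), matching the usual default of the stringdist routine used
# in this literature.

jaro_sim <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L && lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  window <- max(0L, floor(max(la, lb) / 2) - 1L)
  bm <- logical(lb)
  am <- logical(la)
  m <- 0L
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] <- TRUE; bm[j] <- TRUE; m <- m + 1L
        break
      }
    }
  }
  if (m == 0L) return(0)
  bj <- which(bm)
  t <- sum(a[which(am)] != b[bj]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' Jaro-Winkler string distance
#'
#' Distance = 1 - (jaro + l * p * (1 - jaro)) where l is the common-prefix
#' length capped at 4 and p the prefix factor.  Two empty strings have
#' distance 0 by convention.  Vectorized over `a`/`b` (recycled).
#'
#' @param a,b character vectors.
#' @param prefix_factor Winkler prefix scaling p, default 0.1.
#' @return numeric vector of distances in \[0, 1\].
#' @examples
#' jw_distance("DIXIE", "PIXIE")    # 0.1333
#' jw_distance("MARTHA", "MARHTA")  # 0.0389
#' @export
jw_distance <- function(a, b, prefix_factor = 0.1) {
  stopifnot(prefix_factor >= 0, prefix_factor <= 0.25)
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (is.na(a[k]) || is.na(b[k])) { out[k] <- NA_real_; next }
    ca <- strsplit(a[k], "", fixed = TRUE)[[1]]
    cb <- strsplit(b[k], "", fixed = TRUE)[[1]]
    jaro <- jaro_sim(ca, cb)
    l <- 0L
    for (i in seq_len(min(4L, length(ca), length(cb)))) {
      if (ca[i] == cb[i]) l <- l + 1L else break
    }
    out[k] <- 1 - (jaro + l * prefix_factor * (1 - jaro))
  }
  out
}
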