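# Shared fixtures and independent oracles.  Everything is generated in code;
# expensive objects are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small, fast world for unit tests (40 km, 2x2 counties, 4 towns)
small_world_config <- function(...) {
  world_config(n_fires = 30, extent_km = 40, n_county_side = 2, n_towns = 4,
               nonfire_rows = 0, pre2000_rows = 0, ...)
}

small_sim <- function() memo("small_sim", function() {
  generate_truth(small_world_config(), seed = 101)
})

small_clean <- function() memo("small_clean", function() {
  sim <- small_sim()
  cfg <- small_world_config()
  gaz <- world_gazetteer(sim$world)
  srcs <- lapply(c("ics209", "redbooks", "fmag"), function(fl)
    render_sources(sim$fires, fl, noise_config(), 101, cfg))
  cleaned <- lapply(srcs, clean_events, gaz = gaz)
  list(records = do.call(rbind, lapply(cleaned, `[[`, "records")),
       rejections = do.call(rbind, lapply(cleaned, `[[`, "rejections")),
       raw_rows = sum(vapply(srcs, nrow, 0L)),
       sim = sim, cfg = cfg, gaz = gaz)
})

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  sij <- comb2(as.vector(tab))
  n2 <- choose(length(a), 2)
  e <- si * sj / n2
  if ((si + sj) / 2 - e == 0) return(1)
  (sij - e) / ((si + sj) / 2 - e)
}

# truth labels for clustered records: complex id if any, else truth id
truth_unit_labels <- function(records, fires) {
  vapply(strsplit(records$truth_id, ";"), function(t) {
    cid <- fires$complex_id[match(t, fires$truth_id)]
    paste(sort(unique(ifelse(is.na(cid), t, cid))), collapse = "+")
  }, character(1))
}

# Independent Jaro-Winkler oracle, written against the textbook definition
# with a deliberately different matching-scan structure than the package's.
jw_oracle <- function(a, b, p = 0.1) {
  A <- utf8ToInt(a); B <- utf8ToInt(b)
  la <- length(A); lb <- length(B)
  if (la == 0 && lb == 0) return(0)
  if (la == 0 || lb == 0) return(1)
  w <- max(floor(max(la, lb) / 2) - 1, 0)
  used <- rep(FALSE, lb)
  ma <- integer(0); mb_pos <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1, i - w); hi <- min(lb, i + w)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used[j] && A[i] == B[j]) {
        used[j] <- TRUE
        ma <- c(ma, A[i]); mb_pos <- c(mb_pos, j)
        break
      }
    }
  }
  m <- length(ma)
  if (m == 0) return(1)
  mb <- B[sort(mb_pos)]
  t <- sum(ma != mb) / 2
  jaro <- mean(c(m / la, m / lb, (m - t) / m))
  l <- 0
  while (l < min(4, la, lb) && A[l + 1] == B[l + 1]) l <- l + 1
  1 - (jaro + l * p * (1 - jaro))
}

# brute-force Mann-Kendall oracle: explicit double loop over all pairs
mk_oracle <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  tie_counts <- as.numeric(table(x))
  tie_counts <- tie_counts[tie_counts > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  list(S = S, tau = S / choose(n, 2), var_S = varS)
}

# a one-row cleaned record for constructing linkage scenarios directly
make_record <- function(source = "ics209", source_id = "X1", name = "ALDER OAK",
                        state = "CA", county = "ALDERWOOD",
                        ignition = as.Date("2010-06-01"),
                        civilian = NA, total = NA, destroyed = NA, damaged = NA,
                        combined = NA, area = 500, declaration = as.Date(NA)) {
  df <- data.frame(source = source, source_id = source_id, raw_name = name,
                   clean_name = name,
                   year = as.integer(format(ignition %||% declaration, "%Y")),
                   stringsAsFactors = FALSE)
  df$ignition_date <- ignition
  df$containment_date <- ignition + 10
  df$fmag_declaration_date <- declaration
  df$states <- list(state)
  df$counties <- list(county)
  df$civilian_fatalities <- as.numeric(civilian)
  df$total_fatalities <- as.numeric(total)
  df$destroyed_structures <- as.numeric(destroyed)
  df$damaged_structures <- as.numeric(damaged)
  df$combined_damaged_destroyed <- as.numeric(combined)
  df$origin_lon <- NA_real_
  df$origin_lat <- NA_real_
  df$area_acres <- area
  df$shared_id <- NA_character_
  df$truth_id <- NA_character_
  df
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
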