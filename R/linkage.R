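# Cross-source record linkage and conflict resolution.
#
# Two records refer to the same wildfire when their county sets overlap,
# their ignition dates are within 30 days, and some pair of their names has
# Jaro-Winkler distance <= 0.25 (prefix factor 0.1).  Clusters are the
# connected components of the pairwise match graph; each cluster resolves to
# one canonical fire under a Redbooks-wins precedence.

#' Matching thresholds
#'
#' @param jw_max maximum Jaro-Winkler distance for names (0.25).
#' @param prefix_factor Winkler prefix factor (0.1).
#' @param date_window_days maximum ignition-date gap in days (30).
#' @param waive_missing_date if TRUE, records with no usable date (after the
#'   declaration-date fallback) can still match on counties + name.
#' @param complex_mode how complex member-fire counts aggregate within a
#'   source: `"sum"` (default) or `"max"`.
#' @return list of class `match_config`.
#' @export
match_config <- function(jw_max = 0.25, prefix_factor = 0.1,
                         date_window_days = 30, waive_missing_date = TRUE,
                         complex_mode = c("sum", "max")) {
  stopifnot(jw_max >= 0, jw_max <= 1, date_window_days >= 0)
  structure(list(jw_max = jw_max, prefix_factor = prefix_factor,
                 date_window_days = date_window_days,
                 waive_missing_date = waive_missing_date,
                 complex_mode = match.arg(complex_mode)),
            class = "match_config")
}

record_names <- function(rec) {
  nm <- rec$clean_name
  if (is.list(nm)) unlist(nm) else nm
}

record_date <- function(rec) {
  # records lacking an ignition date fall back to the declaration date
  d <- rec$ignition_date
  if (length(d) == 0L || is.na(d)) d <- rec$fmag_declaration_date
  d
}

county_pairs <- function(rec) {
  st <- unlist(rec$states); ct <- unlist(rec$counties)
  n <- max(length(st), length(ct))
  if (n == 0L) return(character(0))
  st <- rep_len(st, n); ct <- rep_len(ct, n)
  keep <- !is.na(ct) & ct != UNRESOLVED_COUNTY
  paste(st[keep], ct[keep], sep = ":")
}

#' Decide whether two cleaned records describe the same wildfire
#'
#' @param e1,e2 one-row data.frames from [clean_events()] records.
#' @param cfg a [match_config()].
#' @return list with `match` (logical) and `evidence` (name distance, date
#'   gap in days, shared county tags).
#' @export
pair_match <- function(e1, e2, cfg = match_config()) {
  shared <- intersect(county_pairs(e1), county_pairs(e2))
  county_ok <- length(shared) > 0L

  d1 <- record_date(e1); d2 <- record_date(e2)
  if (length(d1) && length(d2) && !is.na(d1) && !is.na(d2)) {
    gap <- abs(as.numeric(d1 - d2))
    date_ok <- gap <= cfg$date_window_days
  } else {
    gap <- NA_real_
    date_ok <- isTRUE(cfg$waive_missing_date)
  }

  nd <- suppressWarnings(min(outer(record_names(e1), record_names(e2),
                                   jw_distance, prefix_factor = cfg$prefix_factor)))
  name_ok <- is.finite(nd) && nd <= cfg$jw_max

  list(match = county_ok && date_ok && name_ok,
       evidence = list(name_distance = nd, date_gap_days = gap,
                       shared_counties = shared))
}

# vectorized candidate scan used by cluster_events (same rule as pair_match)
match_edges <- function(rec, cfg) {
  n <- nrow(rec)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0),
                                name_distance = numeric(0),
                                date_gap_days = numeric(0)))
  cps <- lapply(seq_len(n), function(i) county_pairs(rec[i, , drop = FALSE]))
  states <- lapply(seq_len(n), function(i) unique(unlist(rec$states[i])))
  dates <- rec$ignition_date
  fb <- rec$fmag_declaration_date
  dates[is.na(dates)] <- fb[is.na(dates)]
  names_l <- lapply(seq_len(n), function(i) record_names(rec[i, , drop = FALSE]))

  out <- list()
  ord <- seq_len(n)
  for (i in ord) {
    for (j in ord[ord > i]) {
      if (!length(intersect(states[[i]], states[[j]]))) next   # state blocking
      shared <- intersect(cps[[i]], cps[[j]])
      if (!length(shared)) next
      if (!is.na(dates[i]) && !is.na(dates[j])) {
        gap <- abs(as.numeric(dates[i] - dates[j]))
        if (gap > cfg$date_window_days) next
      } else {
        if (!isTRUE(cfg$waive_missing_date)) next
        gap <- NA_real_
      }
      nd <- min(outer(names_l[[i]], names_l[[j]], jw_distance,
                      prefix_factor = cfg$prefix_factor))
      if (nd > cfg$jw_max) next
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, name_distance = nd,
                                            date_gap_days = gap)
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      name_distance = numeric(0),
                                      date_gap_days = numeric(0)))
  do.call(rbind, out)
}

#' Cluster records into same-fire groups
#'
#' Clusters are the connected components of the pairwise match graph
#' (transitive merging: A-B and B-C edges put A, B, C in one cluster).
#' Output order is deterministic and invariant to input row order.
#'
#' @param tables one cleaned records data.frame or a list of them.
#' @param cfg a [match_config()].
#' @return list with `records` (combined, with `cluster` ids), `clusters`
#'   (list of integer row indices per cluster) and `edges` (evidence table).
#' @export
cluster_events <- function(tables, cfg = match_config()) {
  rec <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  ord <- order(rec$source, rec$source_id)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  edges <- match_edges(rec, cfg)
  n <- nrow(rec)
  g <- igraph::make_graph(edges = as.vector(t(as.matrix(edges[c("i", "j")]))),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # stable cluster ids: by smallest member row
  first <- tapply(seq_len(n), memb, min)
  relab <- match(memb, memb[sort(first)])
  rec$cluster <- relab
  list(records = rec,
       clusters = split(seq_len(n), relab),
       edges = edges)
}

agg_count <- function(x, mode) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (mode == "sum") sum(x) else max(x)
}

#' Resolve one cluster into a canonical fire
#'
#' Precedence: harm counts and dates from the Redbooks-flavor source win when
#' present; otherwise counts take the maximum across sources and dates the
#' earliest ignition / latest containment.  Within one source, rows with
#' distinct source ids are distinct member fires of a complex and their
#' counts aggregate per `cfg$complex_mode` (default sum).  All names and all
#' state-county combinations are retained.
#'
#' @param members data.frame of the cluster's cleaned records.
#' @param cfg a [match_config()].
#' @return one-row data.frame (list-columns `names`, `states`, `counties`,
#'   `members`).
#' @export
resolve_cluster <- function(members, cfg = match_config()) {
  if (nrow(members) == 0L) stop("empty cluster")
  mode <- cfg$complex_mode
  bysrc <- split(members, members$source)
  src_agg <- lapply(bysrc, function(m) {
    m <- m[!duplicated(m$source_id), , drop = FALSE]   # dedupe members first
    list(civ = agg_count(m$civilian_fatalities, mode),
         tot = agg_count(m$total_fatalities, mode),
         destr = agg_count(m$destroyed_structures, mode),
         dam = agg_count(m$damaged_structures, mode),
         comb = agg_count(m$combined_damaged_destroyed, mode),
         area = agg_count(m$area_acres, mode),
         ign = if (all(is.na(m$ignition_date))) as.Date(NA) else
           min(m$ignition_date, na.rm = TRUE),
         con = if (all(is.na(m$containment_date))) as.Date(NA) else
           max(m$containment_date, na.rm = TRUE))
  })
  pick <- function(field) {
    rb <- src_agg[["redbooks"]]
    if (!is.null(rb) && !is.na(rb[[field]])) return(rb[[field]])
    vals <- vapply(src_agg, function(s) as.numeric(s[[field]]), numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else max(vals)
  }
  rb <- src_agg[["redbooks"]]
  ign_all <- members$ignition_date
  ign <- if (!is.null(rb) && !is.na(rb$ign)) rb$ign else
    if (all(is.na(ign_all))) as.Date(NA) else min(ign_all, na.rm = TRUE)
  con_all <- members$containment_date
  con <- if (!is.null(rb) && !is.na(rb$con)) rb$con else
    if (all(is.na(con_all))) as.Date(NA) else max(con_all, na.rm = TRUE)
  if (!is.na(ign) && !is.na(con) && con < ign) con <- ign

  has_fmag <- any(members$source == "fmag")
  dec <- members$fmag_declaration_date
  dec <- if (all(is.na(dec))) as.Date(NA) else min(dec, na.rm = TRUE)

  ox <- members$origin_lon[!is.na(members$origin_lon)]
  oy <- members$origin_lat[!is.na(members$origin_lat)]

  st_all <- unlist(members$states); ct_all <- unlist(members$counties)
  keep <- !is.na(ct_all)
  combos <- unique(data.frame(state = st_all[keep], county = ct_all[keep],
                              stringsAsFactors = FALSE))

  out <- data.frame(
    civilian_fatalities = pick("civ"),
    total_fatalities = pick("tot"),
    destroyed_structures = pick("destr"),
    damaged_structures = pick("dam"),
    combined_damaged_destroyed = pick("comb"),
    area_acres = pick("area"),
    fmag = has_fmag,
    stringsAsFactors = FALSE)
  out$ignition_date <- ign
  out$containment_date <- con
  out$fmag_declaration_date <- dec
  out$year <- if (!is.na(ign)) as.integer(format(ign, "%Y")) else
    suppressWarnings(min(members$year, na.rm = TRUE))
  if (is.infinite(out$year)) out$year <- NA_integer_
  out$origin_lon <- if (length(ox)) ox[1] else NA_real_
  out$origin_lat <- if (length(oy)) oy[1] else NA_real_
  out$shared_id <- {
    sid <- members$shared_id[!is.na(members$shared_id)]
    if (length(sid)) sid[1] else NA_character_
  }
  out$names <- list(sort(unique(record_names(members))))
  out$states <- list(unique(st_all[!is.na(st_all)]))
  out$counties <- list(combos$county)
  out$county_states <- list(combos$state)
  out$members <- list(members[c("source", "source_id")])
  out$truth_id <- {
    tid <- unique(unlist(strsplit(members$truth_id[!is.na(members$truth_id)], ";")))
    if (length(tid)) paste(sort(tid), collapse = ";") else NA_character_
  }
  out
}

#' Resolve every cluster into the canonical-fire table
#'
#' @param clustered output of [cluster_events()].
#' @param cfg a [match_config()].
#' @return data.frame of canonical fires with `fire_id`.
#' @export
resolve_all <- function(clustered, cfg = match_config()) {
  rows <- lapply(clustered$clusters, function(ix)
    resolve_cluster(clustered$records[ix, , drop = FALSE], cfg))
  out <- do.call(rbind, rows)
  out$fire_id <- sprintf("WF%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("fire_id", setdiff(names(out), "fire_id"))]
}
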