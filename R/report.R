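# Final dataset output and summary statistics.

#' Percent share, half-up to one decimal
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return 100 * numerator / denominator rounded half-up to one decimal.
#' @examples
#' percent_share(6212, 6871)  # 90.4
#' @export
percent_share <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  floor(x * 10 + 0.5 + 1e-9) / 10
}

#' Mann-Kendall trend test
#'
#' S = sum over pairs i < j of sgn(x_j - x_i); tau = S / (n(n-1)/2); the
#' variance of S carries the standard tie correction and the z statistic a
#' continuity correction.  `method = "exact"` (tie-free series, n <= 10)
#' computes the exact null distribution of S by the inversion-number
#' recursion instead of the normal approximation.
#'
#' @param x numeric series (annual counts), n >= 3.
#' @param method "normal" (default) or "exact".
#' @return list(n, S, var_S, tau, z, p).
#' @export
mann_kendall <- function(x, method = c("normal", "exact")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("mann_kendall needs at least 3 observations")
  S <- 0L
  for (i in seq_len(n - 1L)) {
    S <- S + sum(sign(x[(i + 1L):n] - x[i]))
  }
  ties <- table(x)
  t <- as.numeric(ties[ties > 1])
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  tau <- S / (n * (n - 1) / 2)
  if (method == "exact") {
    if (length(t)) stop("exact method requires a tie-free series")
    if (n > 10L) stop("exact method limited to n <= 10")
    p <- mk_exact_p(S, n)
    z <- NA_real_
  } else {
    z <- if (S == 0 || var_S == 0) 0 else (S - sign(S)) / sqrt(var_S)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(n = n, S = as.integer(S), var_S = var_S, tau = tau, z = z, p = p)
}

# exact two-sided p for tie-free S via the number-of-inversions recursion:
# S = n(n-1)/2 - 2k where k is the inversion count of the rank permutation
mk_exact_p <- function(S, n) {
  counts <- 1            # counts[k+1] = permutations of 1 element with k inversions
  for (m in 2:n) {
    new_len <- length(counts) + m - 1L
    nc <- numeric(new_len)
    for (shift in 0:(m - 1L)) {
      nc[(shift + 1):(shift + length(counts))] <-
        nc[(shift + 1):(shift + length(counts))] + counts
    }
    counts <- nc
  }
  total <- sum(counts)
  npairs <- n * (n - 1) / 2
  svals <- npairs - 2 * (seq_along(counts) - 1L)
  p <- sum(counts[abs(svals) >= abs(S)]) / total
  min(1, p)
}

#' Summary count tables
#'
#' Per-year counts key on the earliest ignition year; multi-state records are
#' counted once per state; criterion counts use the flags.
#'
#' @param records final disaster-record data.frame.
#' @return list(by_year, by_state, by_criterion, by_wui).
#' @export
summarize_counts <- function(records) {
  yr <- records$year
  by_year <- as.data.frame(table(year = yr), stringsAsFactors = FALSE)
  names(by_year) <- c("year", "n")
  by_year$year <- as.integer(by_year$year)

  st <- unlist(lapply(records$states, unique))
  by_state <- as.data.frame(table(state = st), stringsAsFactors = FALSE)
  names(by_state) <- c("state", "n")

  by_criterion <- data.frame(
    criterion = c("fatality", "structure", "fmag"),
    n = c(sum(records$fatality_met, na.rm = TRUE),
          sum(records$structure_met, na.rm = TRUE),
          sum(records$fmag_met, na.rm = TRUE)))

  wc <- records$wui_class
  by_wui <- as.data.frame(table(wui_class = wc[!is.na(wc)]),
                          stringsAsFactors = FALSE)
  names(by_wui) <- c("wui_class", "n")

  list(by_year = by_year, by_state = by_state, by_criterion = by_criterion,
       by_wui = by_wui)
}

DISASTER_FIELDS <- list(
  fire_id = "Unique disaster identifier",
  names = "All cleaned name variants for the incident/complex",
  year = "Earliest ignition year",
  ignition_date = "Earliest resolved ignition date (ISO)",
  containment_date = "Latest resolved containment date (ISO)",
  fmag_declaration_date = "Federal fire-assistance declaration date",
  states = "States touched by the record",
  counties = "Canonical county names (all state-county combinations)",
  origin_lon = "Reported point of origin, longitude",
  origin_lat = "Reported point of origin, latitude",
  area_acres = "Reported burn area, acres",
  area_km2 = "Burn-zone geometry area, km^2",
  civilian_fatalities = "Resolved civilian fatality count",
  total_fatalities = "Resolved total fatality count",
  destroyed_structures = "Resolved destroyed-structure count",
  damaged_structures = "Resolved damaged-structure count",
  combined_damaged_destroyed = "Combined damaged/destroyed (2007-2009 era)",
  fatality_met = "Fatality criterion flag",
  structure_met = "Structure criterion flag",
  fmag_met = "Federal-assistance criterion flag",
  fatality_rule = "Rule that fired for the fatality criterion",
  structure_rule = "Rule that fired for the structure criterion",
  max_density = "Maximum smoothed population density in the buffered zone (people/km^2)",
  mean_density = "Mean smoothed population density in the buffered zone (people/km^2)",
  density_flag = "Max density >= 96 people/km^2",
  wui_class = "WUI overlap of the burn geometry: intermix/interface/both/none",
  community_flag = "Community-proximity criterion (density OR WUI); NA if no geometry",
  epoch_year = "Population-grid epoch used",
  geometry_source = "Where the geometry came from",
  link_method = "Linkage tier that attached the geometry",
  is_disaster = "Meets >= 1 harm criterion AND the community criterion")

geom_to_geojson <- function(geom, frame) {
  if (is.null(geom)) return(NULL)
  if (is.null(dim(geom))) {
    ll <- planar_to_lonlat(geom, frame)
    return(list(type = "Point", coordinates = c(ll[1, 1], ll[1, 2])))
  }
  ll <- planar_to_lonlat(geom, frame)
  ring <- rbind(ll, ll[1, , drop = FALSE])            # close the ring
  list(type = "MultiPolygon",
       coordinates = list(list(lapply(seq_len(nrow(ring)), function(i)
         c(ring[i, 1], ring[i, 2])))))
}

geojson_to_geom <- function(gj, frame) {
  if (is.null(gj) || is.null(gj$type)) return(NULL)
  if (gj$type == "Point") {
    xy <- lonlat_to_planar(c(gj$coordinates[[1]], gj$coordinates[[2]]), frame)
    return(c(x = xy[1, 1], y = xy[1, 2]))
  }
  ring <- gj$coordinates[[1]][[1]]
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  m <- m[-nrow(m), , drop = FALSE]                    # drop closing vertex
  xy <- lonlat_to_planar(m, frame)
  colnames(xy) <- c("x", "y")
  xy
}

#' Write the disaster dataset as GeoJSON plus a data dictionary
#'
#' One feature per record (null geometry for county-only records);
#' coordinates are emitted in lon/lat order.  A machine-written markdown
#' data dictionary is placed next to the GeoJSON.
#'
#' @param records final data.frame (with `geometry` list-column).
#' @param path output GeoJSON path.
#' @param frame planar frame used to convert back to lon/lat.
#' @return invisibly, the GeoJSON path.
#' @export
write_outputs <- function(records, path, frame = burn_frame()) {
  features <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    props <- list()
    for (f in names(DISASTER_FIELDS)) {
      if (!f %in% names(r)) next
      v <- r[[f]]
      if (is.list(v)) v <- v[[1]]
      if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
      if (length(v) == 0L) v <- NULL
      if (length(v) == 1L && is.na(v)) v <- NULL
      props[[f]] <- v
    }
    list(type = "Feature",
         geometry = geom_to_geojson(r$geometry[[1]], frame),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null")
  dict_path <- sub("\\.geojson$", "_data_dictionary.md", path)
  if (dict_path == path) dict_path <- paste0(path, ".dict.md")
  lines <- c("# Data dictionary", "",
             "| field | definition |", "| --- | --- |",
             vapply(names(DISASTER_FIELDS), function(f)
               sprintf("| %s | %s |", f, DISASTER_FIELDS[[f]]), character(1)))
  writeLines(lines, dict_path)
  invisible(path)
}

#' Read a disaster GeoJSON written by [write_outputs()]
#'
#' @param path GeoJSON path.
#' @param frame planar frame.
#' @return data.frame with `geometry` list-column (planar km).
#' @export
read_disasters <- function(path, frame = burn_frame()) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(ft) {
    p <- ft$properties
    listify <- function(x) if (is.null(x)) NA else unlist(x)
    df <- data.frame(fire_id = p$fire_id %||% NA_character_,
                     year = p$year %||% NA_integer_,
                     stringsAsFactors = FALSE)
    for (f in setdiff(names(DISASTER_FIELDS), c("fire_id", "year", "names",
                                                "states", "counties"))) {
      v <- listify(p[[f]])
      df[[f]] <- if (length(v)) v[1] else NA
    }
    df$names <- list(listify(p$names))
    df$states <- list(listify(p$states))
    df$counties <- list(listify(p$counties))
    df$geometry <- list(geojson_to_geom(ft$geometry, frame))
    df
  })
  out <- do.call(rbind, rows)
  for (col in c("ignition_date", "containment_date", "fmag_declaration_date")) {
    out[[col]] <- as.Date(out[[col]])
  }
  out
}
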