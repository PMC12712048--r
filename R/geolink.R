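# Tiered burn-zone geometry assignment.
#
# Tiers, first success wins:
#   1 shared_id        — shared interagency id equality against MTBS-/FIRED-
#                        flavor sets
#   2 mtbs_name        — MTBS-flavor by name (JW <= 0.25) + county within
#                        10 km + ignition within 30 days (+ 10-km origin cap
#                        when both sides have coordinates)
#   2b fired_origin    — FIRED-flavor (no names): origin inside perimeter or
#                        within 1 km, ignition within 30 days
#   3 nifc_name        — NIFC-flavor by name + location + ignition within
#                        [year start - 30 d, year end + 30 d]
#   4 circular_buffer  — planar circle with the reported area at the origin
#   5 point_only       — origin only, no reported area
#   6 county_only      — no feasible origin; geometry none

#' Geometry-linkage thresholds
#' @param jw_max name-distance cap (0.25).
#' @param prefix_factor Winkler prefix factor (0.1).
#' @param date_window_days ignition window, days (30).
#' @param county_dist_km county proximity for "location" matching, km (10).
#' @param origin_dist_km origin-to-perimeter cap in tiers 2-3, km (10).
#' @param fired_origin_km origin tolerance for FIRED-flavor matching, km (1).
#' @return list of class `geolink_config`.
#' @export
geolink_config <- function(jw_max = 0.25, prefix_factor = 0.1,
                           date_window_days = 30, county_dist_km = 10,
                           origin_dist_km = 10, fired_origin_km = 1) {
  structure(as.list(environment()), class = "geolink_config")
}

#' Circle (or point) from a reported origin and burn area
#'
#' @param origin planar c(x, y) in km.
#' @param area_acres reported burn area; `NA` returns the point unchanged.
#' @param n_segments boundary segments for the circle polygon.
#' @return list(geometry, type = "polygon"|"point"); the polygon's planar
#'   area is within 1% of the requested area.
#' @export
circle_from_point <- function(origin, area_acres, n_segments = 256L) {
  if (is.na(area_acres)) {
    return(list(geometry = c(x = origin[1], y = origin[2]), type = "point"))
  }
  if (!is.finite(area_acres) || area_acres <= 0)
    stop("area must be a positive finite number of acres")
  a_km2 <- acres_to_km2(area_acres)
  r <- sqrt(a_km2 / pi)
  list(geometry = circle_polygon(origin[1], origin[2], r, n_segments),
       type = "polygon")
}

# counties (gazetteer rows) within dist_km of a polygon
perimeter_county_tags <- function(poly, counties, dist_km) {
  idx <- counties_touching(poly, counties, pad_km = dist_km)
  paste(counties$state[idx], counties$county[idx], sep = ":")
}

# pre-compute per-perimeter county tags once
prep_perimeters <- function(perims, counties, dist_km) {
  if (is.null(perims) || nrow(perims) == 0L) return(perims)
  perims$county_tags <- lapply(perims$polygon, perimeter_county_tags,
                               counties = counties, dist_km = dist_km)
  perims
}

fire_county_tags <- function(fire) {
  st <- unlist(fire$county_states %||% fire$states)
  ct <- unlist(fire$counties)
  n <- max(length(st), length(ct))
  if (n == 0L) return(character(0))
  st <- rep_len(st, n); ct <- rep_len(ct, n)
  keep <- !is.na(ct) & ct != UNRESOLVED_COUNTY
  paste(st[keep], ct[keep], sep = ":")
}

fire_origin_planar <- function(fire, frame) {
  if (is.na(fire$origin_lon) || is.na(fire$origin_lat)) return(NULL)
  xy <- lonlat_to_planar(c(fire$origin_lon, fire$origin_lat), frame)
  c(xy[1, 1], xy[1, 2])
}

#' Assign burn-zone geometry to one canonical fire
#'
#' @param fire one-row canonical fire (from [resolve_all()] +
#'   [evaluate_criteria()]).
#' @param perimeter_sets named list with elements `mtbs`, `fired`, `nifc`
#'   (data.frames from [render_perimeters()], passed through
#'   `prep_perimeters()` by [assign_geometries()]).
#' @param cfg a [geolink_config()].
#' @param frame the planar [burn_frame()].
#' @return list(geometry, geometry_source, link_method, area_km2,
#'   perimeter_id) — geometry is a polygon matrix, a point, or NULL.
#' @export
assign_geometry <- function(fire, perimeter_sets, cfg = geolink_config(),
                            frame = burn_frame()) {
  origin <- fire_origin_planar(fire, frame)
  tags <- fire_county_tags(fire)
  names_f <- unlist(fire$names)
  ign <- fire$ignition_date

  best_row <- function(perims, ok, nd = NULL, gap = NULL) {
    ix <- which(ok)
    if (!length(ix)) return(NULL)
    o <- order(if (is.null(nd)) rep(0, length(ix)) else nd[ix],
               if (is.null(gap)) rep(0, length(ix)) else gap[ix],
               perims$perimeter_id[ix])
    ix[o[1]]
  }
  result <- function(perims, i, source, method) {
    list(geometry = perims$polygon[[i]], geometry_source = source,
         link_method = method,
         area_km2 = polygon_area(perims$polygon[[i]]),
         perimeter_id = perims$perimeter_id[i])
  }

  # tier 1: shared id
  if (!is.na(fire$shared_id)) {
    for (src in c("mtbs", "fired")) {
      p <- perimeter_sets[[src]]
      if (is.null(p) || !nrow(p) || !"shared_id" %in% names(p)) next
      ok <- !is.na(p$shared_id) & p$shared_id == fire$shared_id
      i <- best_row(p, ok)
      if (!is.null(i)) return(result(p, i, src, "shared_id"))
    }
  }

  # tier 2: mtbs by name + county(10 km) + ignition date (+ origin cap)
  p <- perimeter_sets$mtbs
  if (!is.null(p) && nrow(p)) {
    nd <- vapply(p$name, function(nm)
      min(jw_distance(names_f, nm, prefix_factor = cfg$prefix_factor)),
      numeric(1))
    cty <- vapply(p$county_tags, function(tg) length(intersect(tg, tags)) > 0,
                  logical(1))
    gap <- abs(as.numeric(p$ignition_date - ign))
    ok <- nd <= cfg$jw_max & cty & !is.na(gap) & gap <= cfg$date_window_days
    if (!is.null(origin)) {
      od <- vapply(p$polygon, function(pg)
        dist_points_to_polygon(origin[1], origin[2], pg), numeric(1))
      ok <- ok & od <= cfg$origin_dist_km
    }
    i <- best_row(p, ok, nd, gap)
    if (!is.null(i)) return(result(p, i, "mtbs", "mtbs_name_location_date"))
  }

  # tier 2b: fired by origin + date (no names in this flavor)
  p <- perimeter_sets$fired
  if (!is.null(p) && nrow(p) && !is.null(origin)) {
    od <- vapply(p$polygon, function(pg)
      dist_points_to_polygon(origin[1], origin[2], pg), numeric(1))
    gap <- abs(as.numeric(p$ignition_date - ign))
    ok <- od <= cfg$fired_origin_km & !is.na(gap) & gap <= cfg$date_window_days
    i <- best_row(p, ok, od, gap)
    if (!is.null(i)) return(result(p, i, "fired", "fired_origin_date"))
  }

  # tier 3: nifc by name + location + ignition year +/- 30 days
  p <- perimeter_sets$nifc
  if (!is.null(p) && nrow(p)) {
    nd <- vapply(p$name, function(nm)
      min(jw_distance(names_f, nm, prefix_factor = cfg$prefix_factor)),
      numeric(1))
    cty <- vapply(p$county_tags, function(tg) length(intersect(tg, tags)) > 0,
                  logical(1))
    ystart <- as.Date(sprintf("%d-01-01", p$year))
    yend <- as.Date(sprintf("%d-12-31", p$year))
    yok <- !is.na(ign) & ign >= ystart - cfg$date_window_days &
      ign <= yend + cfg$date_window_days
    ok <- nd <= cfg$jw_max & cty & yok
    if (!is.null(origin)) {
      od <- vapply(p$polygon, function(pg)
        dist_points_to_polygon(origin[1], origin[2], pg), numeric(1))
      ok <- ok & od <= cfg$origin_dist_km
    }
    i <- best_row(p, ok, nd)
    if (!is.null(i)) return(result(p, i, "nifc", "nifc_name_location_year"))
  }

  # tier 4/5: circular buffer or point from origin
  if (!is.null(origin)) {
    circ <- circle_from_point(origin, if (is.na(fire$area_acres)) NA
                              else fire$area_acres)
    if (circ$type == "polygon") {
      return(list(geometry = circ$geometry, geometry_source = "circular_buffer",
                  link_method = "circular_buffer",
                  area_km2 = polygon_area(circ$geometry), perimeter_id = NA_character_))
    }
    return(list(geometry = circ$geometry, geometry_source = "point_only",
                link_method = "point_only", area_km2 = NA_real_,
                perimeter_id = NA_character_))
  }

  # tier 6: county only
  if (length(tags)) {
    return(list(geometry = NULL, geometry_source = "county_only",
                link_method = "county_only", area_km2 = NA_real_,
                perimeter_id = NA_character_))
  }
  list(geometry = NULL, geometry_source = "rejected", link_method = "rejected",
       area_km2 = NA_real_, perimeter_id = NA_character_)
}

#' Assign geometry to every preliminary fire
#'
#' @param fires canonical-fire data.frame.
#' @param perimeter_sets named list of perimeter tables (`mtbs`, `fired`,
#'   `nifc`).
#' @param counties gazetteer county table with polygons (e.g.
#'   `world$counties`).
#' @param cfg a [geolink_config()].
#' @param frame planar frame.
#' @return `fires` with list-column `geometry` and columns `geometry_source`,
#'   `link_method`, `area_km2`, `perimeter_id`.
#' @export
assign_geometries <- function(fires, perimeter_sets, counties,
                              cfg = geolink_config(), frame = burn_frame()) {
  perimeter_sets <- lapply(perimeter_sets, function(p) {
    if (!is.null(p) && nrow(p) && !is.null(p$polygon)) {
      p$polygon <- lapply(p$polygon, repair_ring)
      p <- p[!vapply(p$polygon, is.null, logical(1)), , drop = FALSE]
    }
    prep_perimeters(p, counties, cfg$county_dist_km)
  })
  res <- lapply(seq_len(nrow(fires)), function(i)
    assign_geometry(fires[i, , drop = FALSE], perimeter_sets, cfg, frame))
  fires$geometry <- lapply(res, `[[`, "geometry")
  fires$geometry_source <- vapply(res, `[[`, "", "geometry_source")
  fires$link_method <- vapply(res, `[[`, "", "link_method")
  fires$area_km2 <- vapply(res, `[[`, 0, "area_km2")
  fires$perimeter_id <- vapply(res, `[[`, "", "perimeter_id")
  fires
}

GEOMETRY_PRECEDENCE <- c(shared_id = 1, mtbs_name_location_date = 2,
                         fired_origin_date = 3, nifc_name_location_year = 4,
                         circular_buffer = 5, point_only = 6, county_only = 7,
                         rejected = 8)

#' Merge disjoint linkages
#'
#' Fires linked to the same perimeter are merged into one record: geometry by
#' tier precedence, counts by maximum, earliest ignition, latest containment,
#' FMAG if any member had one.
#'
#' @param fires output of [assign_geometries()].
#' @return merged data.frame.
#' @export
merge_linked_groups <- function(fires) {
  n <- nrow(fires)
  if (n == 0L) return(fires)
  pid <- fires$perimeter_id
  grp <- ifelse(is.na(pid) | pid == "NA" | pid == "", fires$fire_id, pid)
  comps <- split(seq_len(n), grp)
  rows <- lapply(comps, function(ix) {
    if (length(ix) == 1L) return(fires[ix, , drop = FALSE])
    m <- fires[ix, , drop = FALSE]
    best <- ix[order(GEOMETRY_PRECEDENCE[m$link_method])][1]
    out <- fires[best, , drop = FALSE]
    for (col in c("civilian_fatalities", "total_fatalities",
                  "destroyed_structures", "damaged_structures",
                  "combined_damaged_destroyed", "area_acres")) {
      v <- m[[col]]
      out[[col]] <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
    out$ignition_date <- if (all(is.na(m$ignition_date))) as.Date(NA) else
      min(m$ignition_date, na.rm = TRUE)
    out$containment_date <- if (all(is.na(m$containment_date))) as.Date(NA) else
      max(m$containment_date, na.rm = TRUE)
    out$fmag <- any(m$fmag)
    out$fmag_met <- any(m$fmag_met %||% FALSE)
    out$fatality_met <- any(m$fatality_met %||% FALSE)
    out$structure_met <- any(m$structure_met %||% FALSE)
    out$names <- list(sort(unique(unlist(m$names))))
    ct <- unique(data.frame(state = unlist(m$county_states),
                            county = unlist(m$counties),
                            stringsAsFactors = FALSE))
    out$counties <- list(ct$county)
    out$county_states <- list(ct$state)
    out$states <- list(unique(unlist(m$states)))
    out$members <- list(do.call(rbind, m$members))
    tid <- unique(unlist(strsplit(m$truth_id[!is.na(m$truth_id)], ";")))
    out$truth_id <- if (length(tid)) paste(sort(tid), collapse = ";") else NA_character_
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fire_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
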