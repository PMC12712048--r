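# Community-proximity criterion: smoothed population density within
# size-dependent buffers plus WUI overlap of the raw burn geometry.

#' Community-proximity thresholds
#'
#' @param density_threshold people/km^2 marking a community (96, i.e. 250
#'   people per square mile truncated).
#' @param smoothing_radius_km focal-mean radius for the density layer (0.3 km).
#' @param small_buffer_km buffer for small fires and points (10 km).
#' @param large_buffer_km buffer for large fires (20 km).
#' @param size_threshold_acres small/large cutoff (1,000 acres; >= is large).
#' @param cell_km grid cell edge (0.1 km).
#' @param epoch_interval population-grid epoch spacing, years (5).
#' @return list of class `community_config`.
#' @export
community_config <- function(density_threshold = 96, smoothing_radius_km = 0.3,
                             small_buffer_km = 10, large_buffer_km = 20,
                             size_threshold_acres = 1000, cell_km = 0.1,
                             epoch_interval = 5) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg) > 0), small_buffer_km <= large_buffer_km)
  class(cfg) <- "community_config"
  cfg
}

#' Smooth a population grid into a density layer
#'
#' Converts people/cell to people/km^2 (100-m cells cover 0.01 km^2), then
#' assigns each cell the unweighted mean of the densities of all cells whose
#' centres lie within the smoothing radius (29 cells for a 300-m radius on a
#' 100-m lattice).  At grid edges the mean runs over the cells that exist, so
#' the output is everywhere a convex combination of raw densities.
#'
#' @param pop a [burn_grid()] of people per cell.
#' @param radius_km smoothing radius (default 0.3).
#' @return a [burn_grid()] of smoothed density, people/km^2.
#' @export
smooth_density <- function(pop, radius_km = 0.3) {
  if (radius_km <= 0) stop("smoothing radius must be positive")
  dens <- pop$values / (pop$cell^2)          # people per km^2
  r <- floor(radius_km / pop$cell + 1e-9)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= (radius_km / pop$cell)^2 + 1e-9, ]
  nr <- nrow(dens); nc <- ncol(dens)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    sr <- max(1, 1 - dy):min(nr, nr - dy)
    sc <- max(1, 1 - dx):min(nc, nc - dx)
    acc[sr, sc] <- acc[sr, sc] + dens[sr + dy, sc + dx]
    cnt[sr, sc] <- cnt[sr, sc] + 1
  }
  burn_grid(acc / cnt, cell = pop$cell, x0 = pop$x0, y0 = pop$y0,
            frame = pop$frame)
}

#' Size-dependent buffer zone around a burn geometry
#'
#' 10 km for fires under 1,000 acres or point-only geometries; 20 km for
#' fires of at least 1,000 acres.  The zone is represented by the base
#' geometry plus the buffer distance; membership tests use exact Euclidean
#' distance to the geometry (equivalent to the Minkowski buffer polygon for
#' any simple polygon), and an explicit ring is available via `zone$ring()`.
#'
#' @param assignment geometry-assignment fields for one fire: list/row with
#'   `geometry` (polygon matrix or point) and `geometry_source`.
#' @param area_acres reported burn area (NA allowed).
#' @param cfg a [community_config()].
#' @return object of class `buffer_zone` (geometry, dist_km, ring()).
#' @export
buffer_zone <- function(assignment, area_acres, cfg = community_config()) {
  geom <- assignment$geometry
  if (is.list(geom) && !is.matrix(geom)) geom <- geom[[1]]
  if (is.null(geom)) stop("county-only records have no geometry to buffer")
  is_point <- is.null(dim(geom))
  dist <- if (is_point || is.na(area_acres) ||
              area_acres < cfg$size_threshold_acres) {
    cfg$small_buffer_km
  } else {
    cfg$large_buffer_km
  }
  structure(list(geometry = geom, dist_km = dist,
                 ring = function() buffer_ring(geom, dist)),
            class = "buffer_zone")
}

#' Does the zone contain these points?
#' @param zone a [buffer_zone()].
#' @param px,py planar coordinates (km).
#' @return logical vector.
#' @export
zone_contains <- function(zone, px, py) {
  g <- zone$geometry
  if (is.null(dim(g))) {
    sqrt((px - g[1])^2 + (py - g[2])^2) <= zone$dist_km
  } else {
    dist_points_to_polygon(px, py, g) <= zone$dist_km
  }
}

# crop a grid to a planar bbox (expanded to cell boundaries)
crop_grid <- function(grid, xmin, xmax, ymin, ymax) {
  nc <- ncol(grid$values); nr <- nrow(grid$values)
  j0 <- max(1L, floor((xmin - grid$x0) / grid$cell) + 1L)
  j1 <- min(nc, ceiling((xmax - grid$x0) / grid$cell))
  i0 <- max(1L, floor((ymin - grid$y0) / grid$cell) + 1L)
  i1 <- min(nr, ceiling((ymax - grid$y0) / grid$cell))
  if (j0 > j1 || i0 > i1) return(NULL)
  burn_grid(grid$values[i0:i1, j0:j1, drop = FALSE], cell = grid$cell,
            x0 = grid$x0 + (j0 - 1L) * grid$cell,
            y0 = grid$y0 + (i0 - 1L) * grid$cell, frame = grid$frame)
}

zone_bbox <- function(zone) {
  g <- zone$geometry
  if (is.null(dim(g))) {
    c(g[1] - zone$dist_km, g[1] + zone$dist_km,
      g[2] - zone$dist_km, g[2] + zone$dist_km)
  } else {
    c(min(g[, 1]) - zone$dist_km, max(g[, 1]) + zone$dist_km,
      min(g[, 2]) - zone$dist_km, max(g[, 2]) + zone$dist_km)
  }
}

#' Population-density exposure within a buffered zone
#'
#' @param zone a [buffer_zone()].
#' @param smoothed smoothed density grid from [smooth_density()].
#' @param cfg a [community_config()].
#' @return list(max_density, mean_density, density_flag, n_cells,
#'   out_of_extent).
#' @export
density_exposure <- function(zone, smoothed, cfg = community_config()) {
  bb <- zone_bbox(zone)
  sub <- crop_grid(smoothed, bb[1], bb[2], bb[3], bb[4])
  if (is.null(sub)) {
    return(list(max_density = 0, mean_density = 0, density_flag = FALSE,
                n_cells = 0L, out_of_extent = TRUE))
  }
  ctr <- grid_centers(sub)
  ny <- length(ctr$y); nx <- length(ctr$x)
  px <- rep(ctr$x, each = ny); py <- rep(ctr$y, times = nx)
  inz <- zone_contains(zone, px, py)
  if (!any(inz)) {
    return(list(max_density = 0, mean_density = 0, density_flag = FALSE,
                n_cells = 0L, out_of_extent = TRUE))
  }
  vals <- as.vector(sub$values)[inz]
  # tiny relative tolerance so a density that is exactly at the threshold in
  # real arithmetic is not dropped by binary rounding (0.96/0.01 < 96 in FP)
  list(max_density = max(vals), mean_density = mean(vals),
       density_flag = max(vals) >= cfg$density_threshold * (1 - 1e-12),
       n_cells = sum(inz), out_of_extent = FALSE)
}

#' Round an ignition year to its population-grid epoch
#' @param year integer ignition year.
#' @param interval epoch spacing (5).
#' @return nearest multiple of `interval` (half-up).
#' @export
epoch_for_year <- function(year, interval = 5) {
  as.integer(interval * floor(year / interval + 0.5))
}

#' WUI overlap and the community flag
#'
#' The WUI class comes from the intersection of the unbuffered burn geometry
#' with WUI cells (points use their containing cell); the community flag is
#' density_flag OR any WUI overlap.
#'
#' @param assignment geometry assignment (list/row with `geometry`).
#' @param wui WUI class grid from [classify_wui()].
#' @param density_flag logical from [density_exposure()].
#' @return list(wui_class = "intermix"|"interface"|"both"|"none",
#'   community_flag).
#' @export
classify_community <- function(assignment, wui, density_flag) {
  geom <- assignment$geometry
  if (is.list(geom) && !is.matrix(geom)) geom <- geom[[1]]
  wclass <- "none"
  if (!is.null(geom)) {
    if (is.null(dim(geom))) {
      bb <- c(geom[1], geom[1], geom[2], geom[2])
    } else {
      bb <- c(min(geom[, 1]), max(geom[, 1]), min(geom[, 2]), max(geom[, 2]))
    }
    sub <- crop_grid(wui, bb[1] - wui$cell, bb[2] + wui$cell,
                     bb[3] - wui$cell, bb[4] + wui$cell)
    if (!is.null(sub)) {
      m <- grid_mask_near(sub, geom, 0)
      codes <- unique(sub$values[m])
      has_mix <- WUI_INTERMIX %in% codes
      has_int <- WUI_INTERFACE %in% codes
      wclass <- if (has_mix && has_int) "both" else if (has_mix) "intermix"
        else if (has_int) "interface" else "none"
    }
  }
  list(wui_class = wclass,
       community_flag = isTRUE(density_flag) || wclass != "none")
}

#' Evaluate community proximity for every fire
#'
#' County-only records cannot be buffered: they get `community_flag = NA` and
#' stay in the full output but are excluded from the flagged disaster subset.
#'
#' @param fires output of [merge_linked_groups()].
#' @param pop_grids named list of population grids keyed by epoch year
#'   (e.g. `"2010"`), or a function(epoch) returning one.
#' @param wui WUI class grid.
#' @param cfg a [community_config()].
#' @return `fires` with `max_density`, `mean_density`, `density_flag`,
#'   `wui_class`, `community_flag`, `epoch_year`.
#' @export
evaluate_community <- function(fires, pop_grids, wui,
                               cfg = community_config()) {
  n <- nrow(fires)
  get_grid <- if (is.function(pop_grids)) pop_grids else {
    cache <- lapply(pop_grids, smooth_density, radius_km = cfg$smoothing_radius_km)
    function(ep) cache[[as.character(ep)]]
  }
  maxd <- meand <- rep(NA_real_, n)
  dflag <- rep(NA, n)
  wclass <- rep(NA_character_, n)
  cflag <- rep(NA, n)
  epoch <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    geom <- fires$geometry[[i]]
    if (is.null(geom)) next                     # county_only
    yr <- fires$year[i]
    ep <- epoch_for_year(if (is.na(yr)) 2000 else yr, cfg$epoch_interval)
    epoch[i] <- ep
    sm <- get_grid(ep)
    if (is.null(sm)) stop("no population grid for epoch ", ep)
    # size for the 10/20-km rule: reported burn area, else the area of the
    # linked perimeter itself
    eff_area <- fires$area_acres[i]
    if (is.na(eff_area) && !is.na(fires$area_km2[i]))
      eff_area <- km2_to_acres(fires$area_km2[i])
    zone <- buffer_zone(list(geometry = geom), eff_area, cfg)
    de <- density_exposure(zone, sm, cfg)
    maxd[i] <- de$max_density; meand[i] <- de$mean_density
    dflag[i] <- de$density_flag
    cc <- classify_community(list(geometry = geom), wui, de$density_flag)
    wclass[i] <- cc$wui_class
    cflag[i] <- cc$community_flag
  }
  fires$max_density <- maxd
  fires$mean_density <- meand
  fires$density_flag <- dflag
  fires$wui_class <- wclass
  fires$community_flag <- cflag
  fires$epoch_year <- epoch
  fires
}
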