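# Planar geometry primitives.
#
# All spatial computation in this package happens in an equal-area planar
# frame with kilometre units (an Albers-style working frame); longitude and
# latitude appear only at I/O boundaries.  Polygons are numeric matrices with
# columns x, y (kilometres), vertices in order, not explicitly closed.

ACRES_PER_KM2 <- 247.105381467165

#' Convert acres to square kilometres
#' @param acres numeric vector of areas in acres.
#' @return numeric vector of areas in km^2.
#' @export
acres_to_km2 <- function(acres) acres / ACRES_PER_KM2

#' Convert square kilometres to acres
#' @param km2 numeric vector of areas in km^2.
#' @return numeric vector of areas in acres.
#' @export
km2_to_acres <- function(km2) km2 * ACRES_PER_KM2

as_poly_matrix <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly)
  if (!is.matrix(poly) || ncol(poly) < 2L || nrow(poly) < 3L) {
    stop("polygon must be a matrix with >= 3 rows and columns x, y")
  }
  storage.mode(poly) <- "double"
  poly[, 1:2, drop = FALSE]
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly matrix of vertices (x, y) in km; ring need not be closed.
#' @return area in km^2 (absolute value).
#' @export
polygon_area <- function(poly) {
  p <- as_poly_matrix(poly)
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))  # previous vertex
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(poly) {
  p <- as_poly_matrix(poly)
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Test points for polygon containment (even-odd ray casting)
#'
#' Points exactly on an edge count as inside.
#'
#' @param px,py numeric vectors of point coordinates (km).
#' @param poly polygon vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  p <- as_poly_matrix(poly)
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      flip <- xint > px[crosses]
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  on_edge <- dist_points_to_ring(px, py, p) < 1e-9
  inside | on_edge
}

# Minimum distance from each point to the polygon boundary (ring edges).
dist_points_to_ring <- function(px, py, poly) {
  p <- as_poly_matrix(poly)
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- x[j]; ay <- y[j]; bx <- x[i]; by <- y[i]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      dd <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- ((px - ax) * dx + (py - ay) * dy) / len2
      t <- pmin(1, pmax(0, t))
      qx <- ax + t * dx; qy <- ay + t * dy
      dd <- (px - qx)^2 + (py - qy)^2
    }
    d2 <- pmin(d2, dd)
    j <- i
  }
  sqrt(d2)
}

#' Distance from points to a polygon (zero inside)
#'
#' Euclidean distance in the planar frame; points inside (or on the boundary
#' of) the polygon have distance 0, so `dist <= d` is exact membership in the
#' Minkowski d-buffer of the polygon for any simple polygon.
#'
#' @param px,py point coordinates (km).
#' @param poly polygon vertex matrix.
#' @return numeric vector of distances in km.
#' @export
dist_points_to_polygon <- function(px, py, poly) {
  d <- dist_points_to_ring(px, py, poly)
  d[points_in_polygon(px, py, poly)] <- 0
  d
}

#' Regular-polygon approximation of a circle
#'
#' @param cx,cy centre (km).
#' @param radius_km circle radius in km.
#' @param n_segments number of boundary segments (>= 8).
#' @return polygon vertex matrix.
#' @export
circle_polygon <- function(cx, cy, radius_km, n_segments = 256L) {
  stopifnot(is.finite(radius_km), radius_km > 0, n_segments >= 8L)
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  # inflate so the polygon area equals the disc area (vertices on a slightly
  # larger circle than the inscribed regular polygon would use)
  r_adj <- radius_km * sqrt(2 * pi / (n_segments * sin(2 * pi / n_segments)))
  cbind(x = cx + r_adj * cos(th), y = cy + r_adj * sin(th))
}

#' Minkowski buffer of a polygon or point
#'
#' Exact for convex rings (edge offsets joined by vertex arcs); non-convex
#' rings are buffered via their convex hull, which is conservative and is used
#' only where an explicit ring is needed (export/plots).  Membership tests in
#' the pipeline always use [dist_points_to_polygon()], which is exact for any
#' simple polygon.
#'
#' @param poly polygon vertex matrix, or a single point as c(x, y).
#' @param dist_km buffer distance in km (> 0).
#' @param arc_step radians per arc segment.
#' @return polygon vertex matrix.
#' @export
buffer_ring <- function(poly, dist_km, arc_step = pi / 64) {
  stopifnot(is.finite(dist_km), dist_km > 0)
  if (is.numeric(poly) && is.null(dim(poly)) && length(poly) == 2L) {
    return(circle_polygon(poly[1], poly[2], dist_km))
  }
  p <- as_poly_matrix(poly)
  h <- grDevices::chull(p[, 1], p[, 2])
  p <- p[h, , drop = FALSE]
  n <- nrow(p)
  if (n >= 3L) {
    j <- c(n, seq_len(n - 1L))
    signed <- sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2]) / 2
    if (signed < 0) p <- p[rev(seq_len(n)), , drop = FALSE]  # force CCW
  }
  if (n < 3L) return(circle_polygon(mean(p[, 1]), mean(p[, 2]), dist_km))
  out <- list()
  for (i in seq_len(n)) {
    a <- p[if (i == 1L) n else i - 1L, ]
    b <- p[i, ]
    cpt <- p[if (i == n) 1L else i + 1L, ]
    # outward normals of edges (a,b) and (b,c) for a CCW ring
    n1 <- c(b[2] - a[2], a[1] - b[1]); n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(cpt[2] - b[2], b[1] - cpt[1]); n2 <- n2 / sqrt(sum(n2^2))
    th1 <- atan2(n1[2], n1[1]); th2 <- atan2(n2[2], n2[1])
    dth <- th2 - th1
    while (dth < 0) dth <- dth + 2 * pi
    k <- max(1L, ceiling(dth / arc_step))
    th <- th1 + dth * seq(0, 1, length.out = k + 1L)
    out[[i]] <- cbind(b[1] + dist_km * cos(th), b[2] + dist_km * sin(th))
  }
  ring <- do.call(rbind, out)
  colnames(ring) <- c("x", "y")
  ring
}

#' Repair a polygon ring
#'
#' Drops duplicate consecutive vertices and closing repeats; degenerate rings
#' (< 3 distinct vertices or zero area) return NULL.  This is the plain-text
#' analogue of a zero-width-buffer repair followed by a multipolygon cast.
#'
#' @param poly polygon vertex matrix.
#' @return repaired matrix or NULL.
#' @export
repair_ring <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly)
  if (!is.matrix(poly) || nrow(poly) < 3L) return(NULL)
  p <- as_poly_matrix(poly)
  if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-12)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 3L || polygon_area(p) <= 0) return(NULL)
  p
}

#' Planar working frame anchored at a geographic origin
#'
#' Defines the mapping between the package's planar km coordinates and
#' longitude/latitude.  A cylindrical equal-area style local approximation is
#' used: x = R cos(lat0) (lon - lon0), y = R (lat - lat0) (radians); over the
#' few-hundred-km synthetic extents used here area distortion is negligible
#' (< 0.5%) and the frame behaves as equal-area.
#'
#' @param lon0,lat0 geographic anchor (degrees) mapped to planar (0, 0).
#' @return an object of class `burn_frame`.
#' @export
burn_frame <- function(lon0 = -120, lat0 = 39) {
  structure(list(lon0 = lon0, lat0 = lat0, R = 6371.0088),
            class = "burn_frame")
}

#' Planar km to longitude/latitude
#' @param xy matrix/data.frame with x, y columns (km) or length-2 vector.
#' @param frame a [burn_frame()].
#' @return matrix with columns lon, lat (degrees).
#' @export
planar_to_lonlat <- function(xy, frame) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  xy <- as.matrix(xy)
  deg <- 180 / pi
  lon <- frame$lon0 + deg * xy[, 1] / (frame$R * cos(frame$lat0 * pi / 180))
  lat <- frame$lat0 + deg * xy[, 2] / frame$R
  cbind(lon = lon, lat = lat)
}

#' Longitude/latitude to planar km
#' @param ll matrix with lon, lat columns (degrees) or length-2 vector.
#' @param frame a [burn_frame()].
#' @return matrix with columns x, y (km).
#' @export
lonlat_to_planar <- function(ll, frame) {
  if (is.null(dim(ll))) ll <- matrix(ll, ncol = 2L)
  ll <- as.matrix(ll)
  rad <- pi / 180
  x <- frame$R * cos(frame$lat0 * rad) * (ll[, 1] - frame$lon0) * rad
  y <- frame$R * (ll[, 2] - frame$lat0) * rad
  cbind(x = x, y = y)
}
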