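# Wildland-urban interface classification.
#
# Cells are classified from co-registered housing-density and
# vegetation-fraction grids:
#   intermix : vegetation > 50% and housing >= 6.17 houses/km^2
#   interface: housing >= 6.17, vegetation <= 50%, and within 2.4 km of a
#              contiguous (8-connected) patch of cells with vegetation >= 75%
#              covering >= 5 km^2
#   non-WUI  : everything else
# Codes: 0 = non-WUI, 1 = intermix, 2 = interface.

WUI_NONE <- 0L
WUI_INTERMIX <- 1L
WUI_INTERFACE <- 2L

#' WUI rule thresholds
#'
#' @param veg_threshold intermix vegetation fraction threshold (0.5).
#' @param housing_min minimum housing density, houses/km^2 (6.17, i.e. more
#'   than one house per 40 acres).
#' @param interface_dist interface distance to a wildland patch, km (2.4).
#' @param patch_min_area minimum wildland patch area, km^2 (5).
#' @param patch_veg_fraction minimum patch vegetation fraction (0.75).
#' @return list of class `wui_rules`.
#' @export
wui_rules <- function(veg_threshold = 0.5, housing_min = 6.17,
                      interface_dist = 2.4, patch_min_area = 5,
                      patch_veg_fraction = 0.75) {
  r <- as.list(environment())
  stopifnot(all(unlist(r) > 0),
            veg_threshold < 1, patch_veg_fraction < 1)
  class(r) <- "wui_rules"
  r
}

# 8-connected component labels of a logical matrix, via igraph
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  ij <- arrayInd(idx, dim(mask))
  key <- idx                                  # linear index of TRUE cells
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- ij[, 1] + off[1]; nj <- ij[, 2] + off[2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= ncol(mask)
    nb <- (nj[ok] - 1L) * nr + ni[ok]
    hit <- mask[nb]
    edges[[length(edges) + 1L]] <- cbind(key[ok][hit], nb[hit])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(edges = as.vector(t(e)), n = nr * ncol(mask),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  ids <- memb[idx]
  lab[idx] <- match(ids, unique(ids))   # compact labels 1..k over TRUE cells
  lab
}

# binary dilation by a Euclidean disc of radius `radius_cells`, FFT-based
dilate_mask <- function(mask, radius_cells) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ceiling(radius_cells)
  pr <- nr + 2L * r; pc <- nc + 2L * r
  big <- matrix(0, pr, pc)
  big[(r + 1):(r + nr), (r + 1):(r + nc)] <- as.numeric(mask)
  # disc kernel centred at (1,1) with wrapped offsets
  off <- seq(-r, r)
  k <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= radius_cells^2 + 1e-9))
  kern <- matrix(0, pr, pc)
  ri <- ((off) %% pr) + 1L
  ci <- ((off) %% pc) + 1L
  kern[ri, ci] <- k
  conv <- Re(stats::fft(stats::fft(big) * stats::fft(kern), inverse = TRUE)) / (pr * pc)
  out <- conv[(r + 1):(r + nr), (r + 1):(r + nc)] > 0.5
  out | mask
}

#' Classify cells into WUI classes
#'
#' @param housing [burn_grid()] of housing density, houses/km^2.
#' @param vegetation [burn_grid()] of vegetation fraction in \[0, 1\].
#' @param rules a [wui_rules()].
#' @return a [burn_grid()] of integer codes (0 non-WUI, 1 intermix,
#'   2 interface).
#' @export
classify_wui <- function(housing, vegetation, rules = wui_rules()) {
  if (!same_grid_frame(housing, vegetation))
    stop("housing and vegetation grids must share one frame")
  h <- housing$values; v <- vegetation$values
  cell_area <- housing$cell^2
  intermix <- v > rules$veg_threshold & h >= rules$housing_min

  dense_veg <- v >= rules$patch_veg_fraction
  lab <- label_components(dense_veg)
  sizes <- tabulate(lab[lab > 0])
  big_ids <- which(sizes * cell_area >= rules$patch_min_area)
  big_patch <- matrix(lab %in% big_ids & lab > 0, nrow(h), ncol(h))
  near_patch <- if (any(big_patch)) {
    dilate_mask(big_patch, rules$interface_dist / housing$cell)
  } else matrix(FALSE, nrow(h), ncol(h))

  interface <- h >= rules$housing_min & v <= rules$veg_threshold & near_patch

  codes <- matrix(WUI_NONE, nrow(h), ncol(h))
  codes[interface] <- WUI_INTERFACE
  codes[intermix] <- WUI_INTERMIX      # intermix takes precedence (disjoint anyway)
  burn_grid(codes, cell = housing$cell, x0 = housing$x0, y0 = housing$y0,
            frame = housing$frame)
}
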