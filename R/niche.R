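#' Gridded occurrence density in a 2-D environmental space
#'
#' Kernel-smoothed density of occurrence points on a `bins x bins` grid
#' spanning the extent of the background (available environment), corrected
#' for environmental availability: the occurrence density is divided by the
#' background density where the background is positive, then renormalised
#' to sum to 1. The two axes are typically the first two principal
#' components of standardised environmental variables.
#'
#' @param points occurrence coordinates: 2-column matrix/data.frame.
#' @param background available-environment coordinates (2 columns); defines
#'   the grid extent and the availability correction.
#' @param bins grid resolution per axis (default 100, i.e. 10,000 cells).
#' @param bandwidth kernel bandwidth for the occurrence density, one value
#'   per axis (recycled); defaults to the normal-reference bandwidth of the
#'   background axes.
#' @param background_bandwidth bandwidth for the availability surface;
#'   defaults to the normal-reference rule on the background.
#' @return A `refugia_density_grid`: `values` (bins x bins, sums to 1),
#'   `bins`, `extent`, `bandwidth`.
#' @export
occurrence_density_grid <- function(points, background, bins = 100,
                                    bandwidth = NULL,
                                    background_bandwidth = NULL) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  background <- as.matrix(background)[, 1:2, drop = FALSE]
  if (nrow(points) < 1) stop("need at least one occurrence point")
  if (nrow(background) < 1) stop("background is empty")
  if (bins < 2) stop("bins must be >= 2")
  ext <- c(range(background[, 1]), range(background[, 2]))
  if (any(points[, 1] < ext[1] | points[, 1] > ext[2] |
          points[, 2] < ext[3] | points[, 2] > ext[4])) {
    stop("extent of background must cover all occurrence points")
  }
  nrd_bw <- function() {
    h <- c(MASS::bandwidth.nrd(background[, 1]),
           MASS::bandwidth.nrd(background[, 2]))
    h[h <= 0] <- diff(ext[1:2]) / bins
    h
  }
  if (is.null(bandwidth)) bandwidth <- nrd_bw()
  if (is.null(background_bandwidth)) background_bandwidth <- nrd_bw()
  bandwidth <- rep(bandwidth, length.out = 2)
  background_bandwidth <- rep(background_bandwidth, length.out = 2)
  kd <- function(m, h) {
    z <- MASS::kde2d(m[, 1], m[, 2], h = pmax(h, 1e-12), n = bins,
                     lims = ext)$z
    z / sum(z)
  }
  occ <- kd(points, bandwidth)
  bg <- kd(background, background_bandwidth)
  corrected <- ifelse(bg > 1e-12 * max(bg), occ / bg, 0)
  s <- sum(corrected)
  if (s <= 0) stop("occurrence density vanishes over the background support")
  structure(list(values = corrected / s, bins = bins,
                 extent = matrix(ext, 2, 2,
                                 dimnames = list(c("min", "max"),
                                                 c("axis1", "axis2"))),
                 bandwidth = bandwidth),
            class = "refugia_density_grid")
}

#' Schoener's D niche overlap between two density grids
#'
#' `D = 1 - 0.5 * sum |z1 - z2|` over grid cells, with `z` the normalised
#' occurrence densities; 0 = fully disjoint niches, 1 = identical.
#'
#' @param g1,g2 `refugia_density_grid` objects on the same grid.
#' @export
schoener_d <- function(g1, g2) {
  if (!identical(dim(g1$values), dim(g2$values)) ||
      !isTRUE(all.equal(g1$extent, g2$extent))) {
    stop("density grids have different bins or extents")
  }
  1 - 0.5 * sum(abs(g1$values - g2$values))
}
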