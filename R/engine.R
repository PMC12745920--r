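#' Numerical configuration of the diffusion engine
#'
#' The expected spectrum is computed by forward integration of the
#' two-population allele-frequency diffusion on a frequency grid that is
#' uniform in a transformed coordinate crowding points near the boundaries
#' (where the density behaves like `theta/x`), at each of `grid_sizes`
#' resolutions, followed by quadratic extrapolation of every spectrum entry
#' to zero grid spacing.
#'
#' @param grid_sizes strictly increasing integer vector (>= 2 sizes) of grid
#'   resolutions; the default `(40, 50, 60)` is adequate for sample sizes up
#'   to about 20.
#' @param time_step_factor maximum integration time step, in units of
#'   `2 N_ref` generations.
#' @param extrapolation logical; `FALSE` uses only the largest grid.
#' @param crowding in `[0, 1)`: strength of the boundary crowding of the
#'   frequency grid (0 = uniform grid).
#' @export
engine_config <- function(grid_sizes = c(40L, 50L, 60L),
                          time_step_factor = 1e-3,
                          extrapolation = TRUE, crowding = 0.9) {
  grid_sizes <- as.integer(grid_sizes)
  if (length(grid_sizes) < 2 || any(diff(grid_sizes) <= 0)) {
    stop("grid_sizes must be >= 2 strictly increasing values")
  }
  if (time_step_factor <= 0) stop("time_step_factor must be > 0")
  structure(list(grid_sizes = grid_sizes,
                 time_step_factor = time_step_factor,
                 extrapolation = isTRUE(extrapolation),
                 crowding = crowding),
            class = "refugia_engine_config")
}

# frequency grid on [0,1], uniform in u with a smooth sine warp toward ends
frequency_grid <- function(pts, crowding = 0.9) {
  u <- seq(0, 1, length.out = pts)
  u - crowding * sin(2 * pi * u) / (2 * pi)
}

# trapezoid weights for nodes xx
trapezoid_weights <- function(xx) {
  G <- length(xx)
  dx <- diff(xx)
  c(dx[1] / 2, (dx[-1] + dx[-(G - 1)]) / 2, dx[G - 1] / 2)
}

# neutral equilibrium density of the ancestral population (per unit theta)
phi_equilibrium <- function(xx) {
  phi <- 1 / xx
  phi[1] <- phi[2]
  phi
}

# place a 1D density on the diagonal of the 2D grid (same grid both axes)
phi_diagonal <- function(phi1, xx) {
  w <- trapezoid_weights(xx)
  G <- length(xx)
  out <- matrix(0, G, G)
  out[cbind(seq_len(G), seq_len(G))] <- phi1 / w
  out
}

# integrate phi against the binomial sampling kernels -> spectrum entries
extract_sfs_2d <- function(phi, xx, n1, n2) {
  w <- trapezoid_weights(xx)
  W1 <- outer(0:n1, xx, function(a, x) stats::dbinom(a, n1, x))
  W2 <- outer(0:n2, xx, function(a, x) stats::dbinom(a, n2, x))
  sweep(W1, 2, w, "*") %*% phi %*% t(sweep(W2, 2, w, "*"))
}

extract_sfs_1d <- function(phi, xx, n) {
  w <- trapezoid_weights(xx)
  W <- outer(0:n, xx, function(a, x) stats::dbinom(a, n, x))
  as.vector(W %*% (phi * w))
}

# quadratic (Lagrange) extrapolation of results to zero grid spacing;
# results: list of equal-shape arrays, deltas: the spacing of each
richardson_extrapolate <- function(results, deltas) {
  stopifnot(length(results) == length(deltas))
  if (length(results) == 1) return(results[[1]])
  out <- 0
  for (g in seq_along(results)) {
    coef <- prod(-deltas[-g] / (deltas[g] - deltas[-g]))
    out <- out + coef * results[[g]]
  }
  out
}

#' Expected joint SFS under a divergence model (per unit theta)
#'
#' Solves the two-population Wright-Fisher diffusion forward in time: the
#' ancestral population starts at its single-population neutral equilibrium,
#' the split places the density on the diagonal of the 2D frequency grid,
#' and each epoch evolves it under per-population drift (strength
#' `1/nu_i`), linear migration `M_ij (x_j - x_i)`, and continuing
#' low-frequency mutation influx. Entries are the integrals of the density
#' against binomial sampling kernels, extrapolated across grid resolutions.
#'
#' @param model catalog model name (see [model_catalog()]).
#' @param params named parameter vector for the model.
#' @param n1,n2 haploid sample sizes of the output spectrum.
#' @param engine an [engine_config()].
#' @param fold return the folded spectrum?
#' @return A `refugia_spectrum` of expected densities per unit theta.
#' @export
expected_sfs <- function(model, params, n1, n2, engine = engine_config(),
                         fold = FALSE) {
  if (n1 < 2 || n2 < 2) stop("sample sizes must be >= 2")
  epochs <- model_epochs(model, params)
  sizes <- if (engine$extrapolation) engine$grid_sizes else
    max(engine$grid_sizes)
  results <- list()
  deltas <- numeric(0)
  for (pts in sizes) {
    xx <- frequency_grid(pts, engine$crowding)
    phi <- phi_diagonal(phi_equilibrium(xx), xx)
    if (nrow(epochs)) {
      for (e in seq_len(nrow(epochs))) {
        phi <- diff_integrate_2d(phi, xx, epochs$dur[e],
                                 epochs$nu1_0[e], epochs$nu1_1[e],
                                 epochs$nu2_0[e], epochs$nu2_1[e],
                                 epochs$m12[e], epochs$m21[e],
                                 engine$time_step_factor)
      }
    }
    results[[length(results) + 1]] <- extract_sfs_2d(phi, xx, n1, n2)
    deltas <- c(deltas, xx[2] - xx[1])
  }
  out <- pmax(richardson_extrapolate(results, deltas), 0)
  spec <- spectrum2d(out, folded = FALSE)
  if (fold) spec <- fold_spectrum(spec)
  spec
}

#' Expected 1D SFS of one isolated population (engine validation path)
#'
#' Starts from the ancestral equilibrium of size 1 and integrates the 1D
#' diffusion under relative size `nu` for `T_relax` time units (long enough
#' to re-equilibrate by default); at equilibrium the entries approach
#' `nu / i` per unit theta.
#'
#' @param nu relative population size.
#' @param n haploid sample size.
#' @param T_relax integration time in `2 N_ref` generations.
#' @param engine an [engine_config()].
#' @export
expected_sfs_1d <- function(nu, n, T_relax = 8 * max(1, nu),
                            engine = engine_config()) {
  sizes <- if (engine$extrapolation) engine$grid_sizes else
    max(engine$grid_sizes)
  results <- list()
  deltas <- numeric(0)
  for (pts in sizes) {
    xx <- frequency_grid(pts, engine$crowding)
    phi <- diff_integrate_1d(phi_equilibrium(xx), xx, T_relax, nu, nu,
                             engine$time_step_factor, TRUE)
    results[[length(results) + 1]] <- extract_sfs_1d(phi, xx, n)
    deltas <- c(deltas, xx[2] - xx[1])
  }
  pmax(richardson_extrapolate(results, deltas), 0)
}
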