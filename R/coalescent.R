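#' Monte-Carlo expected JSFS from the structured coalescent
#'
#' Independent brute-force check on the diffusion engine: simulates
#' `n_replicates` two-population structured-coalescent genealogies honouring
#' the scenario's split fraction, size trajectories (including continuous
#' exponential growth of a founded deme, by exact inversion of the
#' integrated coalescence intensity) and migration epochs, and averages
#' `0.5 x` branch length subtending each `(i, j)` sample configuration.
#' The result estimates the expected spectrum per unit theta; per-entry
#' Monte-Carlo standard errors are attached as attribute `"se"`.
#'
#' @param config a [sim_config()]; `model_name`, `params`, `n1`, `n2` and
#'   `seed` are used.
#' @param n_replicates number of independent genealogies (one per unlinked
#'   site).
#' @return A `refugia_spectrum` (unfolded, per unit theta) with attribute
#'   `"se"`.
#' @export
simulate_coalescent_jsfs <- function(config, n_replicates = 1e5) {
  stopifnot(n_replicates >= 1)
  epochs <- model_epochs(config$model_name, config$params)
  set.seed(config$seed)

  # convert forward epochs to backward order; backward size within an epoch
  # is nu0 * exp(g * u) with u the time since entering the epoch
  if (nrow(epochs)) {
    bw <- epochs[rev(seq_len(nrow(epochs))), , drop = FALSE]
    dur <- bw$dur
    nu1_0 <- bw$nu1_1
    g1 <- ifelse(dur > 0, log(bw$nu1_0 / bw$nu1_1) / dur, 0)
    nu2_0 <- bw$nu2_1
    g2 <- ifelse(dur > 0, log(bw$nu2_0 / bw$nu2_1) / dur, 0)
    m12 <- bw$m12
    m21 <- bw$m21
  } else {
    dur <- nu1_0 <- g1 <- nu2_0 <- g2 <- m12 <- m21 <- numeric(0)
  }
  # ancestral single population of size 1
  dur <- c(dur, Inf)
  nu1_0 <- c(nu1_0, 1)
  g1 <- c(g1, 0)
  nu2_0 <- c(nu2_0, 1)
  g2 <- c(g2, 0)
  m12 <- c(m12, 0)
  m21 <- c(m21, 0)

  res <- coal_jsfs_cpp(config$n1, config$n2, as.integer(n_replicates),
                       dur, nu1_0, g1, nu2_0, g2, m12, m21)
  spec <- spectrum2d(res$mean, folded = FALSE)
  attr(spec, "se") <- res$se
  spec
}
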