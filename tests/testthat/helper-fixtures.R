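# shared fixture builders

# genotype matrix from a sites x samples dosage matrix with uniform DP/GQ
make_gm <- function(dosage, pops, dp = 30, gq = 99, locus_id = NULL,
                    pos = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  }
  mk <- function(v) matrix(v, nrow(dosage), ncol(dosage))
  genotype_matrix(dosage, dp = mk(dp), gq = mk(gq), locus_id = locus_id,
                  pos = pos, pop_map = stats::setNames(pops, colnames(dosage)))
}

# small random count spectrum
random_spectrum <- function(n1, n2, lambda = 5, seed = 1) {
  set.seed(seed)
  spectrum2d(matrix(rpois((n1 + 1) * (n2 + 1), lambda), n1 + 1, n2 + 1))
}

# fast engine for tests that only need moderate accuracy
fast_engine <- engine_config(grid_sizes = c(30L, 40L, 50L),
                             time_step_factor = 2e-3)

# closed-form expected JSFS at divergence time zero (single ancestral pool):
# S(i,j) = C(n1,i) C(n2,j) / (C(n1+n2, i+j) * (i+j)) per unit theta
closed_form_t0 <- function(n1, n2) {
  outer(0:n1, 0:n2, function(i, j) {
    t <- i + j
    out <- choose(n1, i) * choose(n2, j) / (choose(n1 + n2, t) * pmax(t, 1))
    out[t == 0 | t == n1 + n2] <- NA
    out
  })
}

# exhaustive signed-rank test and Hodges-Lehmann pseudomedian for tiny n
enumerate_signed_rank <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p <- mean(w_all >= w_obs)
  walsh <- outer(x, x, "+")[upper.tri(diag(length(x)), diag = TRUE)] / 2
  list(p = p, pseudomedian = stats::median(walsh))
}
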