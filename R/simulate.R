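#' Simulation configuration for synthetic RADseq-like datasets
#'
#' Describes one synthetic dataset: the divergence scenario, haploid sample
#' sizes, number of variant sites, the total mutation input
#' `theta = 4 N_ref mu L` setting the scale of observed spectra, and the
#' per-genotype coverage/quality/missingness model emulating RADseq
#' genotype calls.
#'
#' @param model_name one of the nine catalog names ([model_catalog()]).
#' @param params named parameter vector for that model.
#' @param n1,n2 haploid sample sizes (even, >= 2; diploid individuals are
#'   `n/2` per population).
#' @param n_sites number of variant sites to emit.
#' @param theta_per_dataset expected total mutation input (dimensionless
#'   spectrum scale).
#' @param coverage_mean,coverage_sd per-genotype read-depth distribution
#'   (normal, rounded, floored at 0).
#' @param gq_model function mapping a depth vector to genotype-quality
#'   scores; the default is `min(99, round(4 DP + noise))`, a fixture
#'   convention only.
#' @param missing_rate fraction of genotypes dropped at random.
#' @param snps_per_locus number of SNPs per RADseq locus identifier (> 1
#'   exercises the single-SNP filter).
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @export
sim_config <- function(model_name, params, n1, n2, n_sites = 5000L,
                       theta_per_dataset = 1000,
                       coverage_mean = 25, coverage_sd = 6,
                       gq_model = default_gq_model,
                       missing_rate = 0, snps_per_locus = 1L, seed = 1L) {
  if (n1 < 2 || n2 < 2 || n1 %% 2 != 0 || n2 %% 2 != 0) {
    stop("n1 and n2 must be even and >= 2 (diploid individuals)")
  }
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (theta_per_dataset <= 0) stop("theta_per_dataset must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  check_params(model_name, params)
  structure(list(model_name = model_name, params = params,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 n_sites = as.integer(n_sites),
                 theta_per_dataset = theta_per_dataset,
                 coverage_mean = coverage_mean, coverage_sd = coverage_sd,
                 gq_model = gq_model, missing_rate = missing_rate,
                 snps_per_locus = as.integer(snps_per_locus),
                 seed = as.integer(seed)),
            class = "refugia_sim_config")
}

#' @rdname sim_config
#' @param dp read-depth vector.
#' @export
default_gq_model <- function(dp) {
  pmin(99L, pmax(0L, as.integer(round(4 * dp + stats::rnorm(length(dp), 0, 2)))))
}

#' Poisson-sample an observed spectrum from an expected one
#'
#' Each unmasked entry is drawn independently from a Poisson law with mean
#' `theta_hat x` the expected entry -- the sampling model under which
#' unlinked-site composite likelihoods and parametric bootstraps operate.
#'
#' @param expected a `refugia_spectrum` of non-negative densities.
#' @param theta_hat non-negative scale factor.
#' @param seed integer seed (reproducible draws).
#' @return A `refugia_spectrum` of integer counts.
#' @export
sample_observed_jsfs <- function(expected, theta_hat, seed = 1L) {
  if (theta_hat < 0) stop("theta_hat must be >= 0")
  set.seed(seed)
  out <- matrix(0, nrow(expected$data), ncol(expected$data))
  un <- !expected$mask
  out[un] <- stats::rpois(sum(un), theta_hat * expected$data[un])
  spectrum2d(out, folded = expected$folded, mask = expected$mask,
             pop_labels = expected$pop_labels)
}

#' Simulate a RADseq-like genotype dataset under a divergence scenario
#'
#' Draws `n_sites` unlinked biallelic variant sites whose joint derived-
#' allele counts follow the scenario's expected JSFS (diffusion engine,
#' conditioned on being variant in the full sample), scatters the derived
#' alleles over haplotypes, and dresses genotypes with read depth, quality
#' and missingness. The REF allele is the true ancestral state; folding
#' downstream is what discards that information.
#'
#' @param config a [sim_config()].
#' @param engine an [engine_config()] for the expected spectrum.
#' @return A [genotype_matrix()]; the generating expected spectrum is
#'   attached as attribute `"expected_sfs"`.
#' @export
simulate_genotype_dataset <- function(config, engine = engine_config()) {
  expected <- expected_sfs(config$model_name, config$params,
                           config$n1, config$n2, engine = engine)
  set.seed(config$seed)
  un <- which(!expected$mask)
  probs <- expected$data[un]
  cells <- sample(un, config$n_sites, replace = TRUE, prob = probs)
  i <- (cells - 1) %% (config$n1 + 1)          # derived count pop 1
  j <- (cells - 1) %/% (config$n1 + 1)         # derived count pop 2

  d1 <- config$n1 / 2L
  d2 <- config$n2 / 2L
  geno <- matrix(0L, config$n_sites, d1 + d2)
  scatter <- function(count, n_hap) {
    hap <- integer(n_hap)
    if (count > 0) hap[sample.int(n_hap, count)] <- 1L
    hap[seq(1, n_hap, by = 2)] + hap[seq(2, n_hap, by = 2)]
  }
  for (s in seq_len(config$n_sites)) {
    geno[s, ] <- c(scatter(i[s], config$n1), scatter(j[s], config$n2))
  }
  colnames(geno) <- c(sprintf("p1_ind%02d", seq_len(d1)),
                      sprintf("p2_ind%02d", seq_len(d2)))
  pop_map <- stats::setNames(rep(c("pop1", "pop2"), c(d1, d2)),
                             colnames(geno))

  dp <- matrix(pmax(0L, as.integer(round(stats::rnorm(
    length(geno), config$coverage_mean, config$coverage_sd)))),
    nrow(geno), ncol(geno))
  gq <- matrix(config$gq_model(as.vector(dp)), nrow(geno), ncol(geno))
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA
  }

  locus_of_site <- (seq_len(config$n_sites) - 1L) %/% config$snps_per_locus
  locus_id <- sprintf("locus_%06d", locus_of_site + 1L)
  pos <- ((seq_len(config$n_sites) - 1L) %% config$snps_per_locus) * 10L + 1L

  gm <- genotype_matrix(geno, dp = dp, gq = gq, locus_id = locus_id,
                        pos = pos, pop_map = pop_map)
  attr(gm, "expected_sfs") <- expected
  gm
}

#' Simulate cluster-assignment (Q) matrices
#'
#' Per-population cluster-proportion rows equal to the requested admixture
#' profile, optionally jittered by a Dirichlet draw centred on the profile.
#'
#' @param n_pops number of populations (rows).
#' @param k number of clusters (columns).
#' @param admixture_profile `n_pops x k` matrix of mixing weights; rows must
#'   sum to 1 (within 1e-9). A single row is recycled.
#' @param seed integer seed.
#' @param jitter_concentration if non-`NULL`, rows are drawn from
#'   `Dirichlet(profile * concentration)`.
#' @return Matrix of class `refugia_qmatrix`, rows named `pop1..popN`.
#' @export
simulate_q_matrices <- function(n_pops, k, admixture_profile, seed = 1L,
                                jitter_concentration = NULL) {
  prof <- matrix(admixture_profile, ncol = k, byrow = FALSE)
  if (nrow(prof) == 1) prof <- prof[rep(1, n_pops), , drop = FALSE]
  if (nrow(prof) != n_pops) stop("profile must have one row per population")
  if (any(abs(rowSums(prof) - 1) > 1e-9)) stop("profile rows must sum to 1")
  set.seed(seed)
  out <- prof
  if (!is.null(jitter_concentration)) {
    for (r in seq_len(n_pops)) {
      g <- stats::rgamma(k, shape = prof[r, ] * jitter_concentration)
      out[r, ] <- g / sum(g)
    }
  }
  rownames(out) <- sprintf("pop%d", seq_len(n_pops))
  colnames(out) <- sprintf("cluster%d", seq_len(k))
  class(out) <- c("refugia_qmatrix", class(out))
  out
}
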