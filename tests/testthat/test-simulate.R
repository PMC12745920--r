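test_that("Poisson sampling of spectra is calibrated and reproducible", {
  ex <- spectrum2d(matrix(c(0, 2, 1, 0.5, 3, 1, 0.2, 1, 0), 3, 3))
  expect_equal(sum(sample_observed_jsfs(ex, 0, seed = 1)$data), 0)

  a <- sample_observed_jsfs(ex, 50, seed = 42)
  b <- sample_observed_jsfs(ex, 50, seed = 42)
  expect_identical(a$data, b$data)

  # mean of entry (1,1) over many draws ~ theta * expected within 3 SE
  draws <- vapply(1:2000, function(k) {
    sample_observed_jsfs(ex, 10, seed = k)$data[2, 2]
  }, numeric(1))
  lam <- 10 * ex$data[2, 2]
  expect_lt(abs(mean(draws) - lam), 3 * sqrt(lam / 2000))

  expect_error(sample_observed_jsfs(ex, -1), "theta_hat")
})

test_that("simulated genotype datasets pass permissive filters unchanged", {
  cfg <- sim_config("vic_no_mig", c(s = 0.5, T = 0.3), 8, 8, n_sites = 200,
                    coverage_mean = 30, coverage_sd = 2, missing_rate = 0,
                    seed = 1)
  gm <- simulate_genotype_dataset(cfg, engine = fast_engine)
  # depth and quality are far inside the pass bands: no genotype is masked
  flt <- apply_genotype_filters(gm, filter_config())
  expect_equal(flt$genotypes, gm$genotypes)
  # with the heterozygosity cap lifted, every site survives the site rules
  out <- apply_site_filters(flt, filter_config(max_obs_het = 1))
  expect_equal(nrow(out$genotypes), 200L)
})

test_that("the rebuilt JSFS matches the generating spectrum (chi-squared)", {
  cfg <- sim_config("vic_no_mig", c(s = 0.5, T = 0.5), 8, 8, n_sites = 5000,
                    missing_rate = 0, seed = 1)
  gm <- simulate_genotype_dataset(cfg, engine = fast_engine)
  expected <- attr(gm, "expected_sfs")
  sp <- build_jsfs(gm, "pop1", "pop2", 8, 8, fold = FALSE)
  un <- !expected$mask
  probs <- expected$data[un] / sum(expected$data[un])
  counts <- sp$data[un]
  keep <- probs * sum(counts) >= 5  # standard expected-count rule
  x <- counts[keep]
  p <- probs[keep]
  if (any(!keep)) {
    x <- c(x, sum(counts[!keep]))
    p <- c(p, sum(probs[!keep]))
  }
  expect_gt(stats::chisq.test(x, p = p)$p.value, 0.01)
})

test_that("identical seeds give byte-identical VCF output", {
  cfg <- sim_config("founder_nomig", c(s = 0.2, nu2 = 1, T = 0.2), 4, 4,
                    n_sites = 50, missing_rate = 0.1, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(simulate_genotype_dataset(cfg, engine = fast_engine), f1)
  write_genotype_vcf(simulate_genotype_dataset(cfg, engine = fast_engine), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("multi-SNP loci exercise the single-SNP filter", {
  cfg <- sim_config("vic_no_mig", c(s = 0.5, T = 0.3), 4, 4, n_sites = 30,
                    snps_per_locus = 3L, seed = 9)
  gm <- simulate_genotype_dataset(cfg, engine = fast_engine)
  expect_equal(length(unique(gm$locus_id)), 10L)
  out <- apply_site_filters(gm, filter_config(min_presence_R = 0))
  expect_equal(nrow(out$genotypes), 10L)
})

test_that("Q-matrix simulation reproduces profiles and feeds the filter", {
  prof <- rbind(c(1, 0, 0), c(0.6, 0.3, 0.1), c(0.45, 0.40, 0.15))
  q <- simulate_q_matrices(3, 3, prof, seed = 2)
  expect_equal(unname(unclass(q)), unname(prof))
  res <- admixture_filter(q)
  expect_true(all(c("pop1", "pop2") %in% res$kept))
  expect_true("pop3" %in% res$excluded)

  qj <- simulate_q_matrices(3, 3, prof, seed = 2, jitter_concentration = 200)
  expect_equal(unname(rowSums(qj)), rep(1, 3), tolerance = 1e-12)
  expect_false(identical(unclass(qj), unclass(q)))

  expect_error(simulate_q_matrices(2, 2, rbind(c(.6, .5), c(.5, .5))),
               "sum to 1")
})

test_that("simulation configuration is validated", {
  expect_error(sim_config("vic_no_mig", c(s = .5, T = .1), 3, 4), "even")
  expect_error(sim_config("vic_no_mig", c(s = .5, T = .1), 4, 4,
                          missing_rate = 1), "missing_rate")
  expect_error(sim_config("vic_no_mig", c(s = .5, T = .1), 4, 4,
                          theta_per_dataset = 0), "theta_per_dataset")
})
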