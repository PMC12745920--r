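test_that("delta-K reproduces the worked second-difference example", {
  means <- c(-1000, -900, -880, -875)
  trace <- data.frame(K = rep(1:4, each = 2),
                      logL = rep(means, each = 2) + c(-2, 2) / sqrt(2))
  # sd of each pair is 2
  expect_equal(as.vector(tapply(trace$logL, trace$K, sd)),
               rep(2, 4), tolerance = 1e-12)
  dk <- evanno_delta_k(trace)
  expect_equal(dk$delta_k, c(40, 7.5), tolerance = 1e-9)
  expect_equal(attr(dk, "best_k"), 2)
})

test_that("delta-K vanishes for likelihoods linear in K", {
  trace <- data.frame(K = rep(1:5, each = 3),
                      logL = rep(-100 * (1:5), each = 3) + c(-1, 0, 1))
  expect_equal(evanno_delta_k(trace)$delta_k, rep(0, 3), tolerance = 1e-9)
})

test_that("delta-K boundary and degenerate cases are handled", {
  expect_error(evanno_delta_k(data.frame(K = rep(1:2, each = 2),
                                         logL = rnorm(4))), ">= 3")
  trace <- data.frame(K = rep(1:3, each = 2), logL = rep(c(-10, -5, -4), each = 2))
  expect_warning(dk <- evanno_delta_k(trace), "infinite")
  expect_identical(dk$delta_k, Inf)
  # matches a brute-force recomputation on a random fixture
  set.seed(14)
  tr <- data.frame(K = rep(1:6, each = 10), logL = rnorm(60, -500, 20))
  dk2 <- evanno_delta_k(tr)
  ms <- tapply(tr$logL, tr$K, mean)
  sds <- tapply(tr$logL, tr$K, sd)
  brute <- abs(ms[3:6] - 2 * ms[2:5] + ms[1:4]) / sds[2:5]
  expect_equal(dk2$delta_k, as.vector(brute), tolerance = 1e-12)
})

test_that("admixture filter applies both strict thresholds", {
  q <- rbind(a = c(0.6, 0.3, 0.1),
             b = c(0.45, 0.40, 0.15),
             c = c(0.55, 0.40, 0.05),
             d = c(0.50, 0.30, 0.20))
  res <- admixture_filter(q)
  expect_equal(res$kept, "a")
  expect_setequal(res$excluded, c("b", "c", "d"))  # b: major <= 0.5;
  # c: second >= 0.35; d: major not > 0.5 (strict)

  # idempotent and row-order independent
  res2 <- admixture_filter(q[res$table$population, ])
  expect_equal(res2$kept, res$kept)
  resr <- admixture_filter(q[c(3, 1, 4, 2), ])
  expect_setequal(resr$kept, res$kept)

  expect_error(admixture_filter(rbind(c(0.7, 0.4))), "summing to 1")
})

test_that("geo-genetic groups validate on at least two of three criteria", {
  crit <- data.frame(
    population = c("p1", "p2", "p3", "p4"),
    distinct_cluster = c(TRUE, TRUE, TRUE, FALSE),
    divergent_branch = c(TRUE, TRUE, FALSE, FALSE),
    geographically_isolated = c(FALSE, FALSE, FALSE, TRUE)
  )
  groups <- list(north = c("p1", "p2"), south = "p3", island = "p4")
  out <- assign_geo_genetic_groups(crit, groups)
  expect_equal(out$validated, c(TRUE, FALSE, FALSE))
  expect_equal(out$n_criteria, c(2L, 1L, 1L))

  # (F,T,T) validates
  crit2 <- crit[1, ]
  crit2[, 2:4] <- c(FALSE, TRUE, TRUE)
  expect_true(assign_geo_genetic_groups(crit2, list(g = "p1"))$validated)

  expect_error(assign_geo_genetic_groups(crit, list(g = c("p1", "p1"))),
               "overlap")
  expect_error(assign_geo_genetic_groups(crit, list(g = "p1")), "partition")
})

test_that("isolation helper flags distant populations", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 10))
  expect_equal(unname(flag_isolated_populations(coords, 5)),
               c(FALSE, FALSE, TRUE))
})
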