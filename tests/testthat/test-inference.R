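# minimal two-cell spectra (n1 = n2 = 1; corners masked, two free entries)
two_cell <- function(v) spectrum2d(matrix(c(0, v[1], v[2], 0), 2, 2))

test_that("composite likelihood uses the analytic optimal theta", {
  cl <- composite_loglik(two_cell(c(4, 6)), two_cell(c(1, 1)))
  expect_equal(cl$theta_hat, 5)
  expect_equal(cl$loglik, 10 * log(5) - 10 - log(24 * 720), tolerance = 1e-9)

  # scaling the model spectrum is absorbed by theta_hat
  cl2 <- composite_loglik(two_cell(c(4, 6)), two_cell(c(10, 10)))
  expect_equal(cl2$loglik, cl$loglik, tolerance = 1e-12)
  expect_equal(cl2$theta_hat, 0.5)

  # theta_hat maximises the Poisson likelihood
  ll_at <- function(th) {
    M <- c(1, 1) * th
    sum(c(4, 6) * log(M) - M - lgamma(c(4, 6) + 1))
  }
  expect_gt(cl$loglik, ll_at(5 * 1.01))
  expect_gt(cl$loglik, ll_at(5 * 0.99))
})

test_that("zero model density under observed data yields -Inf with warning", {
  expect_warning(cl <- composite_loglik(two_cell(c(4, 6)), two_cell(c(0, 1))),
                 "zero density")
  expect_identical(cl$loglik, -Inf)
  bad <- spectrum2d(matrix(c(0, 1, 1, 0), 2, 2),
                    mask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_error(composite_loglik(two_cell(c(1, 2)), bad), "mask")
})

test_that("model ranking reproduces Akaike weights and the parsimony rule", {
  mk <- function(aic, k = 2) {
    structure(list(model = "m", family = "f", orientation = "AB", k = k,
                   loglik = (2 * k - aic) / 2, theta_hat = 1, aic = aic),
              class = "refugia_fit")
  }
  tab <- select_models(list(mk(100), mk(102), mk(110)))
  expect_equal(tab$akaike_weight, c(0.7275, 0.2676, 0.0049), tolerance = 5e-4)
  expect_equal(sum(tab$akaike_weight), 1)

  expect_equal(select_models(list(mk(100)))$akaike_weight, 1)

  # equal loglik: the smaller k wins by Delta AIC = 2
  f2 <- mk(2 * 2 - 2 * (-50), k = 2)
  f3 <- mk(2 * 3 - 2 * (-50), k = 3)
  tab2 <- select_models(list(k3 = f3, k2 = f2))
  expect_equal(tab2$k[1], 2L)
  expect_equal(tab2$delta_aic[2], 2)
})

test_that("the default schedule matches the staged protocol", {
  sch <- optim_schedule()
  expect_equal(sch$folds, c(3, 2, 2, 1))
  expect_equal(sch$reps, c(60, 70, 70, 80))
  expect_equal(sch$maxiters, c(10, 10, 10, 15))
  expect_error(optim_schedule(folds = c(1, 2), reps = 3, maxiters = c(1, 1)),
               "equal length")
})

test_that("optimisation from the truth never degrades the likelihood", {
  truth <- c(s = 0.3, T = 0.4)
  ex <- expected_sfs("vic_no_mig", truth, 6, 6, engine = fast_engine,
                     fold = TRUE)
  data <- sample_observed_jsfs(ex, 800, seed = 4)
  ll0 <- composite_loglik(data, ex)$loglik
  fit <- optimize_fit(data, "vic_no_mig", start = truth,
                      sched = optim_schedule(0, 4, 8),
                      engine = fast_engine, seed = 2)
  expect_gte(fit$loglik, ll0 - 1e-6)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_true(all(diff(fit$trajectory) >= 0))
})

test_that("divergence-time conversion follows N_ref = theta/(4 mu L)", {
  cc <- conversion_constants(mu = 7e-9, L = 1e6, g = 10)
  yrs <- convert_time(0.5, theta_hat = 400, cc)
  expect_equal(attr(yrs, "N_ref"), 400 / (4 * 7e-9 * 1e6), tolerance = 1e-9)
  expect_equal(as.numeric(yrs), 0.5 * 2 * 14285.714286 * 10, tolerance = 1e-6)
  expect_equal(as.numeric(convert_time(0, 400, cc)), 0)
  expect_error(conversion_constants(mu = 0, L = 1, g = 1), "positive")
})

test_that("goodness-of-fit chi-squared and coverage flags are correct", {
  best <- structure(list(model = "m", family = "f", orientation = "AB",
                         params = c(s = .5, T = .1), k = 2, loglik = 0,
                         theta_hat = 5, expected = two_cell(c(1, 1)),
                         aic = 4),
                    class = "refugia_fit")
  g <- goodness_of_fit(two_cell(c(4, 6)), best, n_sims = 50, seed = 1)
  expect_equal(g$empirical_chi2, 0.4, tolerance = 1e-12)  # (1+1)/5
  expect_length(g$sim_logliks, 50)
  expect_true(is.logical(g$loglik_inside) && is.logical(g$chi2_inside))

  # a perfectly matching dataset has chi2 = 0
  g0 <- goodness_of_fit(two_cell(c(5, 5)), best, n_sims = 10, seed = 1)
  expect_equal(g0$empirical_chi2, 0, tolerance = 1e-12)
  expect_error(goodness_of_fit(two_cell(c(4, 6)), best, n_sims = 1), "n_sims")
})

test_that("pre-LGM test matches exhaustive enumeration on tiny samples", {
  res <- test_pre_lgm(c(30, 25, 40), null_ka = 20)
  expect_equal(res$p, 0.125, tolerance = 1e-12)
  expect_equal(res$pseudomedian, 31.25, tolerance = 1e-12)

  for (seed in 1:8) {
    set.seed(seed)
    x <- round(runif(sample(3:5, 1), 5, 60), 2)
    ref <- enumerate_signed_rank(x, 20)
    got <- test_pre_lgm(x, 20)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
    expect_equal(got$pseudomedian, ref$pseudomedian, tolerance = 1e-9)
  }

  res20 <- test_pre_lgm(c(20, 20, 20))
  expect_equal(res20$p, 1)
  expect_equal(res20$pseudomedian, 20)

  frac <- test_pre_lgm(c(15, 30, 40, 50), 20)$frac_below_null
  expect_equal(frac, 0.25)
  expect_error(test_pre_lgm(c(30, 40)), ">= 3")
})
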