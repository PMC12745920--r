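#' Composite (Poisson) log-likelihood of a spectrum given a model
#'
#' The "multinomial" likelihood of an observed JSFS given a per-unit-theta
#' model spectrum, in its equivalent Poisson formulation with the analytic
#' optimum for the scale: `theta_hat = sum(D)/sum(M)` over unmasked entries,
#' and `loglik = sum(D log(theta_hat M) - theta_hat M - log Gamma(D+1))`.
#' Valid for unlinked sites (single SNP per locus).
#'
#' @param data observed `refugia_spectrum` of counts.
#' @param model_unit model `refugia_spectrum` per unit theta (same shape,
#'   same mask, same folding).
#' @return list with `loglik` and `theta_hat`.
#' @export
composite_loglik <- function(data, model_unit) {
  if (data$n1 != model_unit$n1 || data$n2 != model_unit$n2) {
    stop("data and model spectra have different shapes")
  }
  if (!identical(data$mask, model_unit$mask)) stop("mask mismatch")
  if (data$folded != model_unit$folded) stop("folded flag mismatch")
  un <- !data$mask
  D <- data$data[un]
  M <- model_unit$data[un]
  theta_hat <- sum(D) / sum(M)
  if (any(M == 0 & D > 0)) {
    warning("model assigns zero density where data are observed")
    return(list(loglik = -Inf, theta_hat = theta_hat))
  }
  lam <- theta_hat * M
  ok <- lam > 0
  ll <- sum(D[ok] * log(lam[ok]) - lam[ok] - lgamma(D[ok] + 1)) - sum(lam[!ok])
  list(loglik = ll, theta_hat = theta_hat)
}

#' Staged multi-start optimisation schedule
#'
#' The staged search protocol used for all model fits: per round, `reps`
#' replicate local searches are started from the incumbent best parameters
#' perturbed multiplicatively by `2^U(-fold, +fold)` per parameter, each
#' refined by a derivative-free simplex in log-parameter space for at most
#' `maxiters` iterations; the best replicate seeds the next round. Defaults
#' are the standard 4-round schedule: folds (3,2,2,1), reps (60,70,70,80),
#' maxiters (10,10,10,15).
#'
#' @param folds,reps,maxiters equal-length numeric vectors.
#' @export
optim_schedule <- function(folds = c(3, 2, 2, 1),
                           reps = c(60, 70, 70, 80),
                           maxiters = c(10, 10, 10, 15)) {
  if (length(reps) != length(folds) || length(maxiters) != length(folds)) {
    stop("folds, reps, maxiters must have equal length")
  }
  if (any(folds < 0)) stop("folds must be >= 0")
  structure(list(folds = folds, reps = reps, maxiters = maxiters),
            class = "refugia_schedule")
}

#' Fit one divergence model to an observed spectrum
#'
#' Maximises the composite likelihood over the model's free parameters using
#' the staged perturbation schedule. The search runs in log-parameter space
#' (all parameters are positive), clipped to box `bounds`.
#'
#' @param data observed `refugia_spectrum` (counts).
#' @param model catalog model name.
#' @param sched an [optim_schedule()].
#' @param engine an [engine_config()].
#' @param start optional named start vector; a random draw (log-uniform
#'   within bounds) is used when absent.
#' @param bounds list with named `lower` and `upper` vectors; defaults to
#'   [default_bounds()].
#' @param orientation `"AB"` fits the data as-is, `"BA"` fits the
#'   transposed spectrum (populations swapped), used to test the
#'   directionality of founder events.
#' @param seed integer seed for starting points and perturbations.
#' @return A `refugia_fit`: model, orientation, `params`, `loglik`,
#'   `theta_hat`, `k`, `aic`, the fitted unit spectrum `expected`, and the
#'   per-round best trajectory.
#' @export
optimize_fit <- function(data, model, sched = optim_schedule(),
                         engine = engine_config(), start = NULL,
                         bounds = default_bounds(model),
                         orientation = c("AB", "BA"), seed = 1L) {
  orientation <- match.arg(orientation)
  if (orientation == "BA") data <- transpose_spectrum(data)
  mod <- get_model(model)
  pn <- mod$params
  lower <- bounds$lower[pn]
  upper <- bounds$upper[pn]
  set.seed(seed)
  random_start <- is.null(start)
  if (!random_start) start <- pmin(pmax(unlist(start)[pn], lower), upper)

  n_eval <- 0L
  objective <- function(logp) {
    p <- pmin(pmax(exp(logp), lower), upper)
    names(p) <- pn
    n_eval <<- n_eval + 1L
    m <- try(expected_sfs(mod, p, data$n1, data$n2, engine = engine,
                          fold = data$folded), silent = TRUE)
    if (inherits(m, "try-error")) return(1e12)
    # parameter corners can zero out cells the data occupy; that is an
    # ordinary rejected move during search, not a user-facing warning
    ll <- suppressWarnings(composite_loglik(data, m))$loglik
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  if (random_start) {
    # incumbent = best of 25 log-uniform draws over the box,
    # so a single unlucky draw cannot doom the staged search
    best_p <- NULL
    best_nll <- Inf
    for (d in 1:25) {
      cand <- exp(stats::runif(length(pn), log(lower), log(upper)))
      names(cand) <- pn
      v <- objective(log(cand))
      if (v < best_nll) {
        best_nll <- v
        best_p <- cand
      }
    }
  } else {
    # refine the supplied start itself, so short refit schedules adapt to
    # the data instead of returning the start untouched
    best_p <- start
    best_nll <- objective(log(start))
    opt0 <- try(stats::optim(log(start), objective, method = "Nelder-Mead",
                             control = list(maxit = sched$maxiters[1])),
                silent = TRUE)
    if (!inherits(opt0, "try-error") && opt0$value < best_nll) {
      best_nll <- opt0$value
      best_p <- pmin(pmax(exp(opt0$par), lower), upper)
      names(best_p) <- pn
    }
  }
  trajectory <- numeric(0)
  for (r in seq_along(sched$folds)) {
    for (rep in seq_len(sched$reps[r])) {
      pert <- 2^stats::runif(length(pn), -sched$folds[r], sched$folds[r])
      p0 <- pmin(pmax(best_p * pert, lower), upper)
      opt <- try(stats::optim(log(p0), objective, method = "Nelder-Mead",
                              control = list(maxit = sched$maxiters[r])),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (opt$value < best_nll) {
        best_nll <- opt$value
        best_p <- pmin(pmax(exp(opt$par), lower), upper)
        names(best_p) <- pn
      }
    }
    trajectory <- c(trajectory, -best_nll)
  }
  if (!is.finite(best_nll) || best_nll >= 1e12) {
    stop("all optimisation replicates failed numerically")
  }

  expected <- expected_sfs(mod, best_p, data$n1, data$n2, engine = engine,
                           fold = data$folded)
  cl <- composite_loglik(data, expected)
  k <- length(pn)
  structure(list(model = mod$name, family = mod$family,
                 orientation = orientation, params = best_p,
                 loglik = cl$loglik, theta_hat = cl$theta_hat, k = k,
                 aic = 2 * k - 2 * cl$loglik, expected = expected,
                 trajectory = trajectory, n_eval = n_eval),
            class = "refugia_fit")
}

#' @export
print.refugia_fit <- function(x, ...) {
  cat(sprintf("%s (%s, orientation %s): loglik %.2f, theta_hat %.2f, AIC %.2f\n",
              x$model, x$family, x$orientation, x$loglik, x$theta_hat, x$aic))
  print(round(x$params, 4))
  invisible(x)
}

#' Fit a set of models (both orientations for founder models)
#'
#' Convenience wrapper running [optimize_fit()] for each requested catalog
#' model. Founder models are fitted twice, once per orientation, since the
#' source and founded populations are interchangeable hypotheses; the
#' symmetric-role vicariance models are fitted once.
#'
#' @inheritParams optimize_fit
#' @param models character vector of catalog names, or `"all"`.
#' @param orientations `"both"` (founder models in both orientations) or
#'   `"AB"` only.
#' @return list of `refugia_fit` objects.
#' @export
#' @param bounds_fn optional function(model name) returning the bounds list
#'   handed to [optimize_fit()]; defaults to [default_bounds()].
fit_model_set <- function(data, models = "all", sched = optim_schedule(),
                          engine = engine_config(), orientations = "both",
                          seed = 1L, bounds_fn = default_bounds) {
  if (identical(models, "all")) models <- names(model_catalog())
  fits <- list()
  for (m in models) {
    ors <- if (orientations == "both" && get_model(m)$family == "founder")
      c("AB", "BA") else "AB"
    for (o in ors) {
      fits[[paste(m, o, sep = ":")]] <-
        optimize_fit(data, m, sched = sched, engine = engine,
                     orientation = o, seed = seed + length(fits),
                     bounds = bounds_fn(m))
    }
  }
  fits
}

#' Rank fitted models by AIC and Akaike weights
#'
#' @param fits list of `refugia_fit` objects.
#' @return data.frame sorted by AIC with `delta_aic` and Akaike weight
#'   `akaike_weight` (`w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`).
#' @export
select_models <- function(fits) {
  if (inherits(fits, "refugia_fit")) fits <- list(fits)
  if (length(fits) < 1) stop("no fits supplied")
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    family = vapply(fits, `[[`, "", "family"),
    orientation = vapply(fits, `[[`, "", "orientation"),
    k = vapply(fits, function(f) as.integer(f$k), 0L),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    theta_hat = vapply(fits, `[[`, 0, "theta_hat"),
    aic = vapply(fits, `[[`, 0, "aic"),
    row.names = NULL
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  w <- exp(-tab$delta_aic / 2)
  tab$akaike_weight <- w / sum(w)
  tab[order(tab$aic), ]
}

#' Constants for converting diffusion times to years
#'
#' `N_ref = theta_hat / (4 mu L)` and `years = T 2 N_ref g`. The default
#' mutation rate is the Arabidopsis thaliana estimate of 7e-9 substitutions
#' per site per generation; generation time is 10 years for weakly clonal
#' and 20 years for strongly clonal perennials. `L` (total surveyed
#' sequence length behind the SNP set) has direct leverage on absolute
#' times and must be supplied.
#'
#' @param mu mutation rate per site per generation.
#' @param L surveyed sequence length (sites).
#' @param g generation time in years.
#' @export
conversion_constants <- function(mu = 7e-9, L, g = 10) {
  if (mu <= 0 || L <= 0 || g <= 0) stop("conversion constants must be positive")
  structure(list(mu = mu, L = L, g = g), class = "refugia_conversion")
}

#' Convert a model divergence time to years
#'
#' @param T_model time in units of `2 N_ref` generations.
#' @param theta_hat fitted spectrum scale (`4 N_ref mu L`).
#' @param cc a [conversion_constants()].
#' @return time in years; `N_ref` is attached as attribute.
#' @export
convert_time <- function(T_model, theta_hat, cc) {
  n_ref <- theta_hat / (4 * cc$mu * cc$L)
  out <- T_model * 2 * n_ref * cc$g
  attr(out, "N_ref") <- n_ref
  out
}

#' Parametric-bootstrap goodness of fit
#'
#' Simulates `n_sims` Poisson datasets from the fitted spectrum
#' `theta_hat x expected` and records, for each, the composite log-
#' likelihood and Pearson's chi-squared statistic `sum((D-E)^2/E)` over
#' unmasked entries (log10-transformed copies included). The empirical
#' statistics are flagged as inside/outside the central 95% of the
#' simulated distributions. With `refit = TRUE` each simulated dataset is
#' re-optimised (reduced schedule) starting at the best parameters, giving
#' percentile confidence intervals for the split fraction `s` and the
#' divergence times, and -- when `constants` are supplied -- a distribution
#' of divergence times in years with the one-sided pre-LGM Wilcoxon test.
#'
#' @param data observed `refugia_spectrum`.
#' @param best a `refugia_fit` for the retained model.
#' @param n_sims number of bootstrap simulations (default 100).
#' @param refit re-optimise each simulated dataset (slower) instead of
#'   evaluating at the fitted parameters.
#' @param sched reduced schedule used when `refit = TRUE`.
#' @param engine an [engine_config()].
#' @param constants optional [conversion_constants()] for time conversion.
#' @param lgm_ka null divergence time (ka) for the pre-LGM test.
#' @param seed integer seed.
#' @return A `refugia_gof` list; see Details.
#' @export
goodness_of_fit <- function(data, best, n_sims = 100, refit = FALSE,
                            sched = optim_schedule(folds = c(1),
                                                   reps = c(10),
                                                   maxiters = c(10)),
                            engine = engine_config(), constants = NULL,
                            lgm_ka = 20, seed = 1L) {
  if (n_sims < 2) stop("n_sims must be >= 2")
  if (best$orientation == "BA") data <- transpose_spectrum(data)
  un <- !data$mask
  M <- best$expected$data
  emp <- composite_loglik(data, best$expected)
  E_emp <- emp$theta_hat * M
  chi2_emp <- sum((data$data[un] - E_emp[un])^2 / pmax(E_emp[un], 1e-12))

  tn <- intersect(c("T", "T1", "T2"), names(best$params))
  sim_ll <- sim_chi2 <- numeric(n_sims)
  sim_par <- matrix(NA_real_, n_sims, length(best$params),
                    dimnames = list(NULL, names(best$params)))
  sim_theta <- numeric(n_sims)
  for (b in seq_len(n_sims)) {
    sim <- sample_observed_jsfs(best$expected, best$theta_hat,
                                seed = seed + 7919L * b)
    if (refit) {
      f <- optimize_fit(sim, best$model, sched = sched, engine = engine,
                        start = best$params, seed = seed + b)
      sim_ll[b] <- f$loglik
      sim_par[b, ] <- f$params
      sim_theta[b] <- f$theta_hat
      E <- f$theta_hat * f$expected$data
    } else {
      cl <- composite_loglik(sim, best$expected)
      sim_ll[b] <- cl$loglik
      sim_theta[b] <- cl$theta_hat
      E <- cl$theta_hat * best$expected$data
    }
    sim_chi2[b] <- sum((sim$data[un] - E[un])^2 / pmax(E[un], 1e-12))
  }

  qll <- stats::quantile(sim_ll, c(0.025, 0.975), names = FALSE)
  qch <- stats::quantile(sim_chi2, c(0.025, 0.975), names = FALSE)
  out <- list(
    sim_logliks = sim_ll, sim_chi2 = sim_chi2,
    sim_log10_chi2 = log10(pmax(sim_chi2, 1e-300)),
    empirical_loglik = emp$loglik, empirical_chi2 = chi2_emp,
    empirical_log10_chi2 = log10(max(chi2_emp, 1e-300)),
    loglik_inside = emp$loglik >= qll[1] && emp$loglik <= qll[2],
    chi2_inside = chi2_emp >= qch[1] && chi2_emp <= qch[2],
    theta_hats = sim_theta, refit = refit
  )
  if (refit) {
    ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
    out$s_ci <- ci(sim_par[, "s"])
    out$t_ci <- lapply(stats::setNames(tn, tn), function(v) ci(sim_par[, v]))
    out$sim_params <- sim_par
    if (!is.null(constants)) {
      t_tot <- rowSums(sim_par[, tn, drop = FALSE])
      out$times_years <- as.numeric(convert_time(t_tot, sim_theta, constants))
      lgm <- test_pre_lgm(out$times_years / 1000, null_ka = lgm_ka)
      out$p_pre_lgm <- lgm$p
      out$pseudomedian_years <- lgm$pseudomedian * 1000
      out$time_ci_years <- lgm$ci * 1000
      out$frac_post_lgm <- lgm$frac_below_null
    }
  }
  class(out) <- "refugia_gof"
  out
}

#' One-sided test that divergence predates the Last Glacial Maximum
#'
#' Wilcoxon signed-rank test of `H1: location > null_ka` applied to
#' simulated divergence times (ka), with the Hodges-Lehmann pseudomedian
#' (median of Walsh averages) and the signed-rank confidence interval.
#' Exact for `n <= 25` without ties; normal approximation with correction
#' otherwise.
#'
#' @param times_ka numeric vector (>= 3 values) of divergence times in ka.
#' @param null_ka null location, default 20 (approximate LGM age).
#' @return list: `p`, `pseudomedian`, `ci` (two-sided 95%),
#'   `frac_below_null` (share of simulated times younger than the null).
#' @export
test_pre_lgm <- function(times_ka, null_ka = 20) {
  if (length(times_ka) < 3) stop("need >= 3 simulated times")
  d <- times_ka - null_ka
  if (all(d == 0)) {
    return(list(p = 1, pseudomedian = null_ka, ci = c(null_ka, null_ka),
                frac_below_null = 0))
  }
  exact <- length(d[d != 0]) <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(
    stats::wilcox.test(times_ka, mu = null_ka, alternative = "greater",
                       conf.int = TRUE, conf.level = 0.95, exact = exact,
                       correct = TRUE)
  )
  ci2 <- suppressWarnings(
    stats::wilcox.test(times_ka, mu = null_ka, alternative = "two.sided",
                       conf.int = TRUE, conf.level = 0.95, exact = exact,
                       correct = TRUE)
  )
  list(p = unname(wt$p.value), pseudomedian = unname(wt$estimate),
       ci = unname(ci2$conf.int), frac_below_null = mean(times_ka < null_ka))
}
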