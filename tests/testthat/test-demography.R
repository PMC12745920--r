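test_that("the model catalog has nine entries with the expected structure", {
  cat <- model_catalog()
  expect_length(cat, 9L)
  fams <- vapply(cat, `[[`, "", "family")
  expect_equal(sum(fams == "vicariance"), 3L)
  expect_equal(sum(fams == "founder"), 6L)
  k <- vapply(cat, function(m) length(m$params), 0L)
  expect_equal(unname(k), c(2L, 4L, 4L, 3L, 4L, 5L, 5L, 5L, 6L))
})

test_that("founder demes start at fraction s and grow to nu2 across epochs", {
  p <- c(s = 0.2, nu2 = 1.5, M = 0.7, T1 = 0.3, T2 = 0.1, T = 0.4,
         M12 = 0.7, M21 = 0.2)
  for (m in names(Filter(function(x) x$family == "founder", model_catalog()))) {
    ep <- model_epochs(m, p)
    expect_equal(ep$nu2_0[1], 0.2)                   # starts at s
    expect_equal(ep$nu2_1[nrow(ep)], 1.5)            # ends at nu2
    expect_equal(ep$nu1_0, rep(0.8, nrow(ep)))       # source constant 1 - s
  }
  # two-epoch growth is one continuous exponential across T1 + T2
  ep <- model_epochs("founder_sec_contact_sym", p)
  expect_equal(ep$nu2_1[1], 0.2 * (1.5 / 0.2)^(0.3 / 0.4), tolerance = 1e-12)
  # migration epochs: ancient migration first, secondary contact last
  expect_equal(model_epochs("founder_anc_sym_mig", p)$m12, c(0.7, 0))
  expect_equal(model_epochs("founder_sec_contact_sym", p)$m12, c(0, 0.7))
  expect_equal(model_epochs("vic_anc_sym_mig",
                            c(s = .5, M = 1, T1 = .2, T2 = .1))$m12, c(1, 0))
})

test_that("invalid parameters are rejected", {
  expect_error(model_epochs("vic_no_mig", c(s = 1.2, T = 0.1)), "s must be")
  expect_error(model_epochs("vic_no_mig", c(s = 0.5)), "needs parameters")
  expect_error(model_epochs("founder_nomig", c(s = .2, nu2 = -1, T = .1)),
               "sizes")
  expect_error(model_epochs("nonsense", c(s = .5, T = .1)), "unknown model")
  expect_error(expected_sfs("vic_no_mig", c(s = .5, T = .1), 1, 4), ">= 2")
})

test_that("at divergence time zero the spectrum is the single-pool closed form", {
  cf <- closed_form_t0(2, 2)
  for (m in list(list("vic_no_mig", c(s = 0.5, T = 0)),
                 list("founder_nomig", c(s = 0.1, nu2 = 1, T = 0)))) {
    sp <- expected_sfs(m[[1]], m[[2]], 2, 2)
    expect_lt(max(abs(sp$data / cf - 1), na.rm = TRUE), 0.01)
  }
})

test_that("an isolated equilibrium population has entries nu/i", {
  s1 <- expected_sfs_1d(nu = 1, n = 10)
  expect_lt(max(abs(s1[2:10] * (1:9) - 1)), 0.01)
})

test_that("symmetric scenarios give transposition-symmetric spectra", {
  sp <- expected_sfs("vic_no_mig", c(s = 0.5, T = 0.3), 6, 6,
                     engine = fast_engine)
  un <- !sp$mask
  expect_lt(max(abs(sp$data - t(sp$data))[un] / sp$data[un]), 0.01)
  sp2 <- expected_sfs("vic_anc_sym_mig", c(s = 0.5, M = 1, T1 = .2, T2 = .1),
                      6, 6, engine = fast_engine)
  expect_lt(max(abs(sp2$data - t(sp2$data))[un] / sp2$data[un]), 0.01)
})

test_that("spectra vary continuously in the parameters", {
  base <- expected_sfs("vic_no_mig", c(s = 0.3, T = 0.4), 6, 6,
                       engine = fast_engine)
  bumped <- expected_sfs("vic_no_mig", c(s = 0.3 + 1e-4, T = 0.4), 6, 6,
                         engine = fast_engine)
  un <- !base$mask
  expect_lt(max(abs(bumped$data - base$data)[un]), 0.01 * max(base$data[un]))
})

test_that("folded expected spectra mask beyond the fold line", {
  sp <- expected_sfs("vic_no_mig", c(s = 0.4, T = 0.2), 4, 4,
                     engine = fast_engine, fold = TRUE)
  tot <- outer(0:4, 0:4, `+`)
  expect_true(all(sp$mask[tot > 4]))
  expect_true(all(sp$data[!sp$mask] >= 0))
})
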