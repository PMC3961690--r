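test_that("noiseless one-pKa series are recovered exactly", {
  truth <- one_pka_params(28.0, 30.5, 10.6)
  s <- sim_one_pka_titration(params = truth, noise_sd = 0, seed = 1)$series[[1]]
  fit <- fit_one_pka(s)
  expect_equal(fit$params$pka, 10.6, tolerance = 1e-6)
  expect_equal(fit$params$delta_protonated, 28.0, tolerance = 1e-6)
  expect_equal(fit$params$delta_deprotonated, 30.5, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$extrapolated)
  expect_equal(fit$dof, 19 - 3)
})

test_that("noisy one-pKa series are recovered within the asymptotic error", {
  s <- sim_one_pka_titration(10.6, n_resonances = 1,
                             amplitude_range = 2.5, noise_sd = 0.05,
                             seed = 2024)$series[[1]]
  fit <- fit_one_pka(s)
  expect_lt(abs(fit$params$pka - 10.6), 0.1)
  expect_true(is.finite(fit$stderr_pka) && fit$stderr_pka > 0)
})

test_that("degenerate series raise explicit failure states", {
  flat <- titration_series(seq(4, 13, 0.5), rep(25, 19) + 0.001)
  expect_error(fit_one_pka(flat), class = "trxpka_no_titration")
  short <- titration_series(1:5, c(1, 1.2, 1.5, 1.8, 2))
  expect_error(fit_one_pka(short), class = "trxpka_too_few_points")
  expect_error(fit_two_pka(titration_series(1:7, rep(c(1, 2), len = 7))),
               class = "trxpka_too_few_points")
})

test_that("noiseless two-pKa series are recovered exactly with ordered pKas", {
  truth <- two_pka_params(0, 1.35, 2.7, 7.6, 10.4)
  s <- sim_two_pka_titration(params = truth, ph_grid = seq(4, 13, 0.25),
                             noise_sd = 0, seed = 1)$series[[1]]
  fit <- fit_two_pka(s)
  expect_equal(fit$params$pka1, 7.6, tolerance = 1e-5)
  expect_equal(fit$params$pka2, 10.4, tolerance = 1e-5)
  expect_false(fit$nonidentifiable)
})

test_that("fitted two-pKa transitions are always ordered", {
  set.seed(31)
  for (k in 1:5) {
    p1 <- runif(1, 5, 8)
    sim <- sim_two_pka_titration(p1, p1 + runif(1, 1.5, 4),
                                 ph_grid = seq(4, 13, 0.25),
                                 amplitude_range = c(1.5, 3),
                                 noise_sd = 0.05, seed = 400 + k)
    fit <- fit_two_pka(sim$series[[1]])
    expect_lte(fit$params$pka1, fit$params$pka2)
  }
})

test_that("over-parameterized fits of one-pKa data are flagged non-identifiable", {
  s <- sim_one_pka_titration(8.5, n_resonances = 1,
                             ph_grid = seq(4, 13, 0.25),
                             noise_sd = 0.05, seed = 201)$series[[1]]
  fit <- fit_two_pka(s)
  expect_true(fit$nonidentifiable)
  # a genuine double sigmoid is not flagged
  s2 <- sim_two_pka_titration(params = two_pka_params(20, 21.35, 22.7, 7.6, 10.4),
                              ph_grid = seq(4, 13, 0.25), noise_sd = 0.05,
                              seed = 5)$series[[1]]
  expect_false(fit_two_pka(s2)$nonidentifiable)
})

test_that("F-test model selection prefers the generating model", {
  two_s <- sim_two_pka_titration(params = two_pka_params(0, 1.35, 2.7, 7.6, 10.4),
                                 ph_grid = seq(4, 13, 0.25), noise_sd = 0.05,
                                 seed = 8)$series[[1]]
  sel <- select_model(two_s)
  expect_identical(sel$model_kind, "two_pka")
  expect_gt(sel$f_statistic, stats::qf(0.95, 2, sel$fit_two$dof))

  one_s <- sim_one_pka_titration(8.5, ph_grid = seq(4, 13, 0.25),
                                 noise_sd = 0.05, seed = 101)$series[[1]]
  expect_identical(select_model(one_s)$model_kind, "one_pka")
  # limiting significance levels force each model
  expect_identical(select_model(one_s, alpha = 1)$model_kind, "two_pka")
  expect_identical(select_model(two_s, alpha = 1e-300)$model_kind, "one_pka")
})

test_that("aggregation reproduces the mean/SD/(n) convention", {
  pkas <- c(10.5, 10.6, 10.7, 10.4, 10.6, 10.8, 10.6)
  fits <- lapply(pkas, function(pk) {
    s <- sim_one_pka_titration(params = one_pka_params(28, 30.5, pk),
                               noise_sd = 0, seed = 1)$series[[1]]
    fit_one_pka(s)
  })
  est <- aggregate_pka(fits)
  expect_equal(est$mean_pka, 10.6, tolerance = 1e-6)
  expect_equal(est$sd_pka, sd(pkas), tolerance = 1e-6)
  expect_equal(est$sd_pka, 0.129, tolerance = 1e-3)
  expect_identical(est$n_resonances, 7L)
  expect_identical(format_pka_estimate(est), "10.6 ± 0.1 (7)")

  # permutation invariance
  est2 <- aggregate_pka(fits[sample(seq_along(fits))])
  expect_equal(est2$mean_pka, est$mean_pka)
  expect_equal(est2$sd_pka, est$sd_pka)

  # single fit: mean defined, SD flagged undefined
  single <- aggregate_pka(fits[[1]])
  expect_false(single$sd_defined)
  expect_identical(single$n_resonances, 1L)
})

test_that("aggregation refuses mismatched transitions", {
  one_fit <- fit_one_pka(
    sim_one_pka_titration(params = one_pka_params(28, 30.5, 10.6),
                          noise_sd = 0, seed = 1)$series[[1]]
  )
  two_fit <- fit_two_pka(
    sim_two_pka_titration(params = two_pka_params(0, 1.35, 2.7, 7.6, 10.4),
                          ph_grid = seq(4, 13, 0.25), noise_sd = 0,
                          seed = 1)$series[[1]]
  )
  expect_error(aggregate_pka(list(one_fit, two_fit)), "one-pKa")
  expect_error(aggregate_pka(one_fit, "lower"), "two-pKa")
  expect_equal(aggregate_pka(two_fit, "lower")$mean_pka, 7.6,
               tolerance = 1e-5)
  expect_equal(aggregate_pka(two_fit, "upper")$mean_pka, 10.4,
               tolerance = 1e-5)
})

test_that("one-pKa estimates are unbiased and tight over repeated noise draws", {
  truth <- 8.8
  est <- vapply(1:200, function(k) {
    s <- sim_one_pka_titration(truth, n_resonances = 1, amplitude_range = 2,
                               noise_sd = 0.05, seed = 10000 + k)$series[[1]]
    fit_one_pka(s)$params$pka
  }, numeric(1))
  expect_lt(abs(mean(est) - truth), 0.02)
  expect_lt(sd(est), 0.05)
})
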