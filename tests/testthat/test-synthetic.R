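test_that("zero noise returns the exact model curve; seeds are deterministic", {
  tt <- default_schedule()
  obs0 <- generate_observations(2.88, 2.1, 1, tt,
                                noise_model(cv_or_sd = 0, seed = 5))
  expect_equal(obs0$observed, bateman_plasma(2.88, 2.1, 1, tt))
  expect_equal(obs0$clip_rate, 0)

  a <- generate_observations(2.88, 2.1, 1, tt, noise_model(cv_or_sd = 0.05, seed = 9))
  b <- generate_observations(2.88, 2.1, 1, tt, noise_model(cv_or_sd = 0.05, seed = 9))
  d <- generate_observations(2.88, 2.1, 1, tt, noise_model(cv_or_sd = 0.05, seed = 10))
  expect_identical(a$observed, b$observed)
  expect_false(identical(a$observed, d$observed))
  expect_error(noise_model(cv_or_sd = -0.1), "nonnegative")
})

test_that("multiplicative noise is unbiased at the CLT scale", {
  tt <- default_schedule(n = 50)
  obs <- generate_observations(2.88, 2.1, 1, tt,
                               noise_model(cv_or_sd = 0.05, seed = 123))
  ratio <- obs$observed / bateman_plasma(2.88, 2.1, 1, tt) - 1
  expect_lt(abs(mean(ratio)), 3 * 0.05 / sqrt(50))
})

test_that("additive noise below zero is clipped and the rate reported", {
  tt <- default_schedule(n = 40)
  obs <- generate_observations(2.88, 2.1, 1, tt,
                               noise_model("additive_gaussian", 0.5, seed = 2))
  expect_true(all(obs$observed >= 0))
  expect_gt(obs$clip_rate, 0)
})

test_that("noise-free data identifies the true rates to machine-level accuracy", {
  obs <- generate_observations(2.88, 2.1, 1, default_schedule(),
                               noise_model(cv_or_sd = 0, seed = 1))
  fit <- fit_bateman(obs)
  expect_true(fit$converged)
  expect_lt(fit$relative_errors[["k_gi"]], 1e-6)
  expect_lt(fit$relative_errors[["k_plasma"]], 1e-6)
})

test_that("rate exchangeability is resolved to the ordered pair", {
  tt <- default_schedule(n = 40)
  fwd <- generate_observations(2.88, 2.1, 1, tt, noise_model(cv_or_sd = 0, seed = 1))
  swp <- generate_observations(2.1, 2.88, 1, tt, noise_model(cv_or_sd = 0, seed = 1))
  f1 <- fit_bateman(fwd, fit_c0 = TRUE)
  f2 <- fit_bateman(swp, fit_c0 = TRUE)
  expect_true(f1$converged && f2$converged)
  expect_gte(f1$k_gi, f1$k_plasma)
  expect_gte(f2$k_gi, f2$k_plasma)
  expect_equal(f2$k_gi, f1$k_gi, tolerance = 1e-4)
  expect_equal(f2$k_plasma, f1$k_plasma, tolerance = 1e-4)
  # swapped truth implies the swapped amplitude under the exact identity
  expect_equal(f2$c0, 2.1 / 2.88, tolerance = 1e-4)
})

test_that("degenerate flat data does not yield a spurious converged fit", {
  flat <- data.frame(time = 1:10, observed = rep(0.5, 10))
  fit <- fit_bateman(flat, c0 = 1)
  expect_false(isTRUE(fit$converged) &&
                 all(is.finite(c(fit$k_gi, fit$k_plasma))) &&
                 fit$objective < 1e-6)
  expect_error(fit_bateman(flat[1:3, ]), "at least 4")
})

test_that("estimator error shrinks monotonically as noise vanishes", {
  med_err <- vapply(c(0.2, 0.05, 0.01), function(cv) {
    rs <- recovery_study(2.88, 2.1, times = default_schedule(n = 40),
                         cv = cv, n_replicates = 30, seed = 400)
    stats::median(rs$rel_err_k_gi + rs$rel_err_k_plasma, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})
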