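test_that("RK4 reproduces exponential decay and is fourth-order accurate", {
  deriv <- function(t, s) -s
  res <- rk4_integrate(deriv, 1, 0, 1, 0.01)
  expect_equal(res$states[nrow(res$states), 1], exp(-1), tolerance = 1e-8)

  err_at <- function(dt) {
    r <- rk4_integrate(deriv, 1, 0, 1, dt)
    abs(r$states[nrow(r$states), 1] - exp(-1))
  }
  ratio <- err_at(0.02) / err_at(0.01)
  expect_gt(ratio, 12)   # halving dt cuts the error ~16x
  expect_lt(ratio, 20)
})

test_that("RK4 agrees with deSolve on the dosed two-compartment system", {
  reg <- dose_regimen(1, 6, pulse_width = 0.5)
  kg <- 2 * log(2); kp <- log(2) / 1.6
  deriv <- function(t, s) c(dose_train(reg, t) - kg * s[1], kg * s[1] - kp * s[2])
  mine <- rk4_integrate(deriv, c(0, 0), 0, 24, 0.01)
  ds <- deSolve::ode(c(x = 0, y = 0), mine$times,
                     function(t, s, p) list(deriv(t, s)), NULL, method = "rk4")
  expect_lt(max(abs(mine$states - ds[, 2:3])), 1e-10)
})

test_that("zero dose gives an identically zero trajectory and an empty cycle summary", {
  cmp <- fixture_compounds()[["NC"]]
  reg <- dose_regimen(0, 6)
  st <- simulate_longrange(cmp, reg, horizon = 60)
  expect_true(all(st$gi == 0) && all(st$plasma == 0))
  mt <- limit_cycle_metrics(st, reg, burn_in_cycles = 2)
  expect_false(mt$detected)
  expect_true(is.na(mt$detected_period))
})

test_that("dose input integrates to amount x scale per period for both shapes", {
  reg <- dose_regimen(2, 6, pulse_width = 0.5, dissolution_scale = 1 / 12)
  tt <- seq(0, 24, by = 1e-3)
  integral <- sum(dose_train(reg, tt)) * 1e-3
  expect_equal(integral, 4 * 2 / 12, tolerance = 1e-2)
  bol <- dose_regimen(2, 6, pulse_shape = "bolus", dissolution_scale = 1 / 12)
  expect_equal(dose_train(bol, tt), rep(0, length(tt)))
})

test_that("bolus dosing is the narrow-pulse limit of rectangular dosing", {
  cmp <- fixture_compounds()[["NC"]]
  bol <- simulate_longrange(cmp, dose_regimen(1, 6, pulse_shape = "bolus"),
                            horizon = 30, dt = 0.005)
  sup <- vapply(c(0.5, 0.1, 0.02), function(w) {
    rect <- simulate_longrange(cmp, dose_regimen(1, 6, pulse_width = w),
                               horizon = 30, dt = 0.005)
    max(abs(rect$plasma - bol$plasma))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))  # shrinking width converges to the bolus
})

test_that("trajectories superpose and stay nonnegative (linear dosing)", {
  cmp <- fixture_compounds()[["NC"]]
  r1 <- dose_regimen(1, 6, pulse_width = 0.5)
  r2 <- dose_regimen(2.5, 6, pulse_width = 0.5)
  r3 <- dose_regimen(3.5, 6, pulse_width = 0.5)
  s1 <- simulate_longrange(cmp, r1, horizon = 36)
  s2 <- simulate_longrange(cmp, r2, horizon = 36)
  s3 <- simulate_longrange(cmp, r3, horizon = 36)
  expect_lt(max(abs(s1$plasma + s2$plasma - s3$plasma)), 1e-8)
  expect_lt(max(abs(s1$gi + s2$gi - s3$gi)), 1e-8)
  expect_gte(min(s3$gi, s3$plasma), 0)
})

test_that("detected limit-cycle period equals the dosing period and cycles converge", {
  cmp <- fixture_compounds()[["NC"]]
  reg <- dose_regimen(0.49, 6, pulse_width = 0.5, dissolution_scale = 1 / 12)
  st <- simulate_longrange(cmp, reg)
  mt <- limit_cycle_metrics(st, reg)
  expect_true(mt$detected)
  expect_equal(mt$detected_period, 6, tolerance = 0.01 / 6)
  expect_lt(mt$convergence_ratio, 1e-3)
  # doubling the dose doubles the limit-cycle plasma peak
  st2 <- simulate_longrange(cmp, dose_regimen(0.98, 6, pulse_width = 0.5,
                                              dissolution_scale = 1 / 12))
  mt2 <- limit_cycle_metrics(st2, reg)
  expect_equal(mt2$peak_plasma / mt$peak_plasma, 2, tolerance = 1e-6)
})

test_that("asymptotic periodicity: one period apart, the plasma series repeats", {
  cmp <- fixture_compounds()[["NC"]]
  reg <- dose_regimen(1, 6, pulse_width = 0.5)
  st <- simulate_longrange(cmp, reg, horizon = 90)
  per <- round(6 / st$dt)
  after <- st$times >= 72 & st$times <= 84
  shifted <- which(after) + per
  gap <- max(abs(st$plasma[after] - st$plasma[shifted]))
  expect_lt(gap / max(st$plasma), 1e-6)
})

test_that("limit-cycle mean plasma level matches the analytic dose balance (bolus)", {
  cmp <- fixture_compounds()[["NC/HPbCD"]]
  reg <- dose_regimen(0.49, 24, pulse_shape = "bolus")
  st <- simulate_longrange(cmp, reg, horizon = 15 * 24)
  k_plasma <- log(2) / (cmp$t_half_plasma / 60)
  last <- st$times >= 13 * 24 & st$times < 14 * 24
  mean_y <- mean(st$plasma[last])
  expect_equal(mean_y, (0.49 / 24) / k_plasma, tolerance = 0.01)
})

test_that("steps coarser than the fastest timescale are warned about or refused", {
  cmp <- fixture_compounds()[["NC"]]
  reg <- dose_regimen(1, 6)
  expect_error(simulate_longrange(cmp, reg, dt = 1), "timescale")
  expect_warning(simulate_longrange(cmp, reg, horizon = 30, dt = 0.1),
                 "coarsely")
  expect_error(simulate_longrange(cmp, reg, horizon = 12), "5 dose periods")
})
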