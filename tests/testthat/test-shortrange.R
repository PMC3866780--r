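test_that("matrix-exponential solver matches scalar decay and total conversion", {
  sys1 <- linear_compartment_system(matrix(-0.7, 1, 1), 1, labels = "c")
  tr <- solve_linear_system(sys1, seq(0, 10, by = 0.5))
  expect_equal(tr$c, exp(-0.7 * tr$time), tolerance = 1e-12)

  # NC chain: everything ends up as metabolite
  sys <- shortrange_system(23.1, 7.2, c0 = 1)
  tr <- solve_linear_system(sys, c(0, 1, 5, 50))
  last <- nrow(tr)
  expect_lt(tr$gi[last], 1e-12)
  expect_lt(tr$plasma[last], 1e-12)
  expect_equal(tr$metabolite[last], 1, tolerance = 1e-10)
})

test_that("solver construction rejects malformed systems", {
  expect_error(linear_compartment_system(matrix(1, 2, 3), c(1, 0)), "square")
  expect_error(linear_compartment_system(matrix(-1, 2, 2) + diag(0.5, 2), c(1, 0, 0)),
               "length")
  A <- matrix(c(-1, -0.1, 1, -1), 2, 2)  # negative off-diagonal
  expect_error(linear_compartment_system(A, c(1, 0)), "nonnegative")
  A2 <- matrix(c(-1, 2, 0, -1), 2, 2)    # column sum > 0 (mass creation)
  expect_error(linear_compartment_system(A2, c(1, 0)), "column sums")
})

test_that("matrix exponential agrees with an independent RK4 oracle", {
  cmp <- fixture_compounds()[["NC/HPbCD"]]
  sys <- shortrange_system(2.88, 2.1)
  dt <- 1e-3
  orc <- rk4_linear_oracle(sys$rate_matrix, sys$initial, 30, dt)
  tr <- solve_linear_system(sys, orc$times)
  dev <- max(abs(as.matrix(tr[, -1]) - orc$states))
  expect_lt(dev, 1e-6)
})

test_that("mass is conserved and species stay nonnegative across parameter sets", {
  set.seed(7)
  times <- seq(0, 30, by = 0.1)
  for (i in 1:20) {
    kg <- runif(1, 0.05, 25)
    kp <- runif(1, 0.05, 25)
    c0 <- runif(1, 0.1, 10)
    tr <- solve_linear_system(shortrange_system(kg, kp, c0), times)
    total <- tr$gi + tr$plasma + tr$metabolite
    expect_lt(max(abs(total - c0)), 1e-8)
    expect_gt(min(tr$gi, tr$plasma, tr$metabolite), -1e-10)
  }
})

test_that("closed-form plasma curve handles boundaries and the equal-rate limit", {
  expect_equal(bateman_plasma(2.88, 2.1, 1, 0), 0)
  expect_equal(bateman_plasma(1, 1, 1, 1), exp(-1))
  expect_error(bateman_plasma(1, 1, 1, -0.5), "nonnegative")
  # continuity as k_plasma -> k_gi
  k <- 2
  t <- seq(0.1, 5, by = 0.1)
  near <- bateman_plasma(k, k * (1 + 1e-6), 1, t)
  lim <- k * t * exp(-k * t)
  expect_lt(max(abs(near - lim)), 1e-6)
})

test_that("closed form, matrix exponential and RK4 agree on a dense grid", {
  times <- seq(0, 30, length.out = 1000)
  for (nm in names(fixture_compounds())) {
    cmp <- fixture_compounds()[[nm]]
    rep <- cmp$reported
    sys <- shortrange_system(rep$k_gi_display, rep$k_plasma_display)
    tr <- solve_linear_system(sys, times)
    cf <- bateman_plasma(rep$k_gi_display, rep$k_plasma_display, 1, times)
    expect_lt(max(abs(tr$plasma - cf)) / max(cf), 1e-9)
  }
})

test_that("analytic peak matches a dense-grid maximiser for random rate pairs", {
  set.seed(11)
  for (i in 1:100) {
    kg <- runif(1, 0.1, 20)
    kp <- runif(1, 0.1, 20)
    pk <- bateman_peak(kg, kp, 1)
    grid <- seq(1e-4, 10 / min(kg, kp), length.out = 20000)
    cb <- bateman_plasma(kg, kp, 1, grid)
    step <- grid[2] - grid[1]
    expect_lt(abs(pk$tmax - grid[which.max(cb)]), step + 1e-12)
    expect_lte(max(cb), pk$cmax + 1e-12)  # grid never beats the analytic peak
    expect_lt(pk$cmax - max(cb), 1e-4)  # grid resolution, not solver error
    expect_lte(pk$cmax, 1)  # bounded by the initial load
  }
  # degenerate equal-rate limit: tmax = 1/k
  expect_equal(bateman_peak(3, 3, 1)$tmax, 1 / 3)
})

test_that("metabolite fraction enforces conservation and clips roundoff", {
  expect_equal(metabolite_fraction(1, 0, 1), 0)
  expect_equal(metabolite_fraction(0, 0, 1), 1)
  expect_equal(metabolite_fraction(0.6, 0.4 + 1e-9, 1), 0)
  expect_error(metabolite_fraction(0.8, 0.4, 1), "exceeds")
})

test_that("hydrophobic adjustment scales the GI load and applies the 2.5 factor per strategy", {
  sys <- shortrange_system(5.28, 1.56)
  id <- apply_hydrophobic_adjustment(sys, ratio = 1, plasma_factor = 1)
  expect_equal(id$initial, sys$initial)
  expect_equal(id$rate_matrix, sys$rate_matrix)

  adj <- apply_hydrophobic_adjustment(sys, ratio = 4.38)
  expect_equal(adj$initial[1], 1 / 4.38, tolerance = 1e-12)
  expect_equal(attr(adj, "plasma_output_factor"), 2.5)
  expect_equal(adj$rate_matrix, sys$rate_matrix)  # rates untouched

  slow <- apply_hydrophobic_adjustment(sys, 4.38, strategy = "slow_elimination")
  expect_equal(attr(slow, "plasma_output_factor"), 1)
  expect_equal(slow$rate_matrix[3, 2], 1.56 / 2.5)
  expect_equal(sum(slow$rate_matrix[, 2]), 0)  # column still conservative

  expect_error(apply_hydrophobic_adjustment(sys, 4.38, strategy = "bogus"))
})

test_that("compound trajectories carry the adjustment metadata", {
  cmps <- fixture_compounds()
  tr <- shortrange_trajectory(cmps[["NC/TAbCD"]], cmps, t_end = 5, dt = 0.05)
  expect_equal(attr(tr, "strategy"), "output_scale")
  expect_equal(attr(tr, "plasma_output_factor"), 2.5)
  expect_equal(tr$plasma, attr(tr, "plasma_raw") * 2.5)
  # conservation holds for the raw (unscaled) series
  total <- tr$gi + attr(tr, "plasma_raw") + tr$metabolite
  expect_lt(max(abs(total - 1 / 4.375)), 1e-8)
})
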