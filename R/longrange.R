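#' Periodic oral dose regimen
#'
#' A train of oral doses: `dose_amount` (ug/mL concentration-equivalent)
#' delivered every `period` hours, either as an instantaneous bolus into the
#' GI pool or spread uniformly over `pulse_width` hours (rectangular pulse).
#' `dissolution_scale` multiplies the delivered amount; for a formulation
#' dissolving `f`-fold slower than the fastest one it is `1/f` (see
#' [dissolution_fold()]).
#'
#' @param dose_amount Dose per administration (ug/mL), >= 0.
#' @param period Dosing interval, hours.
#' @param pulse_shape `"rectangular"` (default) or `"bolus"`.
#' @param pulse_width Rectangular pulse duration, hours; must be < period.
#' @param dissolution_scale Multiplicative dose scaling, > 0.
#' @return Object of class `pk_regimen`.
#' @export
dose_regimen <- function(dose_amount, period,
                         pulse_shape = c("rectangular", "bolus"),
                         pulse_width = 0.5, dissolution_scale = 1) {
  assert_nonnegative(dose_amount, "dose_amount")
  assert_positive(period, "period")
  assert_positive(dissolution_scale, "dissolution_scale")
  pulse_shape <- match.arg(pulse_shape)
  if (pulse_shape == "rectangular") {
    assert_positive(pulse_width, "pulse_width")
    if (pulse_width >= period) {
      stop("pulse_width must be smaller than the dosing period", call. = FALSE)
    }
  }
  structure(
    list(dose_amount = dose_amount, period = period, pulse_shape = pulse_shape,
         pulse_width = pulse_width, dissolution_scale = dissolution_scale),
    class = "pk_regimen"
  )
}

#' Dose input rate of a regimen at time t
#'
#' Rectangular pulses deliver `dose_amount * dissolution_scale / pulse_width`
#' during each pulse window and zero otherwise, so the input integrates to
#' `dose_amount * dissolution_scale` per period. Bolus doses are instantaneous
#' state increments handled by the integrator, so the continuous rate is zero.
#'
#' @param regimen A `pk_regimen`.
#' @param t Time(s) in hours, >= 0.
#' @return Dose rate(s), ug/mL per hour.
#' @export
dose_train <- function(regimen, t) {
  stopifnot(inherits(regimen, "pk_regimen"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (regimen$pulse_shape == "bolus" || regimen$dose_amount == 0) {
    return(rep(0, length(t)))
  }
  rate <- regimen$dose_amount * regimen$dissolution_scale / regimen$pulse_width
  phase <- t %% regimen$period
  ifelse(phase < regimen$pulse_width, rate, 0)
}

#' Classical fixed-step fourth-order Runge-Kutta integration
#'
#' Integrates `ds/dt = deriv(t, s)` from `t0` to `t1` on a uniform grid,
#' optionally applying instantaneous state jumps (bolus doses) at grid-aligned
#' times. Jumps are applied at the start of the step whose grid time is
#' nearest the requested jump time.
#'
#' @param deriv Function `(t, state) -> dstate/dt`.
#' @param state0 Initial state vector.
#' @param t0,t1 Integration span; `t1 > t0`.
#' @param dt Step size, > 0.
#' @param jumps Optional data.frame with columns `time`, `index`, `amount`.
#' @return List with `times` and `states` (matrix, one row per grid time).
#' @export
rk4_integrate <- function(deriv, state0, t0, t1, dt, jumps = NULL) {
  assert_positive(dt, "dt")
  if (t1 <= t0) stop("t1 must exceed t0", call. = FALSE)
  n_steps <- ceiling((t1 - t0) / dt - 1e-9)
  times <- t0 + dt * (0:n_steps)
  m <- length(state0)
  states <- matrix(NA_real_, n_steps + 1L, m)
  jump_at <- vector("list", n_steps + 1L)
  if (!is.null(jumps) && nrow(jumps) > 0) {
    idx <- pmin(pmax(round((jumps$time - t0) / dt) + 1L, 1L), n_steps + 1L)
    for (r in seq_len(nrow(jumps))) {
      jump_at[[idx[r]]] <- rbind(jump_at[[idx[r]]], jumps[r, , drop = FALSE])
    }
  }
  s <- as.numeric(state0)
  for (i in seq_len(n_steps + 1L)) {
    jl <- jump_at[[i]]
    if (!is.null(jl)) {
      for (r in seq_len(nrow(jl))) {
        s[jl$index[r]] <- s[jl$index[r]] + jl$amount[r]
      }
    }
    states[i, ] <- s
    if (!all(is.finite(s))) {
      stop(sprintf("non-finite state at t = %.6g", times[i]), call. = FALSE)
    }
    if (i <= n_steps) {
      t <- times[i]
      k1 <- deriv(t, s)
      k2 <- deriv(t + dt / 2, s + dt / 2 * k1)
      k3 <- deriv(t + dt / 2, s + dt / 2 * k2)
      k4 <- deriv(t + dt, s + dt * k3)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  list(times = times, states = states)
}

#' Long-range GI/plasma dynamics under periodic dosing
#'
#' Integrates the dosage-driven two-compartment system
#' `dx/dt = D(t) * DR - k_gi x`, `dy/dt = k_gi x - k_plasma y`
#' with `k = ln2 / t1/2` in h^-1 and `x(0) = y(0) = 0`, by fixed-step RK4.
#'
#' @param compound A [pk_compound] (half-lives in minutes; converted to h).
#' @param regimen A `pk_regimen`.
#' @param horizon Simulation span in hours; must cover at least 5 dose
#'   periods. Default 15 periods.
#' @param dt RK4 step, hours (default 0.01). A step within a tenth of the
#'   fastest kinetic timescale triggers a warning; a step at or beyond that
#'   timescale is refused.
#' @return Object of class `pk_longrange`: list with `times` (h), `gi`,
#'   `plasma` vectors, plus the compound name, regimen and step used.
#' @export
simulate_longrange <- function(compound, regimen, horizon = NULL, dt = 0.01) {
  stopifnot(inherits(compound, "pk_compound"), inherits(regimen, "pk_regimen"))
  k_gi <- log(2) / (compound$t_half_gi / 60)      # h^-1
  k_plasma <- log(2) / (compound$t_half_plasma / 60)
  if (is.null(horizon)) horizon <- 15 * regimen$period
  if (horizon < 5 * regimen$period) {
    stop("horizon must cover at least 5 dose periods", call. = FALSE)
  }
  ts_fast <- 1 / max(k_gi, k_plasma)
  if (dt >= ts_fast) {
    stop(sprintf("dt = %.3g h is not below the fastest kinetic timescale (%.3g h)",
                 dt, ts_fast), call. = FALSE)
  }
  if (dt >= ts_fast / 10) {
    warning(sprintf("dt = %.3g h resolves the fastest timescale (%.3g h) coarsely",
                    dt, ts_fast), call. = FALSE)
  }
  deriv <- function(t, s) {
    c(dose_train(regimen, t) - k_gi * s[1], k_gi * s[1] - k_plasma * s[2])
  }
  jumps <- NULL
  if (regimen$pulse_shape == "bolus" && regimen$dose_amount > 0) {
    dose_times <- seq(0, horizon, by = regimen$period)
    jumps <- data.frame(time = dose_times, index = 1L,
                        amount = regimen$dose_amount * regimen$dissolution_scale)
  }
  res <- rk4_integrate(deriv, c(0, 0), 0, horizon, dt, jumps = jumps)
  structure(
    list(times = res$times, gi = res$states[, 1], plasma = res$states[, 2],
         compound = compound$name, regimen = regimen, dt = dt,
         k_gi = k_gi, k_plasma = k_plasma),
    class = "pk_longrange"
  )
}

#' Limit-cycle summary of a long-range simulation
#'
#' After discarding `burn_in_cycles` dosing periods, locates local maxima of
#' the plasma series; the detected period is the median peak-to-peak spacing
#' and the convergence ratio is the relative change between the last two peak
#' heights. Returns an empty-summary sentinel (`detected = FALSE`) when no
#' peaks exist (e.g. zero dose).
#'
#' @param state A `pk_longrange`.
#' @param regimen The dosing regimen used (for the burn-in clock).
#' @param burn_in_cycles Number of initial cycles to discard (default 10).
#' @return List of class `pk_limit_cycle`: `detected`, `detected_period` (h),
#'   `peak_gi`, `peak_plasma`, `convergence_ratio`.
#' @export
limit_cycle_metrics <- function(state, regimen, burn_in_cycles = 10) {
  stopifnot(inherits(state, "pk_longrange"), inherits(regimen, "pk_regimen"))
  span <- max(state$times)
  if (span < (burn_in_cycles + 2) * regimen$period) {
    stop("trajectory must span at least burn_in + 2 dose periods",
         call. = FALSE)
  }
  keep <- state$times >= burn_in_cycles * regimen$period
  t <- state$times[keep]
  y <- state$plasma[keep]
  x <- state$gi[keep]
  n <- length(y)
  empty <- structure(
    list(detected = FALSE, detected_period = NA_real_, peak_gi = NA_real_,
         peak_plasma = NA_real_, convergence_ratio = NA_real_),
    class = "pk_limit_cycle"
  )
  if (n < 3 || max(y) <= 0) return(empty)
  i <- 2:(n - 1)
  is_peak <- y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > 0.1 * max(y)
  pk <- i[is_peak]
  if (length(pk) < 2) return(empty)
  peaks <- y[pk]
  last <- length(peaks)
  structure(
    list(
      detected = TRUE,
      detected_period = stats::median(diff(t[pk])),
      peak_gi = max(x),
      peak_plasma = peaks[last],
      convergence_ratio = abs(peaks[last] - peaks[last - 1]) / peaks[last]
    ),
    class = "pk_limit_cycle"
  )
}
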