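#' Linear compartment system
#'
#' A system `dC/dt = A C` of coupled first-order transfers. Off-diagonal
#' entries of `A` are nonnegative transfer rates; each column sums to at most
#' zero (mass leaves a compartment no faster than it is passed on), so a
#' closed chain conserves total mass.
#'
#' @param rate_matrix Square numeric matrix `A` (min^-1).
#' @param initial Initial concentration vector (ng/mL).
#' @param labels Compartment names; defaults to matrix dimnames or `C1..Cn`.
#' @return Object of class `pk_system`.
#' @export
linear_compartment_system <- function(rate_matrix, initial, labels = NULL) {
  if (!is.matrix(rate_matrix) || nrow(rate_matrix) != ncol(rate_matrix)) {
    stop("rate_matrix must be a square matrix", call. = FALSE)
  }
  n <- nrow(rate_matrix)
  if (length(initial) != n) {
    stop("initial concentration vector length must match matrix dimension",
         call. = FALSE)
  }
  off <- rate_matrix
  diag(off) <- 0
  if (any(off < 0)) {
    stop("off-diagonal transfer rates must be nonnegative", call. = FALSE)
  }
  if (any(colSums(rate_matrix) > 1e-10)) {
    stop("column sums of the rate matrix must be <= 0", call. = FALSE)
  }
  if (is.null(labels)) labels <- colnames(rate_matrix) %||% paste0("C", seq_len(n))
  structure(
    list(rate_matrix = unname(rate_matrix), initial = as.numeric(initial),
         labels = labels),
    class = "pk_system"
  )
}

#' Three-compartment absorption chain GI -> plasma -> metabolite
#'
#' The irreversible first-order scheme: drug (or complex) leaves the GI pool
#' at `k_gi`, appears in plasma, and is eliminated to the metabolite pool at
#' `k_plasma`. Columns of the rate matrix sum to zero, so total concentration
#' is conserved at the initial GI load `c0`.
#'
#' @param k_gi,k_plasma First-order rates (min^-1 magnitudes).
#' @param c0 Initial GI concentration, ng/mL (default 1.0).
#' @return A `pk_system` with compartments `gi`, `plasma`, `metabolite`.
#' @export
shortrange_system <- function(k_gi, k_plasma, c0 = 1.0) {
  assert_positive(k_gi, "k_gi")
  assert_positive(k_plasma, "k_plasma")
  assert_positive(c0, "c0")
  A <- matrix(c(-k_gi, 0, 0,
                k_gi, -k_plasma, 0,
                0, k_plasma, 0),
              nrow = 3, byrow = TRUE)
  linear_compartment_system(A, c(c0, 0, 0),
                            labels = c("gi", "plasma", "metabolite"))
}

# exp(M) by scaling-and-squaring with a Taylor series run to machine
# precision; fallback path for defective (non-diagonalizable) rate matrices.
expm_taylor <- function(M) {
  n <- nrow(M)
  nrm <- max(abs(M))
  j <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0
  Ms <- M / 2^j
  E <- diag(n)
  term <- diag(n)
  for (i in 1:40) {
    term <- term %*% Ms / i
    E <- E + term
    if (max(abs(term)) < 1e-18 * max(abs(E))) break
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

#' Solve a linear compartment system by matrix exponential
#'
#' Evaluates `C(t) = exp(A t) C(0)` at each requested time, using an
#' eigendecomposition of `A` when it is well conditioned and a
#' scaling-and-squaring series otherwise.
#'
#' @param system A `pk_system`.
#' @param times Nonnegative, strictly increasing time grid (minutes).
#' @return data.frame of class `pk_trajectory`: column `time` plus one column
#'   per compartment label. Attributes record `c0_total` (initial mass) and
#'   any plasma output-scale factor set by [apply_hydrophobic_adjustment()].
#' @export
solve_linear_system <- function(system, times) {
  stopifnot(inherits(system, "pk_system"))
  assert_nonnegative(times, "times")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  A <- system$rate_matrix
  c0 <- system$initial
  eg <- eigen(A)
  V <- eg$vectors
  rc <- tryCatch(rcond(Re(V)), error = function(e) 0)
  if (is.finite(rc) && rc > 1e-8) {
    coef <- solve(V, c0)
    # n x T matrix of solutions; eigenvalues may come out complex-typed
    sol <- V %*% (exp(outer(eg$values, times)) * coef)
    if (max(abs(Im(sol))) > 1e-8 * max(abs(Re(sol)), 1)) {
      stop("unexpected complex solution for a real compartment system",
           call. = FALSE)
    }
    sol <- Re(sol)
  } else {
    sol <- vapply(times, function(t) expm_taylor(A * t) %*% c0,
                  numeric(length(c0)))
  }
  out <- data.frame(time = times, t(sol))
  names(out) <- c("time", system$labels)
  class(out) <- c("pk_trajectory", "data.frame")
  attr(out, "c0_total") <- sum(c0)
  attr(out, "plasma_output_factor") <- attr(system, "plasma_output_factor") %||% 1
  attr(out, "strategy") <- attr(system, "strategy") %||% "none"
  out
}

#' Closed-form plasma concentration (Bateman function)
#'
#' Solution of `dCA/dt = -kGI CA`, `dCB/dt = kGI CA - kPlasma CB` with
#' `CA(0) = c0`, `CB(0) = 0`:
#' `CB(t) = c0 kGI/(kPlasma - kGI) (e^{-kGI t} - e^{-kPlasma t})`,
#' with the degenerate equal-rate limit `c0 k t e^{-k t}`.
#'
#' @param k_gi,k_plasma Absorption and elimination rates (min^-1).
#' @param c0 Initial GI concentration (ng/mL).
#' @param t Time(s), minutes; must be nonnegative.
#' @return Plasma concentration(s), ng/mL.
#' @export
bateman_plasma <- function(k_gi, k_plasma, c0, t) {
  assert_positive(k_gi, "k_gi")
  assert_positive(k_plasma, "k_plasma")
  assert_positive(c0, "c0")
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (abs(k_gi - k_plasma) <= 1e-12 * max(k_gi, k_plasma)) {
    k <- (k_gi + k_plasma) / 2
    return(c0 * k * t * exp(-k * t))
  }
  c0 * k_gi / (k_plasma - k_gi) * (exp(-k_gi * t) - exp(-k_plasma * t))
}

#' Analytic plasma peak of the absorption chain
#'
#' `Tmax = ln(kGI/kPlasma)/(kGI - kPlasma)` (limit `1/k` when equal);
#' `Cmax = CB(Tmax)`. `plasma_factor` applies an output-scale factor to the
#' reported concentration (used by the hydrophobic-adjustment strategy).
#'
#' @inheritParams bateman_plasma
#' @param plasma_factor Multiplier on the reported peak concentration.
#' @return List of class `pk_peak` with `tmax` (min) and `cmax` (ng/mL).
#' @export
bateman_peak <- function(k_gi, k_plasma, c0 = 1.0, plasma_factor = 1) {
  assert_positive(k_gi, "k_gi")
  assert_positive(k_plasma, "k_plasma")
  assert_positive(c0, "c0")
  assert_positive(plasma_factor, "plasma_factor")
  tmax <- if (abs(k_gi - k_plasma) <= 1e-12 * max(k_gi, k_plasma)) {
    2 / (k_gi + k_plasma)
  } else {
    log(k_gi / k_plasma) / (k_gi - k_plasma)
  }
  cmax <- bateman_plasma(k_gi, k_plasma, c0, tmax) * plasma_factor
  structure(list(tmax = tmax, cmax = cmax), class = "pk_peak")
}

#' Metabolite concentration by conservation
#'
#' `CC(t) = c0 - CA(t) - CB(t)`, clipped to zero within `tol`; sums exceeding
#' `c0` beyond `tol` indicate an inconsistent input and raise an error.
#'
#' @param c_a,c_b GI and plasma concentrations (ng/mL, vectorised).
#' @param c0 Total initial concentration (ng/mL).
#' @param tol Consistency/clipping tolerance.
#' @return Metabolite concentration(s), ng/mL.
#' @export
metabolite_fraction <- function(c_a, c_b, c0, tol = 1e-8) {
  assert_positive(c0, "c0")
  s <- c_a + c_b
  if (any(s > c0 + tol)) {
    stop("c_a + c_b exceeds the total initial concentration beyond tolerance",
         call. = FALSE)
  }
  cc <- c0 - s
  cc[cc < 0 & cc >= -tol] <- 0
  cc
}

#' Slow-release adjustment for a hydrophobic complex
#'
#' The hydrophobic complex dissolves far more slowly than the free drug; its
#' initial GI load is divided by the GI-rate ratio (see
#' [hydrophobic_initial_scaling()]), and its reported plasma level carries an
#' additional factor whose mechanistic placement is ambiguous in the source
#' analysis. Two readings are provided: `"output_scale"` (default) multiplies
#' the reported plasma series/peak by `plasma_factor`; `"slow_elimination"`
#' divides the plasma elimination rate by it. The choice is recorded on the
#' returned system and propagated to trajectory metadata.
#'
#' @param system A `pk_system` from [shortrange_system()].
#' @param ratio Initial-concentration scaling ratio (> 0); the GI load is
#'   divided by it.
#' @param plasma_factor Plasma factor (> 0), default 2.5.
#' @param strategy `"output_scale"` or `"slow_elimination"`.
#' @return Adjusted `pk_system` with attributes `strategy` and
#'   `plasma_output_factor`.
#' @export
apply_hydrophobic_adjustment <- function(system, ratio, plasma_factor = 2.5,
                                         strategy = c("output_scale",
                                                      "slow_elimination")) {
  stopifnot(inherits(system, "pk_system"))
  assert_positive(ratio, "ratio")
  assert_positive(plasma_factor, "plasma_factor")
  strategy <- match.arg(strategy)
  p <- match("plasma", system$labels)
  m <- match("metabolite", system$labels)
  if (is.na(p) || is.na(m)) {
    stop("system must have 'plasma' and 'metabolite' compartments",
         call. = FALSE)
  }
  system$initial[1] <- system$initial[1] / ratio
  out_factor <- 1
  if (strategy == "output_scale") {
    out_factor <- plasma_factor
  } else {
    kp <- system$rate_matrix[m, p]
    system$rate_matrix[m, p] <- kp / plasma_factor
    system$rate_matrix[p, p] <- system$rate_matrix[p, p] + kp - kp / plasma_factor
  }
  attr(system, "strategy") <- strategy
  attr(system, "plasma_output_factor") <- out_factor
  system
}

#' Short-range trajectory for a compound at face-value table rates
#'
#' Convenience wrapper: builds the GI -> plasma -> metabolite system from the
#' display-rounded rate magnitudes (min^-1), applies the hydrophobic
#' adjustment when the compound calls for it, and solves on a regular grid.
#'
#' @param compound A [pk_compound].
#' @param compounds Full compound set (needed to resolve the hydrophobic
#'   reference); defaults to the bundled study set.
#' @param t_end,dt Grid extent and step, minutes.
#' @param strategy Hydrophobic-adjustment strategy, see
#'   [apply_hydrophobic_adjustment()].
#' @param use_refined Use published refined rates from the compound's
#'   `reported` block instead of Table-rate magnitudes.
#' @return A `pk_trajectory` (plasma column already output-scaled where the
#'   strategy says so; raw series kept in attribute `plasma_raw`).
#' @export
shortrange_trajectory <- function(compound, compounds = NULL,
                                  t_end = 30, dt = 0.01,
                                  strategy = "output_scale",
                                  use_refined = FALSE) {
  stopifnot(inherits(compound, "pk_compound"))
  rates <- shortrange_rate_magnitudes(compound, refined = use_refined)
  sys <- shortrange_system(rates$k_gi, rates$k_plasma, c0 = 1.0)
  if (compound$hydrophobic) {
    if (is.null(compounds)) compounds <- study_compounds()
    ref <- compounds[[compound$hydrophobic_ref]]
    if (is.null(ref)) {
      stop("hydrophobic reference compound '", compound$hydrophobic_ref,
           "' not found", call. = FALSE)
    }
    ratio <- hydrophobic_initial_scaling(
      shortrange_rate_magnitudes(ref)$k_gi, rates$k_gi)
    sys <- apply_hydrophobic_adjustment(sys, ratio, strategy = strategy)
  }
  times <- seq(0, t_end, by = dt)
  traj <- solve_linear_system(sys, times)
  f <- attr(traj, "plasma_output_factor")
  attr(traj, "plasma_raw") <- traj$plasma
  traj$plasma <- traj$plasma * f
  traj
}

# Face-value rate magnitudes (min^-1) for the short-range model: published
# table entries when available (the study's downstream arithmetic uses the
# printed values), otherwise the computed display rounding.
shortrange_rate_magnitudes <- function(compound, refined = FALSE) {
  rep <- compound$reported
  if (refined) {
    if (is.null(rep$k_gi_refined) || is.null(rep$k_plasma_refined)) {
      stop("no refined rates available for ", compound$name, call. = FALSE)
    }
    return(list(k_gi = rep$k_gi_refined, k_plasma = rep$k_plasma_refined))
  }
  disp <- rate_constants(compound, display = TRUE)
  list(k_gi = rep$k_gi_display %||% disp$k_gi,
       k_plasma = rep$k_plasma_display %||% disp$k_plasma)
}
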