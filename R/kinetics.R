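# Modified sliding-rebinding kinetic model of the tip-link interface.
#
# Four occupation states of a doubly bonded adhesive interface:
#   P11 - both pseudo-bonds formed (initial state)
#   P10 - one bond broken, interface intact
#   P01 - single bond of a force-induced, newly formed interface
#   P00 - fully dissociated (absorbing)
# Force enters through Bell off-rates and through the rebinding switch P_n,
# which opens a strengthening pathway between two critical forces and
# produces catch behavior.

#' Parameters of the modified sliding-rebinding model
#'
#' Bundles all rate constants and switch parameters for one tip-link
#' interface variant. Units follow single-molecule convention: rates in 1/s,
#' distances in Angstrom, forces in pN, thermal energy in pN*Angstrom.
#'
#' @param k_minus1_0 Intrinsic (zero-force) single-bond off-rate, 1/s.
#' @param x_beta Distance from the bound state to the transition state, Angstrom.
#' @param k_plus1 Interface reorganization rate (P10 -> P11), 1/s.
#' @param k_plus2 Rebinding rate of the re-formed interface (P01 -> P11), 1/s.
#' @param F_C1 First critical force (slip -> catch onset), pN. The rebinding
#'   probability is zero below it. Default 58 pN, the experimentally observed
#'   onset for the tip-link interface.
#' @param F_C2 Second critical force (catch -> slip), pN.
#' @param n Rebinding-probability exponent (dimensionless, > 0).
#' @param kBT Thermal energy in pN*Angstrom; default 41.14 (298 K; 4.114 pN*nm).
#' @param variant `"WT"` (full model) or `"mutant"` (pivot lost: the
#'   rebinding probability is identically zero whatever `F_C1`/`F_C2`/`n`).
#'
#' @return An object of class `"sliding_rebinding_params"`.
#' @examples
#' p <- sliding_rebinding_params(0.5, 1.0, 2.8, 30.2, F_C2 = 100, n = 2.3)
#' mean_lifetime(p, force = 80)
#' @export
sliding_rebinding_params <- function(k_minus1_0, x_beta, k_plus1 = 0,
                                     k_plus2 = 0, F_C1 = 58, F_C2 = 100,
                                     n = 1, kBT = .KBT_DEFAULT,
                                     variant = c("WT", "mutant")) {
  variant <- match.arg(variant)
  p <- structure(
    list(k_minus1_0 = as.numeric(k_minus1_0), x_beta = as.numeric(x_beta),
         k_plus1 = as.numeric(k_plus1), k_plus2 = as.numeric(k_plus2),
         F_C1 = as.numeric(F_C1), F_C2 = as.numeric(F_C2), n = as.numeric(n),
         kBT = as.numeric(kBT), variant = variant),
    class = "sliding_rebinding_params")
  validate_sliding_rebinding_params(p)
  p
}

validate_sliding_rebinding_params <- function(p) {
  num <- unlist(p[c("k_minus1_0", "x_beta", "k_plus1", "k_plus2",
                    "F_C1", "F_C2", "n", "kBT")])
  if (!all(is.finite(num)))
    stop("all sliding-rebinding parameters must be finite numbers")
  if (any(num[c("k_minus1_0", "k_plus1", "k_plus2")] < 0))
    stop("rates must be >= 0")
  if (p$x_beta < 0) stop("x_beta must be >= 0")
  if (p$F_C1 < 0 || p$F_C1 > p$F_C2) stop("need 0 <= F_C1 <= F_C2")
  if (p$n <= 0) stop("n must be > 0")
  if (p$kBT <= 0) stop("kBT must be > 0")
  invisible(p)
}

#' @export
print.sliding_rebinding_params <- function(x, ...) {
  cat(sprintf("Sliding-rebinding parameters (%s)\n", x$variant))
  cat(sprintf("  k_-1^0 = %.4g 1/s   x_beta = %.4g A   kBT = %.4g pN.A\n",
              x$k_minus1_0, x$x_beta, x$kBT))
  cat(sprintf("  k_+1 = %.4g 1/s   k_+2 = %.4g 1/s\n", x$k_plus1, x$k_plus2))
  cat(sprintf("  F_C1 = %.4g pN   F_C2 = %.4g pN   n = %.4g\n",
              x$F_C1, x$F_C2, x$n))
  invisible(x)
}

#' Bell off-rate under force
#'
#' `k(f) = k0 * exp(f * x_beta / kBT)`: thermally activated escape over a
#' single barrier whose height is tilted by the applied force.
#'
#' @param k0 Zero-force rate, 1/s.
#' @param x_beta Distance to the transition state, Angstrom.
#' @param force Applied force, pN (vectorized).
#' @param kBT Thermal energy, pN*Angstrom.
#' @return Rate(s) in 1/s.
#' @export
bell_rate <- function(k0, x_beta, force, kBT = .KBT_DEFAULT) {
  if (!all(is.finite(c(k0, x_beta, force, kBT))))
    stop("non-finite input to bell_rate")
  if (k0 < 0) stop("k0 must be >= 0")
  if (kBT <= 0) stop("kBT must be > 0")
  k0 * exp(force * x_beta / kBT)
}

#' Off-rate of the doubly bonded state
#'
#' Two bonds share the load equally, each seeing `f/2`, and either may fail:
#' `k_-2(f) = 2 k_-1^0 exp(f x_beta / (2 kBT))`.
#'
#' @param params A [sliding_rebinding_params()] object.
#' @param force Applied force, pN (vectorized).
#' @return Rate(s) in 1/s.
#' @export
double_bond_rate <- function(params, force) {
  validate_sliding_rebinding_params(params)
  2 * bell_rate(params$k_minus1_0, params$x_beta, force / 2, params$kBT)
}

#' Force-dependent rebinding probability P_n
#'
#' The probability that a single-bond failure is diverted into formation of a
#' new, tilted interface instead of dissociation:
#' zero below `F_C1`, `{0.5 * (1 - cos(pi * F / F_C2))}^n` between the two
#' critical forces, and 1 above `F_C2`. The mutant variant has lost the pivot
#' and returns 0 at every force.
#'
#' @inheritParams double_bond_rate
#' @return Probability in \[0, 1\] (vectorized over `force`).
#' @export
rebinding_probability <- function(params, force) {
  validate_sliding_rebinding_params(params)
  if (any(force < 0)) stop("force must be >= 0")
  if (params$variant == "mutant") return(rep(0, length(force)))
  pn <- (0.5 * (1 - cos(pi * force / params$F_C2)))^params$n
  pn[force < params$F_C1] <- 0
  pn[force > params$F_C2] <- 1
  pmin(pmax(pn, 0), 1)
}

# Rates of the four-state scheme at one clamp force.
sr_rates <- function(params, force) {
  list(k1 = bell_rate(params$k_minus1_0, params$x_beta, force, params$kBT),
       k2 = double_bond_rate(params, force),
       kp1 = params$k_plus1, kp2 = params$k_plus2,
       Pn = rebinding_probability(params, force))
}

# Generator restricted to the transient states (P11, P10, P01); rows are
# from-states. Used for the exact mean first-passage time and the spectral
# survival evaluator.
sr_generator <- function(r) {
  matrix(c(-r$k2,   r$k2,                       0,
           2 * r$kp1, -(2 * r$kp1 + 2 * r$k1),  2 * r$Pn * r$k1,
           r$kp2,   0,                          -(r$kp2 + r$k1)),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("P11", "P10", "P01"), c("P11", "P10", "P01")))
}

# Spectral decomposition of the transient block: returns a closure S(t) and
# the exact integral of S over [0, Inf). Eigenvalues of the sub-generator
# have negative real part whenever absorption is possible.
sr_survival_closure <- function(params, force) {
  r <- sr_rates(params, force)
  Q <- sr_generator(r)
  eg <- eigen(t(Q))
  # occupancies p(t) = V exp(Lambda t) V^{-1} p0, p0 = e_P11
  w <- solve(eg$vectors, c(1, 0, 0))
  cs <- as.vector(colSums(eg$vectors) * w)   # S(t) = sum_i cs_i exp(lambda_i t)
  lam <- eg$values
  if (any(Re(lam) >= 1e-12))
    stop("survival does not decay: all escape rates vanish at force ",
         format(force))
  list(
    S = function(t) pmin(pmax(Re(vapply(t, function(tt)
      sum(cs * exp(lam * tt)), complex(1))), 0), 1),
    integral = Re(sum(-cs / lam)),
    lambda = lam, coef = cs)
}

#' Solve the sliding-rebinding survival ODE at a clamp force
#'
#' Integrates the four-state kinetic scheme with rates held at the clamp
#' force, from the fully bonded initial condition `P11(0) = 1`, and returns
#' the bond survival probability `S(t) = P11 + P10 + P01 = 1 - P00`.
#' A stiff-capable integrator is used (`deSolve::lsoda`, rtol 1e-8,
#' atol 1e-10) because the rates span several orders of magnitude at high
#' force.
#'
#' @inheritParams double_bond_rate
#' @param force Clamp force, pN (scalar).
#' @param t_grid Strictly increasing time grid starting at 0, seconds.
#' @return A `"survival_curve"` object: list with `times`, `survival`, and a
#'   `states` attribute holding the full (P11, P10, P01, P00) trajectory.
#' @export
solve_survival <- function(params, force, t_grid) {
  validate_sliding_rebinding_params(params)
  stopifnot(length(force) == 1, is.finite(force))
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must start at 0 and be strictly increasing")
  r <- sr_rates(params, force)
  rhs <- function(t, y, parms) {
    P11 <- y[1]; P10 <- y[2]; P01 <- y[3]
    list(c(2 * r$kp1 * P10 + r$kp2 * P01 - r$k2 * P11,
           r$k2 * P11 - 2 * (r$kp1 + r$k1) * P10,
           2 * r$Pn * r$k1 * P10 - (r$kp2 + r$k1) * P01,
           2 * (1 - r$Pn) * r$k1 * P10 + r$k1 * P01))
  }
  sol <- deSolve::ode(y = c(P11 = 1, P10 = 0, P01 = 0, P00 = 0),
                      times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE solver failed at force %.3g pN (params: k_-1^0=%.3g, x_beta=%.3g)",
                 force, params$k_minus1_0, params$x_beta))
  states <- sol[, c("P11", "P10", "P01", "P00"), drop = FALSE]
  surv <- rowSums(states[, 1:3, drop = FALSE])
  structure(list(times = as.numeric(sol[, "time"]),
                 survival = pmin(pmax(surv, 0), 1)),
            states = states, force = force, class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d time points, t in [%.4g, %.4g] s, S(end) = %.4g\n",
              length(x$times), min(x$times), max(x$times),
              x$survival[length(x$survival)]))
  invisible(x)
}

#' Mean bond lifetime at a clamp force
#'
#' The default `"integral"` estimator evaluates the mean first-passage time
#' to full dissociation exactly, by a linear solve on the transient
#' generator; for this linear scheme it equals the integral of the survival
#' curve. The `"expfit"` estimator instead fits a single exponential to the
#' model survival curve, mirroring how lifetimes are extracted from
#' force-clamp survival data.
#'
#' @inheritParams double_bond_rate
#' @param force Clamp force, pN (scalar).
#' @param estimator `"integral"` (exact mean first-passage time) or
#'   `"expfit"` (single-exponential fit to S(t)).
#' @return Mean lifetime in seconds.
#' @export
mean_lifetime <- function(params, force, estimator = c("integral", "expfit")) {
  validate_sliding_rebinding_params(params)
  estimator <- match.arg(estimator)
  r <- sr_rates(params, force)
  if (r$k1 <= 0 && r$k2 <= 0)
    stop("mean lifetime diverges: all dissociation rates are zero")
  Q <- sr_generator(r)
  tau <- tryCatch(as.numeric(solve(-Q, rep(1, 3))[1]),
                  error = function(e) stop("mean lifetime diverges (singular generator)"))
  if (!is.finite(tau) || tau <= 0)
    stop("mean lifetime diverges or is non-positive")
  if (estimator == "integral") return(as.numeric(tau))
  sc <- sr_survival_closure(params, force)
  tg <- seq(0, 6 * tau, length.out = 201)
  sv <- sc$S(tg)
  fit <- minpack.lm::nlsLM(sv ~ exp(-tg / tt), start = list(tt = tau),
                           lower = 1e-12, control = minpack.lm::nls.lm.control(maxiter = 200))
  as.numeric(coef(fit)[["tt"]])
}

#' Mean lifetime versus clamp force
#'
#' Vectorizes [mean_lifetime()] over a force grid. For wild-type parameter
#' sets with an open rebinding pathway the curve is non-monotonic
#' (slip-catch-slip); for the mutant it decreases monotonically.
#'
#' @inheritParams mean_lifetime
#' @param forces Strictly increasing clamp forces, pN.
#' @param errors Optional per-force lifetime uncertainties, seconds.
#' @param label Optional curve label.
#' @return A `"lifetime_force_curve"`: data.frame with columns `force_pN`,
#'   `lifetime_s` and (if given) `error_s`.
#' @export
lifetime_force_curve <- function(params, forces,
                                 estimator = c("integral", "expfit"),
                                 errors = NULL, label = NULL) {
  estimator <- match.arg(estimator)
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  tau <- vapply(forces, function(f) mean_lifetime(params, f, estimator),
                numeric(1))
  as_lifetime_force_curve(forces, tau, errors, label)
}

#' Construct a lifetime-force curve object
#'
#' @param forces Strictly increasing forces, pN.
#' @param lifetimes Positive mean lifetimes, s.
#' @param errors Optional lifetime uncertainties, s.
#' @param label Optional label.
#' @return A `"lifetime_force_curve"` data.frame.
#' @export
as_lifetime_force_curve <- function(forces, lifetimes, errors = NULL,
                                    label = NULL) {
  if (any(diff(forces) <= 0)) stop("forces must be strictly increasing")
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0")
  df <- data.frame(force_pN = forces, lifetime_s = lifetimes)
  if (!is.null(errors)) df$error_s <- errors
  structure(df, label = label,
            class = c("lifetime_force_curve", "data.frame"))
}

#' Stochastic bond lifetimes by exact event sampling
#'
#' Direct (two-random-number) Gillespie simulation of the four-state Markov
#' chain, from the fully bonded state to absorption, at a fixed clamp force.
#' This is the stochastic counterpart of [solve_survival()] and the engine
#' behind the synthetic lifetime generator.
#'
#' @inheritParams mean_lifetime
#' @param n_samples Number of independent first-passage times to draw.
#' @param seed Integer seed; the sample vector is reproducible given it.
#' @return Numeric vector of `n_samples` lifetimes in seconds.
#' @export
gillespie_lifetimes <- function(params, force, n_samples, seed = NULL) {
  validate_sliding_rebinding_params(params)
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- sr_rates(params, force)
  if (r$k1 <= 0 && r$k2 <= 0)
    stop("absorption impossible: all dissociation rates are zero")
  # per-state outgoing rates and destinations (state 4 = absorbed)
  out_rates <- list(
    c(r$k2),                                         # P11 -> P10
    c(2 * r$kp1, 2 * r$Pn * r$k1, 2 * (1 - r$Pn) * r$k1),  # P10 -> P11/P01/P00
    c(r$kp2, r$k1))                                  # P01 -> P11/P00
  dests <- list(c(2L), c(1L, 3L, 4L), c(1L, 4L))
  totals <- vapply(out_rates, sum, numeric(1))
  times <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    s <- 1L; t <- 0
    repeat {
      t <- t + rexp(1, totals[s])
      u <- runif(1) * totals[s]
      s <- dests[[s]][findInterval(u, cumsum(out_rates[[s]]),
                                   left.open = TRUE) + 1L]
      if (s == 4L) break
    }
    times[i] <- t
  }
  times
}

#' Kolmogorov-Smirnov distance between sampled lifetimes and the model
#'
#' One-sample KS statistic of an empirical lifetime sample against the
#' continuous first-passage-time distribution implied by the kinetic model
#' (CDF `1 - S(t)` from the spectral solution).
#'
#' @inheritParams mean_lifetime
#' @param lifetimes Sampled lifetimes, s.
#' @return The KS statistic (sup-norm distance).
#' @export
ks_distance_model <- function(lifetimes, params, force) {
  sc <- sr_survival_closure(params, force)
  x <- sort(lifetimes)
  n <- length(x)
  Fx <- 1 - sc$S(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}
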