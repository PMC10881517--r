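# Unfolding-augmented unbinding kinetics.
#
# Non-interacting EC domains of the long cadherin arm can unfold under the
# clamp force before the interface lets go. Unfolding dissipates force and
# delays full dissociation, so the dissociated-state probability is weighted
# by the total unfolding probability P_U: P00u(t) = P_U(t) * P00(t), and the
# observable survival becomes 1 - P00u.

#' Bell unfolding parameters for one step-height class
#'
#' @param k_u0 Zero-force unfolding rate, 1/s.
#' @param x_beta_u Distance to the unfolding transition state, Angstrom.
#' @param step_height Step height label, nm (not used in the kinetics).
#' @return An `"unfolding_class_params"` object.
#' @export
unfolding_class_params <- function(k_u0, x_beta_u, step_height = NA_real_) {
  if (!all(is.finite(c(k_u0, x_beta_u))) || k_u0 < 0 || x_beta_u < 0)
    stop("k_u0 and x_beta_u must be finite and >= 0")
  structure(list(k_u0 = as.numeric(k_u0), x_beta_u = as.numeric(x_beta_u),
                 step_height = as.numeric(step_height)),
            class = "unfolding_class_params")
}

#' @export
print.unfolding_class_params <- function(x, ...) {
  cat(sprintf("Unfolding class (~%g nm): k_u^0 = %.4g 1/s, x_beta_u = %.4g A\n",
              x$step_height, x$k_u0, x$x_beta_u))
  invisible(x)
}

#' Force-dependent unfolding rate of a step class
#'
#' Bell kinetics: `k_u(f) = k_u0 * exp(f * x_beta_u / kBT)`.
#'
#' @param class_params An [unfolding_class_params()] object.
#' @param force Force, pN (vectorized).
#' @param kBT Thermal energy, pN*Angstrom.
#' @return Rate(s), 1/s.
#' @export
unfolding_rate <- function(class_params, force, kBT = .KBT_DEFAULT) {
  bell_rate(class_params$k_u0, class_params$x_beta_u, force, kBT)
}

#' Probability of having unfolded by time t
#'
#' `P_u(t) = 1 - exp(-k_u t)` for a first-order unfolding process.
#'
#' @param rate Unfolding rate, 1/s.
#' @param t Time(s), s (>= 0).
#' @return Probability in \[0, 1).
#' @export
unfolding_probability <- function(rate, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (any(rate < 0)) stop("rate must be >= 0")
  1 - exp(-rate * t)
}

#' Observed per-force unfolding counts for the two dominant step classes
#'
#' @param force Clamp forces, pN.
#' @param n1,n2 Observed unfolding counts for the ~5 nm and ~12 nm classes
#'   at each force (non-negative; `n1 + n2 > 0` per force).
#' @return An `"unfolding_counts"` data.frame with normalized weights
#'   `n1N`, `n2N` (summing to 1 at each force with observed events;
#'   `NA` where `n1 + n2 = 0`).
#' @export
unfolding_counts <- function(force, n1, n2) {
  stopifnot(length(force) == length(n1), length(n1) == length(n2))
  if (any(n1 < 0) || any(n2 < 0)) stop("counts must be >= 0")
  tot <- n1 + n2
  # weights are undefined (NA) at forces with no observed unfolding; they
  # are only required where the augmentation is actually evaluated
  w1 <- ifelse(tot > 0, n1 / tot, NA_real_)
  structure(data.frame(force_pN = force, n1 = n1, n2 = n2,
                       n1N = w1, n2N = 1 - w1),
            class = c("unfolding_counts", "data.frame"))
}

#' Total unfolding probability from class weights
#'
#' Convex combination of the two dominant class probabilities with weights
#' `n_iN = n_i / (n1 + n2)` from the observed counts:
#' `P_U = n1N * P1u + n2N * P2u`.
#'
#' @param counts Either an [unfolding_counts()] row (or single-force object)
#'   or a length-2 numeric `c(n1, n2)`.
#' @param P1u,P2u Unfolding probabilities of the ~5 nm and ~12 nm classes
#'   (scalars or vectors over time).
#' @return `P_U`, same length as `P1u`.
#' @export
total_unfolding_probability <- function(counts, P1u, P2u) {
  if (inherits(counts, "data.frame")) {
    stopifnot(nrow(counts) == 1)
    n1 <- counts$n1; n2 <- counts$n2
  } else {
    stopifnot(length(counts) == 2)
    n1 <- counts[1]; n2 <- counts[2]
  }
  if (n1 < 0 || n2 < 0 || n1 + n2 <= 0)
    stop("counts must be >= 0 with positive total")
  (n1 * P1u + n2 * P2u) / (n1 + n2)
}

#' Unfolding-adjusted survival curve
#'
#' Weights the dissociated-state probability by the total unfolding
#' probability: `S_u(t) = 1 - P_U(t) * P00(t)`. Because `P_U <= 1`, the
#' adjusted survival dominates the unadjusted one pointwise - unfolding
#' dissipates force and extends survival.
#'
#' @param P_U Total unfolding probability: scalar in \[0, 1\] or a vector
#'   evaluated at the same times as `P00_curve` (the default, time-consistent
#'   reading evaluates each class probability at the same t as P00).
#' @param P00_curve A `"survival_curve"` from [solve_survival()] (its P00
#'   trajectory is used), or a list with `times` and `P00`.
#' @return A `"survival_curve"` with the adjusted survival.
#' @export
unfolding_adjusted_survival <- function(P_U, P00_curve) {
  if (inherits(P00_curve, "survival_curve")) {
    times <- P00_curve$times
    P00 <- attr(P00_curve, "states")[, "P00"]
    if (is.null(P00)) P00 <- 1 - P00_curve$survival
  } else {
    times <- P00_curve$times; P00 <- P00_curve$P00
  }
  if (any(P_U < 0 | P_U > 1)) stop("P_U must lie in [0, 1]")
  if (length(P_U) != 1 && length(P_U) != length(times))
    stop("P_U must be scalar or match the time grid")
  structure(list(times = times,
                 survival = pmin(pmax(1 - P_U * P00, 0), 1)),
            class = "survival_curve")
}

# Time-dependent P_U(t) closure at one clamp force, from the two dominant
# step classes and their observed counts.
unfolding_PU_closure <- function(classes, counts_row, force,
                                 kBT = .KBT_DEFAULT) {
  stopifnot(length(classes) >= 2)
  k1 <- unfolding_rate(classes[[1]], force, kBT)
  k2 <- unfolding_rate(classes[[2]], force, kBT)
  w <- c(counts_row$n1, counts_row$n2)
  function(t) total_unfolding_probability(
    w, unfolding_probability(k1, t), unfolding_probability(k2, t))
}

#' Mean lifetime under the unfolding-augmented model
#'
#' Integrates the adjusted survival `1 - P_U(t) P00(t)` over time by
#' adaptive quadrature, with `P00` from the spectral solution of the kinetic
#' scheme and `P_U(t)` from the two dominant step classes evaluated at the
#' same times.
#'
#' @inheritParams mean_lifetime
#' @param classes List of [unfolding_class_params()] (first two = ~5 nm and
#'   ~12 nm classes).
#' @param counts An [unfolding_counts()] table; the row at (or nearest to)
#'   `force` supplies the weights.
#' @param mode `"time"` (default; P_U evaluated at the same t as P00) or
#'   `"scalar"` (P_U frozen at the unadjusted mean lifetime, a sensitivity
#'   variant). With a constant `P_U < 1` the adjusted survival tends to
#'   `1 - P_U > 0`, so the scalar mode integrates over the clamp window
#'   `[0, t_clamp]` only.
#' @param t_clamp Clamp duration used by the scalar mode, s (default 10).
#' @return Mean lifetime, s.
#' @export
mean_lifetime_unfolding <- function(params, force, classes, counts,
                                    mode = c("time", "scalar"),
                                    t_clamp = 10) {
  mode <- match.arg(mode)
  validate_sliding_rebinding_params(params)
  i <- which.min(abs(counts$force_pN - force))
  PU <- unfolding_PU_closure(classes, counts[i, , drop = FALSE], force,
                             params$kBT)
  sc <- sr_survival_closure(params, force)
  tau0 <- sc$integral
  # no unfolding pathway at all: the augmentation is inert and the plain
  # kinetic lifetime applies (P_U would stay 0 and S_u would never decay)
  if (unfolding_rate(classes[[1]], force, params$kBT) <= 0 &&
      unfolding_rate(classes[[2]], force, params$kBT) <= 0)
    return(tau0)
  if (mode == "scalar") {
    pu <- PU(tau0)
    f <- function(t) 1 - pu * (1 - sc$S(t))
    return(integrate(f, 0, t_clamp, rel.tol = 1e-9)$value)
  }
  f <- function(t) 1 - PU(t) * (1 - sc$S(t))
  # S_u decays like the slowest of the kinetic eigenvalues and the unfolding
  # rates; integrate in geometrically growing panels until the increment is
  # negligible.
  total <- 0; lo <- 0; hi <- max(5 * tau0, 1)
  repeat {
    piece <- integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-12,
                       stop.on.error = FALSE)$value
    total <- total + piece
    if (piece < 1e-9 * max(total, 1e-12) || hi > 1e7 * tau0) break
    lo <- hi; hi <- hi * 4
  }
  total
}
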