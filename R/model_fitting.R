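# Nonlinear least-squares fitting of the sliding-rebinding model (with or
# without the unfolding augmentation) to lifetime-force curves, plus
# parameter-recovery harnesses on synthetic data.

sr_free_names <- function(variant, free_FC1 = FALSE) {
  if (variant == "mutant") return(c("k_minus1_0", "x_beta", "k_plus1"))
  c("k_minus1_0", "x_beta", "k_plus1", "k_plus2", "F_C2", "n",
    if (free_FC1) "F_C1")
}

sr_default_bounds <- function(names, forces) {
  fmax <- max(forces)
  lower <- c(k_minus1_0 = 1e-3, x_beta = 0.01, k_plus1 = 0, k_plus2 = 0,
             F_C2 = 10, n = 0.2, F_C1 = 1)
  upper <- c(k_minus1_0 = 20, x_beta = 5, k_plus1 = 50, k_plus2 = 200,
             F_C2 = max(300, 1.5 * fmax), n = 10, F_C1 = fmax)
  list(lower = lower[names], upper = upper[names])
}

# Start designs for the multi-start search. Rates are sampled on a log
# scale (they span decades); x_beta, F_C2 and n uniformly. A block of
# data-informed starts seeds the Bell-like basin: zero-force intercept and
# low-force slope of log(tau) vs f fix k_minus1_0 and x_beta, the interior
# maximum (if any) fixes F_C2, and the rebinding rates are gridded.
sr_make_starts <- function(curve, free, b, n_starts, kBT, F_C1) {
  f <- curve$force_pN; tau <- curve$lifetime_s
  logrates <- c("k_minus1_0", "k_plus1", "k_plus2")
  low <- f <= max(min(F_C1, max(f) * 0.6), f[2])
  sl <- tryCatch(coef(lm(log(tau[low]) ~ f[low])), error = function(e) c(0, 0))
  k1_0 <- min(max(1 / (2 * exp(sl[1])), b$lower["k_minus1_0"] * 1.01),
              b$upper["k_minus1_0"])
  xb_0 <- min(max(-sl[2] * kBT, b$lower["x_beta"] * 1.01), b$upper["x_beta"])
  hi <- which(f > F_C1)
  FC2_0 <- if (length(hi) > 2 && any(diff(tau[hi]) > 0))
    f[hi][which.max(tau[hi])] else 0.9 * max(f)
  FC2_0 <- min(max(FC2_0, b$lower["F_C2"]), b$upper["F_C2"])
  grid <- expand.grid(k_plus1 = c(0.5, 5), k_plus2 = c(2, 30), n = c(1, 3))
  data_starts <- lapply(seq_len(nrow(grid)), function(i) {
    st <- c(k_minus1_0 = unname(k1_0), x_beta = unname(xb_0),
            k_plus1 = grid$k_plus1[i], k_plus2 = grid$k_plus2[i],
            F_C2 = FC2_0, n = grid$n[i], F_C1 = unname(min(F_C1, FC2_0)))
    st[free]
  })
  lo <- b$lower; hi_b <- b$upper
  lo[intersect(free, logrates)] <- pmax(lo[intersect(free, logrates)], 1e-3)
  des <- lhs::randomLHS(n_starts, length(free))
  lhs_starts <- lapply(seq_len(nrow(des)), function(i) {
    st <- numeric(length(free)); names(st) <- free
    for (j in seq_along(free)) {
      nm <- free[j]
      st[j] <- if (nm %in% logrates)
        10^(log10(lo[nm]) + des[i, j] * (log10(hi_b[nm]) - log10(lo[nm])))
      else lo[nm] + des[i, j] * (hi_b[nm] - lo[nm])
    }
    st
  })
  c(data_starts, lhs_starts)
}

# assemble a full parameter object from a free-parameter vector
sr_assemble <- function(theta, names, base) {
  p <- base
  p[names] <- as.list(theta)
  if (p$F_C1 > p$F_C2) p$F_C1 <- p$F_C2   # keep the switch ordered during search
  class(p) <- "sliding_rebinding_params"
  p
}

#' Fit the sliding-rebinding model to a lifetime-force curve
#'
#' Weighted nonlinear least squares of the model mean lifetime against
#' measured mean lifetimes, by Levenberg-Marquardt with multi-start
#' initialization (Latin-hypercube starts within the bounds, deterministic
#' given `seed`). For the wild type the free parameters are
#' `k_minus1_0, x_beta, k_plus1, k_plus2, F_C2, n` (and optionally `F_C1`);
#' the mutant frees only `k_minus1_0, x_beta, k_plus1` since its rebinding
#' pathway is absent.
#'
#' The objective acts on lifetimes (optionally log-lifetimes, useful when
#' they span orders of magnitude across the force range), weighted by
#' `1/error_s` when the curve carries uncertainties.
#'
#' @param curve A `"lifetime_force_curve"` with >= 5 force points.
#' @param variant `"WT"` or `"mutant"`.
#' @param init Optional named list/vector of starting values (used as the
#'   first start).
#' @param bounds Optional list with named `lower` and `upper` vectors.
#' @param fixed Named list of parameters to hold fixed (e.g.
#'   `list(F_C1 = 58)`; `F_C1` is fixed at 58 pN by default unless
#'   `free_FC1 = TRUE`).
#' @param free_FC1 Free the first critical force under `0 < F_C1 < F_C2`?
#' @param estimator Lifetime estimator used for the model prediction (see
#'   [mean_lifetime()]).
#' @param log_lifetime Fit on log-lifetimes?
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed Integer seed for the start design.
#' @param kBT Thermal energy, pN*Angstrom.
#' @return An `"sr_fit"`: list with `params` (best-fit
#'   [sliding_rebinding_params()]), `se`, `correlation` (parameter
#'   correlation matrix), `rss`, `dof`, `fixed` flags, `converged`,
#'   `n_starts_converged`, `fitted`.
#' @export
fit_sliding_rebinding <- function(curve, variant = c("WT", "mutant"),
                                  init = NULL, bounds = NULL, fixed = list(),
                                  free_FC1 = FALSE,
                                  estimator = c("integral", "expfit"),
                                  log_lifetime = FALSE, n_starts = 16,
                                  seed = 1, kBT = .KBT_DEFAULT) {
  variant <- match.arg(variant)
  estimator <- match.arg(estimator)
  forces <- curve$force_pN; tau <- curve$lifetime_s
  if (length(forces) < 5) stop("need >= 5 force points")
  n_free <- length(setdiff(sr_free_names(variant, free_FC1), names(fixed)))
  if (length(forces) < n_free)
    stop("need at least as many force points (", length(forces),
         ") as free parameters (", n_free, ")")
  wts <- if (!is.null(curve$error_s)) 1 / pmax(curve$error_s, 1e-9) else
    rep(1, length(tau))
  free <- setdiff(sr_free_names(variant, free_FC1), names(fixed))
  base <- list(k_minus1_0 = 0.5, x_beta = 1, k_plus1 = 1, k_plus2 = 10,
               F_C1 = 58, F_C2 = 100, n = 1, kBT = kBT, variant = variant)
  base[names(fixed)] <- fixed
  b <- sr_default_bounds(free, forces)
  if (!is.null(bounds)) {
    b$lower[names(bounds$lower)] <- bounds$lower
    b$upper[names(bounds$upper)] <- bounds$upper
  }
  model_tau <- function(theta) {
    p <- sr_assemble(theta, free, base)
    vapply(forces, function(f) tryCatch(mean_lifetime(p, f, estimator),
                                        error = function(e) NA_real_),
           numeric(1))
  }
  resid_fun <- function(theta) {
    m <- model_tau(theta)
    if (any(!is.finite(m)) || any(m <= 0))
      return(rep(1e6, length(tau)))
    if (log_lifetime) wts * (log(m) - log(tau)) else wts * (m - tau)
  }
  # multi-start design: user start first, then data-informed grid and
  # log-scale Latin-hypercube points
  set.seed(seed)
  starts <- sr_make_starts(curve, free, b, n_starts, kBT, base$F_C1)
  if (!is.null(init)) {
    iv <- unlist(init)[free]
    if (!any(is.na(iv))) starts <- c(list(iv), starts)
  }
  best <- NULL; n_conv <- 0L
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, b$lower), b$upper),
                         fn = resid_fun, lower = b$lower, upper = b$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$info %in% 1:4) n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("sliding-rebinding fit failed to converge from any of ",
         length(starts), " starts (variant ", variant, ")")
  theta <- setNames(as.numeric(best$par), free)
  p_hat <- sr_assemble(theta, free, base)
  validate_sliding_rebinding_params(p_hat)
  rss <- best$deviance
  dof <- length(tau) - length(free)
  cv <- sr_fit_covariance(resid_fun, theta, rss, dof, b)
  structure(list(params = p_hat, se = cv$se, correlation = cv$correlation,
                 rss = rss, dof = dof, estimator = estimator,
                 fixed = c(fixed, if (!free_FC1 && variant == "WT" &&
                                      !("F_C1" %in% names(fixed)))
                   list(F_C1 = base$F_C1)),
                 free = free, converged = best$info %in% 1:4,
                 n_starts_converged = n_conv,
                 fitted = model_tau(theta), curve = curve),
            class = "sr_fit")
}

# Gauss-Newton covariance at the optimum via finite-difference Jacobian;
# also reports the parameter correlation matrix (the rebinding rates are
# often strongly correlated and point estimates alone would mislead).
sr_fit_covariance <- function(resid_fun, theta, rss, dof, b) {
  k <- length(theta)
  r0 <- resid_fun(theta)
  J <- matrix(NA_real_, length(r0), k)
  for (j in seq_len(k)) {
    h <- max(1e-6 * abs(theta[j]), 1e-8)
    up <- theta; up[j] <- min(up[j] + h, b$upper[j])
    dn <- theta; dn[j] <- max(dn[j] - h, b$lower[j])
    J[, j] <- (resid_fun(up) - resid_fun(dn)) / (up[j] - dn[j])
  }
  sigma2 <- rss / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0))
    return(list(se = setNames(rep(NA_real_, k), names(theta)),
                correlation = NULL))
  se <- sqrt(diag(cov))
  corr <- cov / tcrossprod(se)
  dimnames(corr) <- list(names(theta), names(theta))
  list(se = setNames(se, names(theta)), correlation = corr)
}

#' @export
print.sr_fit <- function(x, ...) {
  cat(sprintf("Sliding-rebinding fit (%s), RSS = %.4g, dof = %d%s\n",
              x$params$variant, x$rss, x$dof,
              if (x$converged) "" else "  [NOT converged]"))
  for (nm in x$free)
    cat(sprintf("  %-11s = %8.4g +/- %.3g\n", nm, x$params[[nm]],
                x$se[[nm]]))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  if (!is.null(x$correlation)) {
    hi <- which(abs(x$correlation) > 0.95 & upper.tri(x$correlation),
                arr.ind = TRUE)
    if (nrow(hi))
      cat("  strongly correlated:",
          paste(rownames(x$correlation)[hi[, 1]],
                colnames(x$correlation)[hi[, 2]], sep = "~",
                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit the unfolding-augmented model to a lifetime-force curve
#'
#' As [fit_sliding_rebinding()], but the model lifetime integrates the
#' unfolding-adjusted survival `1 - P_U(t) P00(t)`, with the total unfolding
#' probability built from the two dominant step classes and the observed
#' per-force unfolding counts.
#'
#' @inheritParams fit_sliding_rebinding
#' @param classes List of [unfolding_class_params()]; the first two entries
#'   (the ~5 nm and ~12 nm classes) enter the augmentation.
#' @param counts An [unfolding_counts()] table covering the curve's forces.
#' @return An `"sr_fit"` (with `unfolding = TRUE`).
#' @export
fit_with_unfolding <- function(curve, classes, counts,
                               variant = c("WT", "mutant"), init = NULL,
                               bounds = NULL, fixed = list(),
                               free_FC1 = FALSE, log_lifetime = FALSE,
                               n_starts = 8, seed = 1, kBT = .KBT_DEFAULT) {
  variant <- match.arg(variant)
  forces <- curve$force_pN; tau <- curve$lifetime_s
  if (length(forces) < 5) stop("need >= 5 force points")
  n_free2 <- length(setdiff(sr_free_names(variant, free_FC1), names(fixed)))
  if (length(forces) < n_free2)
    stop("need at least as many force points (", length(forces),
         ") as free parameters (", n_free2, ")")
  wts <- if (!is.null(curve$error_s)) 1 / pmax(curve$error_s, 1e-9) else
    rep(1, length(tau))
  free <- setdiff(sr_free_names(variant, free_FC1), names(fixed))
  base <- list(k_minus1_0 = 0.5, x_beta = 1, k_plus1 = 1, k_plus2 = 10,
               F_C1 = 58, F_C2 = 100, n = 1, kBT = kBT, variant = variant)
  base[names(fixed)] <- fixed
  b <- sr_default_bounds(free, forces)
  if (!is.null(bounds)) {
    b$lower[names(bounds$lower)] <- bounds$lower
    b$upper[names(bounds$upper)] <- bounds$upper
  }
  model_tau <- function(theta) {
    p <- sr_assemble(theta, free, base)
    vapply(forces, function(f)
      tryCatch(mean_lifetime_unfolding(p, f, classes, counts),
               error = function(e) NA_real_), numeric(1))
  }
  resid_fun <- function(theta) {
    m <- model_tau(theta)
    if (any(!is.finite(m)) || any(m <= 0)) return(rep(1e6, length(tau)))
    if (log_lifetime) wts * (log(m) - log(tau)) else wts * (m - tau)
  }
  set.seed(seed)
  starts <- sr_make_starts(curve, free, b, n_starts, kBT, base$F_C1)
  if (!is.null(init)) {
    iv <- unlist(init)[free]
    if (!any(is.na(iv))) starts <- c(list(iv), starts)
  }
  best <- NULL; n_conv <- 0L
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, b$lower), b$upper),
                         fn = resid_fun, lower = b$lower, upper = b$upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ptol = 1e-9, ftol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$info %in% 1:4) n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("unfolding-augmented fit failed from all starts")
  theta <- setNames(as.numeric(best$par), free)
  p_hat <- sr_assemble(theta, free, base)
  rss <- best$deviance
  dof <- length(tau) - length(free)
  cv <- sr_fit_covariance(resid_fun, theta, rss, dof, b)
  structure(list(params = p_hat, se = cv$se, correlation = cv$correlation,
                 rss = rss, dof = dof, estimator = "integral",
                 unfolding = TRUE, fixed = fixed, free = free,
                 converged = best$info %in% 1:4, n_starts_converged = n_conv,
                 fitted = model_tau(theta), curve = curve),
            class = "sr_fit")
}

#' Bell fits of per-class unfolding lifetime data
#'
#' For each step-height class, fits the force dependence of the mean
#' unfolding lifetime `tau_u(f) = (1/k_u0) exp(-f x_beta_u / kBT)` (Bell
#' kinetics) and reports the zero-force unfolding rate and distance to the
#' unfolding transition.
#'
#' @param step_lifetime_table data.frame with columns `step_height` (class
#'   label, nm), `force_pN`, `lifetime_s`.
#' @param kBT Thermal energy, pN*Angstrom.
#' @return A list of [unfolding_class_params()] (attributes `se` and
#'   `boundary` flag zero-slope classes), ordered by step height.
#' @export
fit_unfolding_bell <- function(step_lifetime_table, kBT = .KBT_DEFAULT) {
  need <- c("step_height", "force_pN", "lifetime_s")
  if (!all(need %in% names(step_lifetime_table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  out <- lapply(split(step_lifetime_table, step_lifetime_table$step_height),
                function(d) {
    if (nrow(d) < 3)
      stop("need >= 3 force points per step class (class ",
           d$step_height[1], " nm)")
    lf <- lm(log(lifetime_s) ~ force_pN, data = d)
    slope <- coef(lf)[[2]]
    x_u <- max(-slope * kBT, 0)
    k0 <- exp(-coef(lf)[[1]])
    fit <- tryCatch(minpack.lm::nlsLM(
      lifetime_s ~ (1 / k0) * exp(-force_pN * xb / kBT),
      data = cbind(d, kBT = kBT),
      start = list(k0 = k0, xb = max(x_u, 1e-3)),
      lower = c(1e-9, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      k0 <- coef(fit)[["k0"]]; x_u <- coef(fit)[["xb"]]
      se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 2))
    } else se <- rep(NA_real_, 2)
    cp <- unfolding_class_params(k_u0 = k0, x_beta_u = x_u,
                                 step_height = d$step_height[1])
    attr(cp, "se") <- se
    attr(cp, "boundary") <- x_u <= 1e-6
    cp
  })
  out[order(vapply(out, function(x) x$step_height, numeric(1)))]
}

#' End-to-end parameter-recovery experiment
#'
#' Validation harness for the full synthetic pipeline: stochastic lifetime
#' sampling (Gillespie) -> product-limit survival -> exponential lifetime ->
#' lifetime-force curve -> sliding-rebinding fit. Reports per-parameter
#' bias, RMSE and the spread of the recovered estimates across replicates.
#'
#' @param true_params Generating [sliding_rebinding_params()].
#' @param forces Clamp forces, pN.
#' @param n_per_force Events per force per replicate.
#' @param replicates Number of replicates.
#' @param seed Integer seed (replicate r uses `seed + r`).
#' @param max_duration Clamp window for censoring, s.
#' @param fit_args Extra arguments passed to [fit_sliding_rebinding()].
#' @return A `"recovery_report"`: list with `estimates` (replicates x
#'   parameters), `summary` (truth, mean, bias, sd, rmse, covered_2sd per
#'   parameter), and the call settings.
#' @export
recovery_experiment <- function(true_params, forces, n_per_force = 60,
                                replicates = 20, seed = 1,
                                max_duration = 10, fit_args = list()) {
  validate_sliding_rebinding_params(true_params)
  free <- sr_free_names(true_params$variant)
  est <- matrix(NA_real_, replicates, length(free),
                dimnames = list(NULL, free))
  for (r in seq_len(replicates)) {
    curve <- tryCatch(
      synthetic_lifetime_curve(true_params, forces, n_per_force,
                               seed = seed + r, max_duration = max_duration),
      error = function(e) NULL)
    if (is.null(curve)) next
    fit <- tryCatch(do.call(fit_sliding_rebinding, c(
      list(curve = curve, variant = true_params$variant,
           seed = seed + 1000L + r, kBT = true_params$kBT,
           fixed = list(F_C1 = true_params$F_C1)),
      fit_args)), error = function(e) NULL)
    if (is.null(fit)) next
    est[r, ] <- unlist(fit$params[free])
  }
  truth <- unlist(true_params[free])
  ok <- stats::complete.cases(est)
  m <- colMeans(est[ok, , drop = FALSE])
  s <- apply(est[ok, , drop = FALSE], 2, sd)
  summary <- data.frame(
    parameter = free, truth = truth, mean = m, bias = m - truth, sd = s,
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            rep(truth, each = sum(ok)))^2)),
    covered_2sd = abs(m - truth) <= 2 * s, row.names = NULL)
  structure(list(estimates = est, summary = summary, forces = forces,
                 n_per_force = n_per_force, replicates = replicates,
                 n_used = sum(ok), seed = seed),
            class = "recovery_report")
}

# Gillespie samples -> empirical survival -> mono-exponential lifetime, for
# each force; the synthetic counterpart of the experimental pipeline.
synthetic_lifetime_curve <- function(params, forces, n_per_force, seed,
                                     max_duration = 10) {
  taus <- numeric(length(forces)); errs <- numeric(length(forces))
  for (i in seq_along(forces)) {
    lt <- gillespie_lifetimes(params, forces[i], n_per_force,
                              seed = seed * 131 + i)
    cens <- lt >= max_duration
    lt[cens] <- max_duration
    if (all(cens)) stop("all events censored at force ", forces[i])
    ds <- clamp_dataset(forces[i], lt, cens, max_duration)
    fit <- fit_exponential(empirical_survival(ds), order = 1)
    taus[i] <- fit$taus[1]
    errs[i] <- if (is.finite(fit$se[1])) fit$se[1] else NA_real_
  }
  err <- if (all(is.finite(errs)) && all(errs > 0)) errs else NULL
  as_lifetime_force_curve(forces, taus, err)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d/%d replicates usable, n = %d events/force, %d forces\n",
              x$n_used, x$replicates, x$n_per_force, length(x$forces)))
  print(x$summary, digits = 3)
  invisible(x)
}
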