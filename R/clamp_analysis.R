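# Force-clamp survival analysis pipeline: product-limit survival estimation,
# exponential model selection by F-test, Bell fits of slip/ideal regions,
# step detection in clamp traces, and step-height mixture fitting.

#' Lifetime samples at one clamp force
#'
#' @param clamp_force Clamp setpoint, pN.
#' @param lifetimes Per-event bond lifetimes, s, in `(0, max_duration]`.
#' @param censored Logical per event: `TRUE` if the bond survived the whole
#'   clamp window (its lifetime then equals `max_duration`).
#' @param max_duration Clamp duration, s (10 or 20 depending on protocol).
#' @return A `"clamp_dataset"` object.
#' @export
clamp_dataset <- function(clamp_force, lifetimes,
                          censored = rep(FALSE, length(lifetimes)),
                          max_duration = 10) {
  stopifnot(length(censored) == length(lifetimes))
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0")
  if (any(lifetimes > max_duration + 1e-9))
    stop("lifetimes cannot exceed max_duration")
  if (any(censored & abs(lifetimes - max_duration) > 1e-9))
    stop("censored events must have lifetime = max_duration")
  structure(list(clamp_force = clamp_force,
                 lifetimes = as.numeric(lifetimes),
                 censored = as.logical(censored),
                 max_duration = max_duration),
            class = "clamp_dataset")
}

#' @export
print.clamp_dataset <- function(x, ...) {
  cat(sprintf("Clamp dataset: %g pN, %d events (%d censored at %g s)\n",
              x$clamp_force, length(x$lifetimes), sum(x$censored),
              x$max_duration))
  invisible(x)
}

#' Empirical bond survival probability
#'
#' Product-limit (Kaplan-Meier) estimate of `S(t)`, the fraction of bonds
#' surviving beyond time t at the clamp force. Events that survive the whole
#' clamp window are treated as right-censored; with no censoring the
#' estimator reduces to the naive counting fraction.
#'
#' @param dataset A [clamp_dataset()].
#' @return A `"survival_curve"` with the step-function values at `t = 0` and
#'   each event time.
#' @export
empirical_survival <- function(dataset) {
  stopifnot(inherits(dataset, "clamp_dataset"))
  if (!any(!dataset$censored))
    stop("need at least one uncensored (observed) dissociation event")
  fit <- survival::survfit(
    survival::Surv(dataset$lifetimes, !dataset$censored) ~ 1)
  structure(list(times = c(0, fit$time), survival = c(1, fit$surv)),
            n_events = length(dataset$lifetimes),
            force = dataset$clamp_force, class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Right-continuous step interpolation for empirical curves; linear
#' interpolation would bias exponential fits of step estimators.
#'
#' @param curve A `"survival_curve"`.
#' @param t Times, s.
#' @return Survival values.
#' @export
eval_survival <- function(curve, t) {
  idx <- findInterval(t, curve$times)
  idx[idx < 1] <- 1
  curve$survival[idx]
}

#' Fit exponential decay models to a survival curve
#'
#' Least-squares fit of `S(t) = exp(-t/tau)` (order 1) or
#' `S(t) = A exp(-t/tau1) + (1-A) exp(-t/tau2)` (order 2, `tau1 < tau2`
#' enforced by ordering) to the survival values, mirroring how mean bond
#' lifetimes are extracted from force-clamp survival curves.
#'
#' @param curve A `"survival_curve"` (empirical or model).
#' @param order 1 (mono-) or 2 (bi-exponential).
#' @return An `"exp_fit"`: list with `order`, `taus`, `amplitudes` (sum to
#'   1), `rss`, `dof`, `se` (parameter standard errors), `fitted`.
#' @export
fit_exponential <- function(curve, order = 1) {
  stopifnot(order %in% c(1, 2))
  t <- curve$times; s <- curve$survival
  keep <- is.finite(t) & is.finite(s)
  t <- t[keep]; s <- s[keep]
  if (length(t) < 2 + 2 * order) stop("too few points for an exponential fit")
  tau_init <- tau_init_from_curve(t, s)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-12,
                                     ftol = 1e-12)
  if (order == 1) {
    model <- function(p) exp(-t / p[1])
    lower <- 1e-9; upper <- 1e9
    starts <- list(tau_init, tau_init / 3, tau_init * 3)
  } else {
    model <- function(p) p[1] * exp(-t / p[2]) + (1 - p[1]) * exp(-t / p[3])
    lower <- c(0, 1e-9, 1e-9); upper <- c(1, 1e9, 1e9)
    starts <- list(c(0.5, tau_init / 4, tau_init * 2),
                   c(0.3, tau_init / 10, tau_init),
                   c(0.7, tau_init / 2, tau_init * 4))
  }
  best <- NULL; tried <- character(0)
  for (st in starts) {
    f <- tryCatch(minpack.lm::nls.lm(par = st, fn = function(p) model(p) - s,
                                     lower = lower, upper = upper,
                                     control = ctrl),
                  error = function(e) NULL)
    tried <- c(tried, paste(signif(unlist(st), 3), collapse = "/"))
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
      best <- f
  }
  if (is.null(best))
    stop(if (order == 1) "mono" else "bi",
         "-exponential fit failed to converge; starts tried: ",
         paste(tried, collapse = "; "))
  p_hat <- best$par
  fitted <- model(p_hat)
  rss <- best$deviance
  dof <- length(t) - (2 * order - 1)
  se <- exp_fit_se(model, p_hat, s, rss, dof, lower, upper)
  if (order == 1) {
    taus <- p_hat[1]; amps <- 1
  } else {
    ord <- order(p_hat[2:3])
    taus <- p_hat[2:3][ord]
    amps <- c(p_hat[1], 1 - p_hat[1])[ord]
    se <- c(se[1], se[2:3][ord])
  }
  structure(list(order = order, taus = as.numeric(taus),
                 amplitudes = as.numeric(amps),
                 rss = rss, dof = dof,
                 se = se, fitted = fitted, times = t, survival = s),
            class = "exp_fit")
}

# Gauss-Newton standard errors from a finite-difference Jacobian; tolerant
# of degenerate solutions (an amplitude pinned at a bound makes the other
# component parameters unidentifiable).
exp_fit_se <- function(model, p, s, rss, dof, lower, upper) {
  k <- length(p)
  J <- matrix(NA_real_, length(s), k)
  for (j in seq_len(k)) {
    h <- max(1e-6 * abs(p[j]), 1e-8)
    up <- p; up[j] <- min(up[j] + h, upper[j])
    dn <- p; dn[j] <- max(dn[j] - h, lower[j])
    J[, j] <- (model(up) - model(dn)) / (up[j] - dn[j])
  }
  cov <- tryCatch(rss / max(dof, 1) * solve(crossprod(J)),
                  error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) < 0)) return(rep(NA_real_, k))
  sqrt(diag(cov))
}

tau_init_from_curve <- function(t, s) {
  # crude initial tau: time at which the curve crosses 1/e, else trapezoid
  below <- which(s <= exp(-1))
  if (length(below) > 0 && below[1] > 1) return(max(t[below[1]], 1e-6))
  max(sum(diff(t) * (head(s, -1) + tail(s, -1)) / 2), 1e-6)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%s-exponential survival fit: tau = %s s (amplitudes %s), RSS = %.4g, dof = %d\n",
              if (x$order == 1) "Mono" else "Bi",
              paste(signif(x$taus, 4), collapse = ", "),
              paste(signif(x$amplitudes, 3), collapse = ", "),
              x$rss, x$dof))
  invisible(x)
}

#' F-test selection between nested exponential survival models
#'
#' `F = ((RSS1 - RSS2)/(dof1 - dof2)) / (RSS2/dof2)`; the bi-exponential is
#' selected iff its improvement is significant at `alpha`.
#'
#' @param fit1,fit2 [fit_exponential()] results of order 1 and 2 on the same
#'   curve.
#' @param alpha Significance level (default 0.05).
#' @return Integer 1 or 2 (selected order) with attributes `F`, `p`.
#' @export
select_model_ftest <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(fit1$order == 1, fit2$order == 2)
  if (length(fit1$times) != length(fit2$times))
    stop("fits must be on identical data")
  df1 <- fit1$dof - fit2$dof
  if (fit2$rss <= .Machine$double.eps^2) {
    sel <- if (fit1$rss > .Machine$double.eps^2) 2L else 1L
    return(structure(sel, F = Inf, p = 0))
  }
  Fstat <- ((fit1$rss - fit2$rss) / df1) / (fit2$rss / fit2$dof)
  Fstat <- max(Fstat, 0)
  p <- pf(Fstat, df1, fit2$dof, lower.tail = FALSE)
  structure(if (p < alpha) 2L else 1L, F = Fstat, p = p)
}

#' Bell-model fit of a slip (or ideal) region of a lifetime-force curve
#'
#' Fits `<tau> = tau0 * exp(-f / f*)` over a force window (slip region), or
#' the force-insensitive `<tau> = tau0` (ideal region). The percent fit
#' error is `100 * RMS(residual) / mean(fitted)` over the window.
#'
#' @param curve A `"lifetime_force_curve"`.
#' @param force_window `c(min, max)` window in pN (inclusive).
#' @param region `"slip"` or `"ideal"`.
#' @return A `"bell_slip_fit"`: list with `tau0` (s), `f_star` (pN, `Inf`
#'   with `ideal_flag = TRUE` when the window is force-insensitive),
#'   `fit_error_percent`, `se`.
#' @export
fit_bell_slip <- function(curve, force_window, region = c("slip", "ideal")) {
  region <- match.arg(region)
  f <- curve$force_pN; tau <- curve$lifetime_s
  keep <- f >= force_window[1] & f <= force_window[2]
  if (sum(keep) < 3) stop("need >= 3 points inside the force window")
  f <- f[keep]; tau <- tau[keep]
  if (region == "ideal") {
    tau0 <- mean(tau)
    res <- tau - tau0
    return(structure(list(tau0 = tau0, f_star = Inf, ideal_flag = TRUE,
                          fit_error_percent = 100 * sqrt(mean(res^2)) / tau0,
                          se = c(tau0 = sd(tau) / sqrt(length(tau)))),
                     class = "bell_slip_fit"))
  }
  # log-linear start, then nonlinear refinement on the natural scale
  lmfit <- lm(log(tau) ~ f)
  slope <- coef(lmfit)[[2]]
  start <- list(tau0 = exp(coef(lmfit)[[1]]),
                fstar = if (slope < -1e-12) -1 / slope else 1e6)
  fit <- minpack.lm::nlsLM(tau ~ tau0 * exp(-f / fstar), start = start,
                           lower = c(1e-12, 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  res <- tau - predict(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  structure(list(tau0 = cf[["tau0"]], f_star = cf[["fstar"]],
                 ideal_flag = cf[["fstar"]] > 50 * diff(range(f)),
                 fit_error_percent = 100 * sqrt(mean(res^2)) / mean(predict(fit)),
                 se = se),
            class = "bell_slip_fit")
}

#' @export
print.bell_slip_fit <- function(x, ...) {
  if (is.finite(x$f_star))
    cat(sprintf("Bell slip fit: tau0 = %.4g s, f* = %.4g pN (%.2g%% fit error)%s\n",
                x$tau0, x$f_star, x$fit_error_percent,
                if (isTRUE(x$ideal_flag)) " [force-insensitive: f* >> window]" else ""))
  else
    cat(sprintf("Ideal-region fit: tau0 = %.4g s (%.2g%% fit error)\n",
                x$tau0, x$fit_error_percent))
  invisible(x)
}

#' Detect unfolding steps in a force-clamp trace
#'
#' Unfolding events appear as brief force spikes (the clamp force
#' momentarily drops while the feedback re-extends) accompanied by a
#' discrete gain in tip-surface height. Events are detected as contiguous
#' runs where the force falls below `setpoint - force_drop_sigma * noise SD`
#' and quantified by the difference of windowed medians of the height before
#' and after the run.
#'
#' @param trace A `"clamp_trace"` (see [generate_trace()]) or data.frame
#'   with columns `time_s`, `force_pN`, `height_nm` and attributes
#'   `setpoint` (pN) and `sampling_rate` (Hz).
#' @param force_drop_sigma Detection threshold in units of the plateau force
#'   noise SD (default 3).
#' @param min_height_nm Minimum height gain to report (default 1 nm).
#' @param min_run Minimum number of consecutive below-threshold samples
#'   (default 3).
#' @param median_window_s Half-window for the before/after height medians,
#'   s (default 0.05).
#' @return A data.frame of step events: `time_s`, `height_gain_nm`,
#'   `spike_duration_s`.
#' @export
detect_steps <- function(trace, force_drop_sigma = 3, min_height_nm = 1,
                         min_run = 3, median_window_s = 0.05) {
  setpoint <- attr(trace, "setpoint")
  rate <- attr(trace, "sampling_rate")
  if (is.null(setpoint) || is.null(rate))
    stop("trace needs 'setpoint' and 'sampling_rate' attributes")
  f <- trace$force_pN; h <- trace$height_nm; tm <- trace$time_s
  # plateau check: most samples must sit near the setpoint
  near <- abs(f - setpoint) < max(0.25 * abs(setpoint), 5)
  if (mean(near) < 0.5)
    stop("no clamp plateau found: force is not held at the setpoint")
  # robust noise SD from first differences (insensitive to rare spikes)
  noise_sd <- mad(diff(f)) / sqrt(2)
  if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- 1e-6
  # median-smooth before thresholding so noise cannot fragment a spike run
  k <- max(3L, round(median_window_s * rate / 2) * 2L + 1L)
  fs <- if (length(f) > k) as.numeric(stats::runmed(f, k)) else f
  thr <- setpoint - force_drop_sigma * noise_sd
  below <- fs < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_run)
  w <- max(1L, round(median_window_s * rate))
  out <- list()
  for (k in runs) {
    i0 <- starts[k]; i1 <- ends[k]
    pre <- h[max(1, i0 - w):max(1, i0 - 1)]
    post <- h[min(length(h), i1 + 1):min(length(h), i1 + w)]
    gain <- median(post) - median(pre)
    if (is.finite(gain) && gain >= min_height_nm)
      out[[length(out) + 1]] <- data.frame(
        time_s = tm[i0], height_gain_nm = gain,
        spike_duration_s = (i1 - i0 + 1) / rate)
  }
  if (length(out) == 0)
    return(data.frame(time_s = numeric(0), height_gain_nm = numeric(0),
                      spike_duration_s = numeric(0)))
  do.call(rbind, out)
}

#' Gaussian mixture fit of unfolding step heights
#'
#' Fits an `n_components` Gaussian mixture to pooled step heights and
#' returns the ordered component means - the most probable step heights.
#'
#' @param heights Step heights, nm.
#' @param n_components Number of mixture components (>= 1).
#' @return A `"step_height_fit"`: list with sorted `means` (nm), `sds`,
#'   `proportions`, `mean_se` (approximate standard errors of the means),
#'   and the underlying `mclust` model.
#' @export
fit_step_height_mixture <- function(heights, n_components = 4) {
  stopifnot(n_components >= 1)
  if (length(heights) < 5 * n_components)
    stop("too few step heights for ", n_components, " components")
  # equal-variance hierarchical initialization: the default pairing is
  # unstable for well-separated 1-d mixtures with unequal weights
  init <- mclust::hc(heights, modelName = "E", use = "VARS")
  fit <- mclust::Mclust(heights, G = n_components, modelNames = "V",
                        initialization = list(hcPairs = init),
                        verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit did not converge")
  mu <- as.numeric(fit$parameters$mean)
  sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sdv) == 1) sdv <- rep(sdv, n_components)
  pro <- as.numeric(fit$parameters$pro)
  if (any(pro < 1e-6)) warning("mixture component collapsed (weight ~ 0)")
  ord <- order(mu)
  nk <- pmax(pro[ord] * length(heights), 1)
  structure(list(means = mu[ord], sds = sdv[ord], proportions = pro[ord],
                 mean_se = sdv[ord] / sqrt(nk), model = fit),
            class = "step_height_fit")
}

#' @export
print.step_height_fit <- function(x, ...) {
  cat("Step-height mixture fit (nm): ",
      paste(sprintf("%.2f +/- %.2f", x$means, x$mean_se), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
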