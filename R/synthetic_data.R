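# Synthetic force-clamp data generator. Emulates what the AFM delivers to
# the analysis pipeline: per-force bond-lifetime samples (with censoring at
# the clamp duration and an optional short-lived second component at high
# force) and time/force/height traces with clamp plateaus, transient force
# spikes and discrete height steps from domain unfolding.

#' Recipe for a synthetic force-clamp trace
#'
#' @param clamp_force Clamp setpoint, pN.
#' @param max_duration Clamp window, s (default 10, as in the standard
#'   protocol; 20 for the long-protocol variant).
#' @param sampling_rate Sampling rate, Hz (default 500).
#' @param force_noise_sd Gaussian force noise SD on the plateau, pN
#'   (default 2).
#' @param height_noise_sd Gaussian height noise SD, nm (default 0.5).
#' @param step_classes data.frame with columns `mean_nm`, `sd_nm`, `k_u0`,
#'   `x_beta_u`: the height-step classes and their Bell unfolding kinetics.
#'   Default: the two dominant classes (~5.3 and ~11.5 nm).
#' @param spike_duration_s Duration of the transient force dip that
#'   accompanies each unfolding step, s (default 0.16).
#' @param spike_drop_pN Depth of the force dip, pN (default 8).
#' @param kinetics [sliding_rebinding_params()] used to draw the
#'   dissociation time (default: the bundled wild-type interface fit).
#' @param kBT Thermal energy, pN*Angstrom.
#' @return A `"trace_recipe"` object.
#' @export
trace_recipe <- function(clamp_force, max_duration = 10, sampling_rate = 500,
                         force_noise_sd = 2, height_noise_sd = 0.5,
                         step_classes = default_step_classes(),
                         spike_duration_s = 0.16, spike_drop_pN = 8,
                         kinetics = NULL, kBT = .KBT_DEFAULT) {
  if (is.null(kinetics)) kinetics <- load_params("interface_wt")
  if (!is.null(step_classes)) {
    stopifnot(all(c("mean_nm", "sd_nm", "k_u0", "x_beta_u") %in%
                    names(step_classes)))
    if (anyDuplicated(step_classes$mean_nm))
      stop("step class means must be distinct")
  }
  stopifnot(max_duration > 0, sampling_rate > 0, spike_duration_s > 0)
  structure(list(clamp_force = clamp_force, max_duration = max_duration,
                 sampling_rate = sampling_rate,
                 force_noise_sd = force_noise_sd,
                 height_noise_sd = height_noise_sd,
                 step_classes = step_classes,
                 spike_duration_s = spike_duration_s,
                 spike_drop_pN = spike_drop_pN,
                 kinetics = kinetics, kBT = kBT),
            class = "trace_recipe")
}

#' The two dominant unfolding step classes
#'
#' Most frequent extension ~5.3 nm, next ~11.5 nm; Bell kinetics from the
#' bundled per-class unfolding fits (~5 and ~12 nm classes).
#' @return data.frame with `mean_nm`, `sd_nm`, `k_u0`, `x_beta_u`.
#' @export
default_step_classes <- function() {
  data.frame(mean_nm = c(5.3, 11.5), sd_nm = c(0.8, 1.0),
             k_u0 = c(0.17, 0.45), x_beta_u = c(2.3, 1.0))
}

#' Generate synthetic per-force lifetime datasets
#'
#' Lifetimes are drawn from the kinetic model by exact stochastic sampling
#' and censored at the clamp duration. In the optional high-force mode a
#' short-lived (~1 s) exponential component is mixed in above 70 pN with a
#' force-increasing (logistic) weight, reproducing the emergence of
#' bi-exponential survival decays at high force.
#'
#' @param params Generating [sliding_rebinding_params()].
#' @param forces Clamp forces, pN.
#' @param n_per_force Events per force.
#' @param seed Integer seed.
#' @param bi_exp_highforce Mix in the short-lived component above
#'   `bi_exp_onset`?
#' @param bi_exp_onset Onset force of the short-lived component, pN
#'   (default 70).
#' @param bi_exp_tau Mean of the short-lived component, s (default 1).
#' @param max_duration Clamp window for censoring, s.
#' @return A list of [clamp_dataset()] objects, one per force.
#' @export
generate_lifetime_dataset <- function(params, forces, n_per_force,
                                      seed = 1, bi_exp_highforce = FALSE,
                                      bi_exp_onset = 70, bi_exp_tau = 1,
                                      max_duration = 10) {
  stopifnot(n_per_force >= 1)
  out <- vector("list", length(forces))
  for (i in seq_along(forces)) {
    f <- forces[i]
    lt <- gillespie_lifetimes(params, f, n_per_force, seed = seed * 173 + i)
    if (bi_exp_highforce && f > bi_exp_onset) {
      # weight rises smoothly from 0 at the onset towards ~0.5 far above it
      w <- 0.5 / (1 + exp(-(f - bi_exp_onset) / 10)) - 0.25
      w <- max(0, 2 * w)
      short <- runif(n_per_force) < w
      lt[short] <- rexp(sum(short), rate = 1 / bi_exp_tau)
    }
    cens <- lt >= max_duration
    lt[cens] <- max_duration
    out[[i]] <- clamp_dataset(f, lt, cens, max_duration)
  }
  names(out) <- as.character(forces)
  out
}

#' Generate a synthetic force-clamp trace
#'
#' Builds a time/force/height trace: a clamp plateau with Gaussian force
#' noise, unfolding events injected at Bell-rate-distributed times (each a
#' discrete height gain drawn from its step class, accompanied by a
#' transient force dip of the recipe's spike duration), terminated at a
#' dissociation time drawn from the kinetic model.
#'
#' @param recipe A [trace_recipe()].
#' @param seed Integer seed.
#' @return A `"clamp_trace"` data.frame with columns `time_s`, `force_pN`,
#'   `height_nm`; attributes `setpoint`, `sampling_rate`, `events` (the
#'   injected steps) and `dissociation_s`.
#' @export
generate_trace <- function(recipe, seed = 1) {
  stopifnot(inherits(recipe, "trace_recipe"))
  set.seed(seed)
  f0 <- recipe$clamp_force
  rate <- recipe$sampling_rate
  t_diss <- gillespie_lifetimes(recipe$kinetics, f0, 1,
                                seed = seed * 509 + 7)
  t_end <- min(t_diss, recipe$max_duration)
  nsamp <- max(2L, ceiling(t_end * rate))
  tm <- seq_len(nsamp) / rate
  set.seed(seed * 977 + 13)
  force <- f0 + rnorm(nsamp, 0, recipe$force_noise_sd)
  height <- rnorm(nsamp, 0, recipe$height_noise_sd)
  events <- data.frame(time_s = numeric(0), height_gain_nm = numeric(0),
                       class = integer(0))
  if (!is.null(recipe$step_classes) && nrow(recipe$step_classes) > 0) {
    for (k in seq_len(nrow(recipe$step_classes))) {
      cl <- recipe$step_classes[k, ]
      ku <- bell_rate(cl$k_u0, cl$x_beta_u, f0, recipe$kBT)
      if (ku <= 0) next
      # renewal process of unfolding events within the trace
      tev <- cumsum(rexp(50, ku))
      tev <- tev[tev < t_end - recipe$spike_duration_s]
      for (te in tev) {
        gain <- max(rnorm(1, cl$mean_nm, cl$sd_nm), 0.5)
        i0 <- max(1L, ceiling(te * rate))
        i1 <- min(nsamp, i0 + round(recipe$spike_duration_s * rate) - 1L)
        force[i0:i1] <- force[i0:i1] - recipe$spike_drop_pN
        height[i0:nsamp] <- height[i0:nsamp] + gain
        events <- rbind(events, data.frame(time_s = te,
                                           height_gain_nm = gain,
                                           class = k))
      }
    }
    events <- events[order(events$time_s), , drop = FALSE]
  }
  structure(data.frame(time_s = tm, force_pN = force, height_nm = height),
            setpoint = f0, sampling_rate = rate, events = events,
            dissociation_s = t_diss,
            class = c("clamp_trace", "data.frame"))
}

#' Generate per-force unfolding counts for the dominant step classes
#'
#' Poisson counts with means proportional to the Bell unfolding
#' probabilities of each class at each force, evaluated over the class's
#' characteristic dwell (the clamp window), scaled by the exposure (events
#' recorded per force).
#'
#' @param class_params List of [unfolding_class_params()] (first two
#'   classes are used).
#' @param forces Clamp forces, pN.
#' @param exposure Events recorded per force (>= 1).
#' @param seed Integer seed.
#' @param dwell Representative time under load, s (default 1).
#' @param kBT Thermal energy, pN*Angstrom.
#' @return An [unfolding_counts()] table.
#' @export
generate_unfolding_counts <- function(class_params, forces, exposure,
                                      seed = 1, dwell = 1,
                                      kBT = .KBT_DEFAULT) {
  stopifnot(exposure >= 1)
  set.seed(seed)
  p1 <- unfolding_probability(
    unfolding_rate(class_params[[1]], forces, kBT), dwell)
  p2 <- unfolding_probability(
    unfolding_rate(class_params[[2]], forces, kBT), dwell)
  n1 <- rpois(length(forces), exposure * p1)
  n2 <- rpois(length(forces), exposure * p2)
  unfolding_counts(forces, n1, n2)
}
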