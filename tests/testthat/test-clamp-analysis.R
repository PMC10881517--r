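test_that("the empirical survival estimator is a proper survival function", {
  ds <- clamp_dataset(40, c(1, 2, 4))
  sv <- empirical_survival(ds)
  expect_equal(sv$survival[1], 1)
  expect_equal(eval_survival(sv, 1.5), 2 / 3)
  expect_true(all(diff(sv$survival) <= 0))
  expect_true(all(sv$survival >= 0 & sv$survival <= 1))

  # product-limit equals the naive counting fraction without censoring
  set.seed(8)
  lt <- rexp(200, 1 / 3)
  sv2 <- empirical_survival(clamp_dataset(40, lt, max_duration = 1e6))
  tq <- quantile(lt, c(0.2, 0.5, 0.8))
  expect_equal(eval_survival(sv2, tq),
               vapply(tq, function(t) mean(lt > t), 1),
               ignore_attr = TRUE)

  # all-censored datasets carry no dissociation information
  expect_error(empirical_survival(
    clamp_dataset(40, rep(10, 5), rep(TRUE, 5), max_duration = 10)),
    "uncensored")
  # dataset invariants
  expect_error(clamp_dataset(40, c(-1, 2)), "> 0")
  expect_error(clamp_dataset(40, c(1, 12), max_duration = 10), "exceed")
  expect_error(clamp_dataset(40, c(1, 5), censored = c(FALSE, TRUE),
                             max_duration = 10), "censored")
})

test_that("exponential survival fits recover mono- and bi-exponential decays", {
  t <- seq(0, 15, 0.1)
  mono <- structure(list(times = t, survival = exp(-t / 3)),
                    class = "survival_curve")
  f1 <- fit_exponential(mono, 1)
  expect_equal(f1$taus, 3, tolerance = 1e-6)

  bi <- structure(list(times = t,
                       survival = 0.4 * exp(-t) + 0.6 * exp(-t / 8)),
                  class = "survival_curve")
  f2 <- fit_exponential(bi, 2)
  expect_equal(f2$taus, c(1, 8), tolerance = 1e-4)
  expect_equal(f2$amplitudes, c(0.4, 0.6), tolerance = 1e-4)
  expect_lt(f2$taus[1], f2$taus[2])
  expect_equal(sum(f2$amplitudes), 1, tolerance = 1e-9)

  # nested models: order-2 RSS never exceeds order-1 RSS
  set.seed(13)
  for (i in 1:5) {
    s_noisy <- pmax(exp(-t / runif(1, 1, 5)) + rnorm(length(t), 0, 0.02), 0)
    cv <- structure(list(times = t, survival = s_noisy),
                    class = "survival_curve")
    g1 <- fit_exponential(cv, 1); g2 <- fit_exponential(cv, 2)
    expect_lte(g2$rss, g1$rss + 1e-12)
  }
})

test_that("the F-test selects the bi-exponential only when it earns its parameters", {
  t <- seq(0, 15, length.out = 50)
  mk <- function(s) structure(list(times = t, survival = s),
                              class = "survival_curve")
  # identical RSS: F = 0, keep the mono-exponential
  cv <- mk(exp(-t / 3))
  f1 <- fit_exponential(cv, 1); f2 <- fit_exponential(cv, 2)
  sel <- select_model_ftest(f1, f2)
  expect_equal(as.integer(sel), 1L)

  # null simulation: pure mono-exponential + 2% noise, order 1 chosen >= 90%
  set.seed(41)
  picks <- vapply(1:200, function(i) {
    s <- pmin(pmax(exp(-t / 3) + rnorm(length(t), 0, 0.02), 1e-6), 1)
    cv <- mk(s)
    as.integer(select_model_ftest(fit_exponential(cv, 1),
                                  fit_exponential(cv, 2)))
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.9)

  # strong alternative: well-separated bi-exponential is detected
  set.seed(42)
  s <- pmin(pmax(0.5 * exp(-t / 0.5) + 0.5 * exp(-t / 10) +
                   rnorm(length(t), 0, 0.01), 1e-6), 1)
  cv <- mk(s)
  expect_equal(as.integer(select_model_ftest(fit_exponential(cv, 1),
                                             fit_exponential(cv, 2))), 2L)
})

test_that("Bell fits of slip and ideal regions recover the generating parameters", {
  fo <- seq(10, 35, 2.5)
  cv <- as_lifetime_force_curve(fo, 31.8 * exp(-fo / 24.5))
  bf <- fit_bell_slip(cv, c(10, 35))
  expect_equal(bf$tau0, 31.8, tolerance = 1e-6)
  expect_equal(bf$f_star, 24.5, tolerance = 1e-6)
  expect_lt(bf$fit_error_percent, 1e-6)

  fo2 <- seq(80, 150, 10)
  cv2 <- as_lifetime_force_curve(fo2, 8.4 * exp(-fo2 / 231.3))
  bf2 <- fit_bell_slip(cv2, c(80, 150))
  expect_equal(bf2$tau0, 8.4, tolerance = 1e-6)
  expect_equal(bf2$f_star, 231.3, tolerance = 1e-5)

  # constant curve: the ideal fit returns the constant, the slip fit flags
  # a force-insensitive window
  cvc <- as_lifetime_force_curve(seq(36, 70, length.out = 8), rep(6.3, 8))
  fid <- fit_bell_slip(cvc, c(36, 70), region = "ideal")
  expect_equal(fid$tau0, 6.3)
  expect_true(fid$ideal_flag)
  fslip <- fit_bell_slip(cvc, c(36, 70), region = "slip")
  expect_true(fslip$ideal_flag)
  expect_error(fit_bell_slip(cv, c(200, 300)), ">= 3 points")
})

test_that("step detection round-trips injected unfolding events", {
  # one injected ~5.3 nm step
  rec <- trace_recipe(clamp_force = 40, max_duration = 4,
                      step_classes = data.frame(mean_nm = 5.3, sd_nm = 1e-6,
                                                k_u0 = 0.3, x_beta_u = 0))
  found <- 0L; tested <- 0L
  for (s in 1:30) {
    tr <- generate_trace(rec, seed = s)
    ev <- attr(tr, "events")
    if (nrow(ev) != 1) next
    tested <- tested + 1L
    st <- detect_steps(tr)
    if (nrow(st) == 1 && abs(st$height_gain_nm - ev$height_gain_nm) < 0.5)
      found <- found + 1L
  }
  expect_gte(tested, 5L)
  expect_gte(found / tested, 0.95)

  # two well-separated steps are reported in order (slow-dissociating
  # kinetics guarantee a long plateau)
  slow <- sliding_rebinding_params(0.01, 0.1, variant = "mutant")
  rec2 <- trace_recipe(clamp_force = 40, max_duration = 6,
                       force_noise_sd = 1, step_classes = NULL,
                       kinetics = slow)
  tr2 <- generate_trace(rec2, seed = 5)
  rate <- attr(tr2, "sampling_rate")
  n <- nrow(tr2)
  inject <- function(tr, i0, dur, gain) {
    i1 <- i0 + round(dur * rate)
    tr$force_pN[i0:i1] <- tr$force_pN[i0:i1] - 8
    tr$height_nm[i0:n] <- tr$height_nm[i0:n] + gain
    tr
  }
  tr2 <- inject(tr2, round(0.8 * rate), 0.16, 5.3)
  tr2 <- inject(tr2, round(2.0 * rate), 0.16, 11.5)
  st2 <- detect_steps(tr2)
  expect_equal(nrow(st2), 2)
  expect_lt(abs(st2$height_gain_nm[1] - 5.3), 0.5)
  expect_lt(abs(st2$height_gain_nm[2] - 11.5), 0.5)
  expect_true(all(diff(st2$time_s) > 0))

  # false positives on flat noisy traces are rare at the 3-sigma threshold
  recf <- trace_recipe(clamp_force = 40, max_duration = 4,
                       step_classes = NULL)
  fp <- vapply(1:200, function(s)
    nrow(detect_steps(generate_trace(recf, seed = 1000 + s))), integer(1))
  expect_gte(mean(fp == 0L), 0.99)

  # traces without a plateau are rejected
  bad <- data.frame(time_s = seq(0, 1, 0.01),
                    force_pN = seq(0, 100, length.out = 101),
                    height_nm = 0)
  attr(bad, "setpoint") <- 40; attr(bad, "sampling_rate") <- 100
  expect_error(detect_steps(bad), "plateau")
})

test_that("the step-height mixture fit recovers well-separated component means", {
  set.seed(19)
  h1 <- rnorm(400, 5.2, 0.4)
  m1 <- fit_step_height_mixture(h1, 1)
  expect_lt(abs(m1$means - 5.2), 0.1)

  h4 <- c(rnorm(500, 5.2, 0.9), rnorm(300, 12.9, 1.0),
          rnorm(150, 22.6, 1.1), rnorm(100, 34.3, 1.0))
  m4 <- fit_step_height_mixture(h4, 4)
  expect_lt(max(abs(m4$means - c(5.2, 12.9, 22.6, 34.3))), 1)
  expect_true(all(diff(m4$means) > 0))

  # permutation invariance
  m4b <- fit_step_height_mixture(sample(h4), 4)
  expect_equal(m4$means, m4b$means, tolerance = 1e-6)
  expect_error(fit_step_height_mixture(rnorm(8), 4), "too few")
})
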