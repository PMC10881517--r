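test_that("lifetime datasets are reproducible and round-trip through the survival pipeline", {
  wt <- wt_params()
  d1 <- generate_lifetime_dataset(wt, c(28, 80), 100, seed = 6)
  d2 <- generate_lifetime_dataset(wt, c(28, 80), 100, seed = 6)
  expect_identical(d1[["28"]]$lifetimes, d2[["28"]]$lifetimes)
  expect_s3_class(d1[[1]], "clamp_dataset")
  expect_true(all(d1[[1]]$lifetimes <= d1[[1]]$max_duration))

  # refit at 28 pN recovers the generating mean lifetime within 2 SE
  ds <- generate_lifetime_dataset(wt, 28, 1000, seed = 15)[[1]]
  fit <- fit_exponential(empirical_survival(ds), 1)
  tau_true <- mean_lifetime(wt, 28)
  expect_lt(abs(fit$taus[1] - tau_true), 2 * max(fit$se[1], 0.05 * tau_true))
})

test_that("the high-force mode makes bi-exponential decays emerge above the onset", {
  wt <- wt_params()
  picks <- vapply(1:20, function(r) {
    ds <- generate_lifetime_dataset(wt, 100, 200, seed = 300 + r,
                                    bi_exp_highforce = TRUE)[[1]]
    sv <- empirical_survival(ds)
    as.integer(select_model_ftest(fit_exponential(sv, 1),
                                  fit_exponential(sv, 2)))
  }, integer(1))
  expect_gt(mean(picks == 2L), 0.5)
  # below the onset the mono-exponential still wins mostly
  picks_lo <- vapply(1:10, function(r) {
    ds <- generate_lifetime_dataset(wt, 41, 200, seed = 400 + r,
                                    bi_exp_highforce = TRUE)[[1]]
    sv <- empirical_survival(ds)
    as.integer(select_model_ftest(fit_exponential(sv, 1),
                                  fit_exponential(sv, 2)))
  }, integer(1))
  expect_gte(mean(picks_lo == 1L), 0.7)
})

test_that("generated traces have the advertised plateau structure", {
  # zero noise, no step classes: flat plateau ending at the dissociation time
  rec <- trace_recipe(clamp_force = 40, force_noise_sd = 1e-12,
                      height_noise_sd = 1e-12, step_classes = NULL)
  tr <- generate_trace(rec, seed = 3)
  expect_lt(sd(tr$force_pN), 1e-9)
  expect_equal(mean(tr$force_pN), 40)
  t_end <- min(attr(tr, "dissociation_s"), rec$max_duration)
  expect_equal(nrow(tr), max(2, ceiling(t_end * rec$sampling_rate)))
  # round-trip: with only the ~5.3 nm class and zero noise, every injected
  # event is recovered
  rec2 <- trace_recipe(clamp_force = 40, force_noise_sd = 1e-12,
                       height_noise_sd = 1e-12,
                       step_classes = data.frame(mean_nm = 5.3, sd_nm = 0.3,
                                                 k_u0 = 0.17,
                                                 x_beta_u = 2.3))
  for (s in 4:8) {
    tr2 <- generate_trace(rec2, seed = s)
    ev <- attr(tr2, "events")
    st <- detect_steps(tr2)
    expect_equal(nrow(st), nrow(ev), label = paste("seed", s))
  }
})

test_that("detection sensitivity for ~5.3 nm steps stays above 95% at default noise", {
  rec <- trace_recipe(clamp_force = 40,
                      step_classes = data.frame(mean_nm = 5.3, sd_nm = 0.3,
                                                k_u0 = 0.17, x_beta_u = 2.3))
  injected <- 0L; recovered <- 0L
  for (s in 1:200) {
    tr <- generate_trace(rec, seed = 5000 + s)
    ev <- attr(tr, "events")
    if (nrow(ev) == 0) next
    st <- detect_steps(tr)
    t_end <- max(tr$time_s)
    # sensitivity is defined over resolvable events: isolated from their
    # neighbours and from the trace edges by more than the spike plus the
    # median window
    gap <- 0.16 + 2 * 0.05
    for (k in seq_len(nrow(ev))) {
      others <- ev$time_s[-k]
      if (length(others) && min(abs(others - ev$time_s[k])) < gap) next
      if (ev$time_s[k] < gap || ev$time_s[k] > t_end - gap) next
      injected <- injected + 1L
      if (nrow(st) && min(abs(st$time_s - ev$time_s[k])) < 0.12)
        recovered <- recovered + 1L
    }
  }
  expect_gt(injected, 100)
  expect_gte(recovered / injected, 0.95)
})

test_that("synthetic unfolding counts follow the Bell class probabilities", {
  classes <- load_unfolding_classes()
  # zero rates produce zero counts
  dead <- list(unfolding_class_params(0, 0), unfolding_class_params(0, 0))
  cnt0 <- generate_unfolding_counts(dead, c(20, 60), exposure = 100,
                                    seed = 2)
  expect_true(all(cnt0$n1 == 0 & cnt0$n2 == 0))
  # reproducibility
  c1 <- generate_unfolding_counts(classes, c(20, 60), 100, seed = 5)
  c2 <- generate_unfolding_counts(classes, c(20, 60), 100, seed = 5)
  expect_identical(c1$n1, c2$n1)
  # count ratio converges to the probability ratio at large exposure
  f <- 30
  big <- generate_unfolding_counts(classes, f, exposure = 2e5, seed = 8)
  p1 <- unfolding_probability(unfolding_rate(classes[[1]], f), 1)
  p2 <- unfolding_probability(unfolding_rate(classes[[2]], f), 1)
  expect_equal(big$n1 / big$n2, p1 / p2, tolerance = 0.05)
})
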