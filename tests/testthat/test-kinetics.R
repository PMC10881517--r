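test_that("Bell rates obey the exponential force law and its identities", {
  expect_equal(bell_rate(0.5, 1.0, 0), 0.5)
  expect_equal(bell_rate(0.5, 1.0, 4.114, kBT = 4.114), 0.5 * exp(1),
               tolerance = 1e-12)
  expect_equal(bell_rate(0, 1.0, 123), 0)
  expect_error(bell_rate(0.5, 1.0, NaN), "non-finite")
  expect_error(bell_rate(-1, 1.0, 0), ">= 0")

  p <- chain_params(0.5, 1.0)
  expect_equal(double_bond_rate(p, 0), 2 * 0.5)
  # force chosen so that f * x / (2 kBT) = 1
  expect_equal(double_bond_rate(p, 2 * p$kBT), 1.0 * exp(1),
               tolerance = 1e-9)
  # k_-2(f)/k_-1(f) = 2 exp(-f x / (2 kBT)) for all f
  f <- seq(0, 150, 10)
  expect_equal(double_bond_rate(p, f) / bell_rate(0.5, 1.0, f),
               2 * exp(-f * 1.0 / (2 * p$kBT)), tolerance = 1e-12)
  # monotone increasing in force when x_beta > 0
  expect_true(all(diff(bell_rate(0.5, 1.0, f)) > 0))
})

test_that("the rebinding switch P_n is zero below F_C1, one above F_C2, and cosine-shaped between", {
  p <- sliding_rebinding_params(0.5, 1, 1, 10, F_C1 = 30, F_C2 = 100, n = 1)
  expect_equal(rebinding_probability(p, c(0, 10, 29.9)), rep(0, 3))
  expect_equal(rebinding_probability(p, 100), 1)
  expect_equal(rebinding_probability(p, 150), 1)
  expect_equal(rebinding_probability(p, 50), 0.5)  # cos(pi/2) = 0
  pn <- rebinding_probability(p, seq(0, 200, 1))
  expect_true(all(pn >= 0 & pn <= 1))
  p23 <- sliding_rebinding_params(0.5, 1, 1, 10, F_C1 = 30, F_C2 = 100,
                                  n = 2.3)
  expect_equal(rebinding_probability(p23, 60),
               (0.5 * (1 - cos(pi * 0.6)))^2.3, tolerance = 1e-12)
  # mutant: switch disabled at every force
  m <- mutant_params()
  expect_equal(rebinding_probability(m, c(0, 60, 90, 200)), rep(0, 4))
  expect_error(rebinding_probability(p, -5), ">= 0")
})

test_that("the survival ODE conserves probability and matches the sequential-chain closed form", {
  tg <- seq(0, 20, 0.05)
  for (f in c(0, 41, 80, 143)) {
    sc <- solve_survival(wt_params(), f, tg)
    expect_equal(sc$survival[1], 1)
    states <- attr(sc, "states")
    expect_lt(max(abs(rowSums(states) - 1)), 1e-8)
    expect_true(all(diff(sc$survival) <= 1e-10))
    expect_true(all(sc$survival >= 0 & sc$survival <= 1))
  }
  # closed form: k_plus1 = k_plus2 = 0, P_n = 0 is a linear two-step decay
  p <- chain_params(0.5, 1.0)
  for (f in c(0, 37, 90)) {
    a <- double_bond_rate(p, f)
    b <- 2 * bell_rate(0.5, 1.0, f)
    sc <- solve_survival(p, f, tg)
    expect_equal(sc$survival, chain_survival(tg, a, b), tolerance = 1e-7)
  }
  expect_error(solve_survival(wt_params(), 80, c(1, 2)), "start at 0")
})

test_that("mean lifetime equals the sequential-chain mean first-passage time in the closed-form limit", {
  p <- chain_params(0.5, 1.0)
  expect_equal(mean_lifetime(p, 0), 1 / 1.0 + 1 / 1.0, tolerance = 1e-12)
  for (f in c(5, 37, 90, 140)) {
    mf <- 1 / double_bond_rate(p, f) + 1 / (2 * bell_rate(0.5, 1, f))
    expect_equal(mean_lifetime(p, f), mf, tolerance = 1e-6)
  }
  # divergent when nothing can dissociate
  p0 <- sliding_rebinding_params(0, 1, 1, 0, variant = "mutant")
  expect_error(mean_lifetime(p0, 10), "diverge")
  # expfit estimator close to the exact integral for a near-exponential decay
  expect_equal(mean_lifetime(wt_params(), 80, "expfit"),
               mean_lifetime(wt_params(), 80), tolerance = 0.05)
})

test_that("lifetime-force curves are slip-catch-slip for the wild type and monotone slip for the mutant", {
  fs <- seq(5, 150, 5)
  cw <- lifetime_force_curve(wt_params(), fs)
  tau <- cw$lifetime_s
  # slip below F_C1: lifetime decreases monotonically
  expect_true(all(diff(tau[fs <= 55]) < 0))
  # catch: an interior local maximum between F_C1 and ~F_C2 that beats both
  # the pre-switch lifetime and the high-force tail
  in_win <- fs > wt_params()$F_C1 & fs <= wt_params()$F_C2 + 10
  peak <- max(tau[in_win])
  f_peak <- fs[in_win][which.max(tau[in_win])]
  expect_gt(peak, tau[fs == 55] * 1.2)
  expect_gt(peak, tau[length(tau)] * 1.2)
  expect_lt(f_peak, wt_params()$F_C2 + 10)
  # second slip: decreasing beyond the peak
  expect_true(all(diff(tau[fs >= f_peak]) < 0))
  cm <- lifetime_force_curve(mutant_params(), fs)
  expect_true(all(diff(cm$lifetime_s) < 0))
})

test_that("multiplying all rates by c rescales all lifetimes by 1/c at fixed P_n", {
  base <- sliding_rebinding_params(0.5, 1.0, 2.8, 30.2, F_C1 = 58,
                                   F_C2 = 100, n = 2.3)
  for (c0 in c(0.2, 3)) {
    scaled <- sliding_rebinding_params(0.5 * c0, 1.0, 2.8 * c0, 30.2 * c0,
                                       F_C1 = 58, F_C2 = 100, n = 2.3)
    f <- c(10, 70, 120)
    expect_equal(vapply(f, function(ff) mean_lifetime(scaled, ff), 1),
                 vapply(f, function(ff) mean_lifetime(base, ff), 1) / c0,
                 tolerance = 1e-10)
  }
})

test_that("the mutant scheme equals the full scheme with the rebinding switch forced off", {
  m <- mutant_params()
  wt_off <- sliding_rebinding_params(m$k_minus1_0, m$x_beta, m$k_plus1,
                                     m$k_plus2, F_C1 = 1e7, F_C2 = 1e7,
                                     n = 1, variant = "WT")
  fs <- seq(5, 150, 15)
  expect_equal(lifetime_force_curve(m, fs)$lifetime_s,
               lifetime_force_curve(wt_off, fs)$lifetime_s,
               tolerance = 1e-10)
})

test_that("Gillespie sampling is seed-reproducible and agrees with the deterministic solution", {
  p <- wt_params()
  lt1 <- gillespie_lifetimes(p, 80, 500, seed = 11)
  lt2 <- gillespie_lifetimes(p, 80, 500, seed = 11)
  expect_identical(lt1, lt2)
  expect_false(identical(lt1, gillespie_lifetimes(p, 80, 500, seed = 12)))

  # closed-form chain: sample mean within 3 SE of the exact MFPT
  pc <- chain_params(0.5, 1.0)
  lt <- gillespie_lifetimes(pc, 0, 10000, seed = 21)
  mf <- 2.0
  expect_lt(abs(mean(lt) - mf), 3 * sd(lt) / sqrt(length(lt)))

  # KS distance between empirical and model survival
  for (f in c(28, 103)) {
    lt <- gillespie_lifetimes(p, f, 4000, seed = 31 + f)
    expect_lt(ks_distance_model(lt, p, f), 0.025)
  }
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(sliding_rebinding_params(-0.1, 1), "rates")
  expect_error(sliding_rebinding_params(0.5, -1), "x_beta")
  expect_error(sliding_rebinding_params(0.5, 1, F_C1 = 120, F_C2 = 100),
               "F_C1")
  expect_error(sliding_rebinding_params(0.5, 1, n = 0), "n must")
  expect_error(sliding_rebinding_params(0.5, 1, kBT = -1), "kBT")
  expect_error(as_lifetime_force_curve(c(10, 10), c(1, 1)),
               "strictly increasing")
  expect_error(as_lifetime_force_curve(c(10, 20), c(1, -1)), "> 0")
})
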