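test_that("reduced-to-physical conversions reproduce the standard anchors", {
  u <- reduced_units()
  expect_equal(to_physical(1, "force", u), 0.42, tolerance = 1e-12)
  expect_equal(to_physical(1, "time", u), 2.381e-3, tolerance = 1e-3)
  expect_equal(to_physical(0, "length", u), 0)
  expect_equal(to_physical(5.1, "bending", u), 2.142e-4, tolerance = 1e-12)
  expect_equal(to_physical(15, "stiffness", u), 0.63, tolerance = 1e-12)
  expect_error(to_physical(1, "volume", u))
})

test_that("the catch-slip bond rate has the documented minimum and asymptotics", {
  p <- langevin_params()
  expect_equal(catch_slip_rate(0, p), 0.100004, tolerance = 1e-9)
  fstar <- catch_slip_optimum(p)
  expect_equal(fstar, log(12500) / 0.3, tolerance = 1e-12)
  # numeric minimum agrees with the closed form
  fgrid <- seq(0, 100, 0.01)
  expect_equal(fgrid[which.min(catch_slip_rate(fgrid, p))], fstar,
               tolerance = 1e-3)
  # slip term dominates far beyond the optimum
  f <- 200
  expect_equal(catch_slip_rate(f, p) / (p$omega0_1 * exp(f / p$f_d1)), 1,
               tolerance = 1e-6)
  expect_error(catch_slip_rate(-1, p), ">= 0")
})

test_that("energy terms match hand-evaluated configurations", {
  # straight chain at rest length: no stretching, no bending
  pos <- cbind(0:9, 0)
  expect_equal(stretching_energy(pos)$energy, 0)
  expect_equal(bending_energy(pos)$energy, 0)
  # single bond stretched to 1.1 sigma: A/(2 sigma) (0.1 sigma)^2
  pos2 <- cbind(c(0, 1.1), 0)
  expect_equal(stretching_energy(pos2, A = 5e3)$energy, 0.005 * 5e3,
               tolerance = 1e-9)
  # right-angle kink: kappa / sigma
  kink <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(bending_energy(kink, kappa = 5.1)$energy, 5.1,
               tolerance = 1e-12)
  # WCA: zero at the cutoff, eps at r = sigma, continuous force at cutoff
  r0 <- 2^(1 / 6)
  expect_equal(wca_energy(rbind(c(0, 0), c(5, 5), c(r0, 0)))$energy, 0,
               tolerance = 1e-12)
  w1 <- wca_energy(rbind(c(0, 0), c(5, 5), c(1, 0)), eps_wca = 1)
  expect_equal(w1$energy, 1, tolerance = 1e-12)
  wnear <- wca_energy(rbind(c(0, 0), c(5, 5), c(r0 - 1e-7, 0)))
  expect_lt(max(abs(wnear$forces)), 1e-4)
  expect_error(stretching_energy(cbind(c(0, 0), c(0, 0))), "coincident")
})

test_that("analytic forces equal central finite differences of the energies", {
  set.seed(33)
  n <- 8
  pos <- cbind(seq_len(n) - 1, 0) + matrix(rnorm(2 * n, 0, 0.05), n, 2)
  checks <- list(
    list(f = function(p) stretching_energy(p, A = 100)$energy,
         g = stretching_energy(pos, A = 100)$forces),
    list(f = function(p) bending_energy(p, kappa = 5.1)$energy,
         g = bending_energy(pos, kappa = 5.1)$forces))
  # squashed configuration so several WCA pairs are active
  pwca <- pos; pwca[, 1] <- pwca[, 1] * 0.55
  checks[[3]] <- list(f = function(p) wca_energy(p, eps_wca = 1)$energy,
                      g = wca_energy(pwca, eps_wca = 1)$forces)
  poslist <- list(pos, pos, pwca)
  for (k in seq_along(checks)) {
    num <- fd_forces(poslist[[k]], checks[[k]]$f)
    scale <- max(abs(num), 1)
    expect_lt(max(abs(num - checks[[k]]$g)) / scale, 1e-6,
              label = paste("energy term", k))
  }
})

test_that("arrangements are built with the documented topology", {
  p <- langevin_params()
  d <- build_arrangement("dimer", p, n_b = 10)
  expect_equal(nrow(d$breakable), 10)
  expect_equal(length(d$fixed), 1)
  expect_equal(nrow(d$permanent), 0)
  tf <- build_arrangement("tetramer_free", p, n_b = 10)
  expect_equal(nrow(tf$breakable), 20)
  expect_equal(length(tf$fixed), 2)
  tx <- build_arrangement("tetramer_crosslinked", p, n_b = 10)
  expect_equal(nrow(tx$breakable), 20)
  expect_equal(nrow(tx$permanent), nrow(tf$permanent) + 3)
  # bond rest lengths equal the construction separations
  expect_true(all(d$breakable[, 3] == 1))
  expect_error(build_arrangement("dimer", p, n_b = 50), "n_b")
})

test_that("trajectories are deterministic under a fixed seed and stable at near-zero temperature", {
  p <- langevin_params(dt = 0.001)
  sys <- build_arrangement("dimer", p)
  s1 <- langevin_step(sys, p, n_steps = 200, F_e = 10, seed = 5)
  s2 <- langevin_step(sys, p, n_steps = 200, F_e = 10, seed = 5)
  expect_identical(s1$positions, s2$positions)
  s3 <- langevin_step(sys, p, n_steps = 200, F_e = 10, seed = 6)
  expect_false(identical(s1$positions, s3$positions))

  # near-zero temperature, no force, equilibrium configuration: positions
  # stay put (a straight free chain at rest spacing is a fixed point; the
  # dimer is not one, since excluded volume preloads its cross-filament
  # bonds)
  pcold <- langevin_params(kBT = 1e-18)
  chain <- structure(list(positions = cbind(0:9, 0), chain_starts = 0L,
                          chain_lengths = 10L,
                          breakable = matrix(numeric(0), 0, 3),
                          permanent = matrix(numeric(0), 0, 4),
                          fixed = integer(0),
                          pulled = matrix(numeric(0), 0, 3),
                          tag = "free", n_b = 0L),
                     class = "filament_system")
  out <- langevin_step(chain, pcold, n_steps = 500, F_e = 0, seed = 1,
                       rupture = FALSE)
  drift <- max(abs(out$positions - chain$positions))
  expect_lt(drift, 1e-6)
})

test_that("the thermostat satisfies equipartition for a free filament", {
  ke <- measure_equipartition(langevin_params(), n_steps = 6e4, seed = 3,
                              burnin = 5000)
  expect_lt(abs(ke - 0.5) / 0.5, 0.05)
})

test_that("the tangent correlation decays with the wormlike-chain persistence length", {
  # at the study discretization the exact decay length of the discrete 2D
  # wormlike chain is -1/ln(I1/I0) = 9.07 sigma; the simulation must
  # reproduce it, and the discrete law itself approaches the continuum
  # 2 kappa / kBT as the chain is refined
  p <- langevin_params()
  lambda <- measure_persistence_length(p, n_runs = 25, n_steps = 3e4,
                                       sample_every = 5000, burnin = 9000,
                                       seed = 7)
  expect_lt(abs(lambda - discrete_persistence_length(p)) /
              discrete_persistence_length(p), 0.05)
  # discretization bias at u = 3.33, N = 35 is ~11% and shrinks with
  # refinement (closed form, no simulation needed)
  expect_lt(abs(discrete_persistence_length(p) - 2 * p$kappa) /
              (2 * p$kappa), 0.15)
  p_fine <- langevin_params(kappa = 20.4)
  expect_lt(abs(discrete_persistence_length(p_fine) - 2 * p_fine$kappa) /
              (2 * p_fine$kappa), 0.05)
})

test_that("single-bond rupture times reproduce the analytic catch-slip rate", {
  p <- langevin_params()
  for (f in c(0, 10, 31.44)) {
    ts <- sample_rupture_times(f, p, n = 2000, seed = 17 + round(f))
    rate_hat <- 1 / mean(ts)
    expect_lt(abs(rate_hat - catch_slip_rate(f, p)) / catch_slip_rate(f, p),
              0.05, label = paste("force", f))
    # KS against the exponential law at the 5% level
    D <- max(abs(seq_along(ts) / length(ts) -
                   (1 - exp(-catch_slip_rate(f, p) * sort(ts)))))
    expect_lt(D, 1.36 / sqrt(length(ts)))
  }
})

test_that("attachment lifetimes behave as documented", {
  p <- langevin_params()
  sys <- build_arrangement("dimer", p)
  nob <- sys; nob$breakable <- matrix(numeric(0), 0, 3)
  expect_equal(run_lifetime(nob, p, 10, seed = 1)$lifetime, 0)
  r1 <- run_lifetime(sys, p, 40, seed = 3, t_max = 2000, n_equil = 500)
  r2 <- run_lifetime(sys, p, 40, seed = 3, t_max = 2000, n_equil = 500)
  expect_identical(r1$lifetime, r2$lifetime)
  expect_gt(r1$lifetime, 0)
  expect_error(lifetime_vs_force("dimer", c(10, 20), n_runs = 1),
               "n_runs >= 2")

  # stochastic dominance: a faster slip channel cannot lengthen the mean
  # attachment lifetime (paired seeds, ensemble means)
  pfast <- langevin_params(omega0_1 = 4e-4)
  lt_slow <- lt_fast <- numeric(6)
  for (r in 1:6) {
    lt_slow[r] <- run_lifetime(sys, p, 60, seed = 100 + r, t_max = 2000,
                               n_equil = 500)$lifetime
    lt_fast[r] <- run_lifetime(sys, pfast, 60, seed = 100 + r,
                               t_max = 2000, n_equil = 500)$lifetime
  }
  expect_lt(mean(lt_fast), mean(lt_slow))
})
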