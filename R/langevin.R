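# Coarse-grained Langevin model: semiflexible bead-spring filaments coupled
# by breakable catch-slip elastic bonds, in dimeric and tetrameric
# (optionally cross-linked) arrangements under constant pulling force.
# All simulation quantities are in reduced units (length sigma, energy kBT,
# time tau = alpha sigma^2 / kBT); to_physical() maps to pN/nm/s.

#' Parameters of the filament Langevin model (reduced units)
#'
#' Defaults are the study conditions: `N = 35` beads per filament,
#' stretching stiffness `A = 5e3 kBT/sigma`, bending rigidity
#' `kappa = 5.1 kBT sigma` (rigidity parameter `u = L/lambda = 3.33` in 2D),
#' inter-filament bond stiffness `k_m = 3e-3 A/sigma`, bare detachment rates
#' `omega0_1 = 4e-6`, `omega0_2 = 0.1` (1/tau), detachment force scales
#' `f_d1 = 5`, `f_d2 = 10` (kBT/sigma), timestep `dt = 0.001 tau`, unit
#' mass and unit friction.
#'
#' @param N Beads per filament.
#' @param A Stretching stiffness, kBT/sigma.
#' @param kappa Bending rigidity, kBT*sigma.
#' @param eps_wca WCA energy scale, kBT.
#' @param k_m Inter-filament bond stiffness, kBT/sigma^2 (default `3e-3 * A`).
#' @param omega0_1,omega0_2 Bare detachment rates (slip and catch channels),
#'   1/tau.
#' @param f_d1,f_d2 Detachment force scales, kBT/sigma.
#' @param dt Timestep, tau.
#' @param mass Bead mass (reduced; 1).
#' @param alpha Friction coefficient (reduced; 1, so the time unit is tau).
#' @param kBT Thermal energy (reduced; 1).
#' @param sigma Bond length (reduced; 1).
#' @return A `"langevin_params"` list.
#' @export
langevin_params <- function(N = 35, A = 5e3, kappa = 5.1, eps_wca = 1,
                            k_m = 3e-3 * A, omega0_1 = 4e-6, omega0_2 = 0.1,
                            f_d1 = 5, f_d2 = 10, dt = 0.001, mass = 1,
                            alpha = 1, kBT = 1, sigma = 1) {
  p <- list(N = as.integer(N), A = A, kappa = kappa, eps_wca = eps_wca,
            k_m = k_m, omega0_1 = omega0_1, omega0_2 = omega0_2,
            f_d1 = f_d1, f_d2 = f_d2, dt = dt, mass = mass, alpha = alpha,
            kBT = kBT, sigma = sigma)
  if (any(unlist(p) <= 0)) stop("all Langevin parameters must be positive")
  if (dt >= 0.1) stop("dt must be << 1 tau")
  structure(p, class = "langevin_params")
}

#' Reduced-to-physical unit mapping
#'
#' The physical anchor points: bond length `sigma = 10 nm`, ambient thermal
#' energy `kBT = 0.0042 pN um`, solvent `gamma = 1 pN s/um^2` giving a bead
#' drag `alpha = 3 pi gamma sigma`, rounded to `0.1 pN s/um` (the rounding
#' convention used throughout, so that printed conversions reproduce
#' exactly). Derived: force unit `kBT/sigma = 0.42 pN`, time unit
#' `tau = alpha sigma^2 / kBT ~ 2.38e-3 s`.
#'
#' @param sigma_nm Bond length, nm.
#' @param kBT_pN_um Thermal energy, pN*um.
#' @param gamma_pN_s_um2 Solvent viscosity parameter, pN*s/um^2.
#' @param alpha_pN_s_um Bead drag; default rounds `3 pi gamma sigma` to one
#'   decimal (0.1 pN s/um for the default anchors).
#' @return A `"reduced_units"` list with the anchors and derived `tau_s`
#'   (time unit, s) and `force_unit_pN`.
#' @export
reduced_units <- function(sigma_nm = 10, kBT_pN_um = 0.0042,
                          gamma_pN_s_um2 = 1, alpha_pN_s_um = NULL) {
  sigma_um <- sigma_nm / 1000
  if (is.null(alpha_pN_s_um))
    alpha_pN_s_um <- round(3 * pi * gamma_pN_s_um2 * sigma_um, 1)
  u <- list(sigma_nm = sigma_nm, sigma_um = sigma_um,
            kBT_pN_um = kBT_pN_um, gamma_pN_s_um2 = gamma_pN_s_um2,
            alpha_pN_s_um = alpha_pN_s_um,
            tau_s = alpha_pN_s_um * sigma_um^2 / kBT_pN_um,
            force_unit_pN = kBT_pN_um / sigma_um)
  if (any(unlist(u) <= 0)) stop("all unit anchors must be positive")
  structure(u, class = "reduced_units")
}

#' Convert a reduced-unit quantity to physical units
#'
#' @param value Value in reduced units (length in sigma, time in tau, force
#'   in kBT/sigma, rate in 1/tau, stiffness in kBT/sigma^2, bending modulus
#'   in kBT*sigma, energy in kBT).
#' @param quantity One of `"length"` (-> nm), `"time"` (-> s), `"force"`
#'   (-> pN), `"rate"` (-> 1/s), `"stiffness"` (-> pN/nm), `"bending"`
#'   (-> pN*um^2), `"energy"` (-> pN*um).
#' @param units A [reduced_units()] object.
#' @return The value in the physical unit named above.
#' @export
to_physical <- function(value, quantity, units = reduced_units()) {
  switch(match.arg(quantity, c("length", "time", "force", "rate",
                               "stiffness", "bending", "energy")),
         length = value * units$sigma_nm,
         time = value * units$tau_s,
         force = value * units$force_unit_pN,
         rate = value / units$tau_s,
         stiffness = value * units$kBT_pN_um / units$sigma_um^2 / 1000,
         bending = value * units$kBT_pN_um * units$sigma_um,
         energy = value * units$kBT_pN_um)
}

#' Catch-slip detachment rate of an inter-filament bond
#'
#' `omega_off(f) = omega0_1 exp(f/f_d1) + omega0_2 exp(-f/f_d2)`: a
#' force-accelerated slip channel plus a force-suppressed catch channel.
#' The rate is minimal (bond lifetime maximal) at
#' `f* = ln(omega0_2 f_d1 / (omega0_1 f_d2)) / (1/f_d1 + 1/f_d2)`.
#'
#' @param bond_force Magnitude of the bond load `|k_m dr|`, kBT/sigma
#'   (vectorized, >= 0).
#' @param params A [langevin_params()].
#' @return Detachment rate(s), 1/tau.
#' @export
catch_slip_rate <- function(bond_force, params = langevin_params()) {
  if (any(bond_force < 0)) stop("bond force magnitude must be >= 0")
  params$omega0_1 * exp(bond_force / params$f_d1) +
    params$omega0_2 * exp(-bond_force / params$f_d2)
}

#' Force at which the catch-slip rate is minimal
#' @param params A [langevin_params()].
#' @return `f*` in kBT/sigma.
#' @export
catch_slip_optimum <- function(params = langevin_params()) {
  log(params$omega0_2 * params$f_d1 / (params$omega0_1 * params$f_d2)) /
    (1 / params$f_d1 + 1 / params$f_d2)
}

# ---- energy surfaces (exposed for verification and reuse) ----------------

single_chain_sys <- function(n, breakable = empty_bonds(),
                             permanent = empty_links(), fixed = integer(0),
                             pulled = empty_pulled(), chains = NULL) {
  if (is.null(chains)) chains <- list(starts = 0L, lengths = as.integer(n))
  list(chain_starts = as.integer(chains$starts),
       chain_lengths = as.integer(chains$lengths),
       breakable = breakable, permanent = permanent,
       fixed = as.integer(fixed), pulled = pulled)
}

empty_bonds <- function() matrix(numeric(0), 0, 3)
empty_links <- function() matrix(numeric(0), 0, 4)
empty_pulled <- function() matrix(numeric(0), 0, 3)

#' Stretching energy and forces of a bead-spring filament
#'
#' `E_s = sum A/(2 sigma) (|b_i| - sigma)^2` over consecutive bonds; forces
#' are the exact negative gradient.
#'
#' @param positions n x 2 matrix of bead coordinates (reduced units).
#' @param A Stretching stiffness, kBT/sigma.
#' @param sigma Bond rest length.
#' @return List with `energy` and `forces` (n x 2).
#' @export
stretching_energy <- function(positions, A = 5e3, sigma = 1) {
  stopifnot(nrow(positions) >= 2)
  par <- langevin_params(N = nrow(positions), A = A, sigma = sigma)
  par$kappa <- 1e-300; par$eps_wca <- 1e-300   # isolate the stretching term
  r <- .lgv_energy_forces(positions, single_chain_sys(nrow(positions)), par)
  list(energy = r$stretch, forces = r$forces)
}

#' Bending energy and forces of a semiflexible filament
#'
#' `E_b = sum kappa/(2 sigma) |t_{i+1} - t_i|^2` over consecutive unit
#' tangents; zero for a straight chain.
#'
#' @inheritParams stretching_energy
#' @param kappa Bending rigidity, kBT*sigma.
#' @return List with `energy` and `forces` (n x 2).
#' @export
bending_energy <- function(positions, kappa = 5.1, sigma = 1) {
  stopifnot(nrow(positions) >= 3)
  par <- langevin_params(N = nrow(positions), kappa = kappa, sigma = sigma)
  par$A <- 1e-300; par$eps_wca <- 1e-300
  r <- .lgv_energy_forces(positions, single_chain_sys(nrow(positions)), par)
  list(energy = r$bend, forces = r$forces)
}

#' WCA excluded-volume energy and forces
#'
#' Purely repulsive cut-and-shifted Lennard-Jones,
#' `4 eps [(sigma/r)^12 - (sigma/r)^6 + 1/4]` for `r < 2^(1/6) sigma` and 0
#' beyond, over all non-bonded pairs (consecutive beads of the same
#' filament are excluded).
#'
#' @inheritParams stretching_energy
#' @param eps_wca Energy scale, kBT.
#' @param chains Optional list with `starts` and `lengths` (0-based)
#'   describing multiple filaments; default treats `positions` as one chain.
#' @return List with `energy` and `forces` (n x 2).
#' @export
wca_energy <- function(positions, eps_wca = 1, sigma = 1, chains = NULL) {
  stopifnot(nrow(positions) >= 2)
  par <- langevin_params(N = nrow(positions), eps_wca = eps_wca,
                         sigma = sigma)
  par$A <- 1e-300; par$kappa <- 1e-300
  r <- .lgv_energy_forces(positions,
                          single_chain_sys(nrow(positions), chains = chains),
                          par)
  list(energy = r$wca, forces = r$forces)
}

# ---- arrangements --------------------------------------------------------

#' Build a filament arrangement for lifetime simulations
#'
#' Geometries mimic the tip-link architectures:
#' * `"dimer"`: an anchored filament (one end tethered) and a pulled
#'   filament, antiparallel, overlapping over `n_b` beads joined by
#'   breakable bonds - an individual tip-link.
#' * `"tetramer_free"`: two such dimers side by side; the two pulled ends
#'   are held together by a stiff permanent spring and the external force
#'   is shared between them. No cross-links.
#' * `"tetramer_crosslinked"`: as `tetramer_free` plus three permanent
#'   cross-links - the anchored pair joined near the anchor and at
#'   one-third of the chain (the cis-dimerization contacts of the anchored
#'   protein), and the pulled pair joined at the bead adjacent to the
#'   bonded region (the lateral contact of the pulled protein).
#'
#' @param tag Arrangement name (above).
#' @param params A [langevin_params()].
#' @param n_b Number of breakable bonds in each bonded overlap (default 10).
#' @return A `"filament_system"`: positions, chain topology, breakable
#'   bonds, permanent links, tethered and pulled beads.
#' @export
build_arrangement <- function(tag = c("dimer", "tetramer_free",
                                      "tetramer_crosslinked"),
                              params = langevin_params(), n_b = 10) {
  tag <- match.arg(tag)
  N <- params$N
  if (n_b < 1 || n_b >= N) stop("need 1 <= n_b < N")
  chain_y <- function(y) cbind(seq_len(N) - 1, rep(y, N))
  pulled_chain <- function(y) cbind((N - n_b) + seq_len(N) - 1, rep(y, N))
  # dimer 1: anchored chain at y=0 (beads 0..N-1), pulled at y=1
  pos <- rbind(chain_y(0), pulled_chain(1))
  chain_starts <- c(0L, N)
  chain_lengths <- c(N, N)
  bonds1 <- cbind((N - n_b) + 0:(n_b - 1),          # anchored beads
                  N + 0:(n_b - 1),                  # pulled beads
                  1)                                # rest length = y gap
  fixed <- 0L
  pulled <- cbind(2L * N - 1L, 1, 0)                # far end of chain B, +x
  breakable <- bonds1
  permanent <- empty_links()
  if (tag != "dimer") {
    # dimer 2 mirrored above: pulled chain at y=2, anchored at y=3
    off <- 2L * N
    pos <- rbind(pos, pulled_chain(2), chain_y(3))
    chain_starts <- c(chain_starts, off, off + N)
    chain_lengths <- c(chain_lengths, N, N)
    bonds2 <- cbind(off + N + (N - n_b) + 0:(n_b - 1),  # anchored 2
                    off + 0:(n_b - 1),                  # pulled 2
                    1)
    breakable <- rbind(bonds1, bonds2)
    fixed <- c(0L, off + N)             # tether bead 0 of anchored chain 2
    # the two pulled ends held at the same position: stiff tie spring
    tie_k <- params$A / params$sigma
    permanent <- rbind(permanent,
                       c(2L * N - 1L, off + N - 1L, 1, tie_k))
    # external force shared between the two pulled ends
    pulled <- rbind(cbind(2L * N - 1L, 0.5, 0),
                    cbind(off + N - 1L, 0.5, 0))
    if (tag == "tetramer_crosslinked") {
      a1 <- 0L; a2 <- off + N                       # anchored chain starts
      # anchored pair: one link near the anchor (the membrane-proximal
      # cis-dimerization contact) and one just below the bonded overlap
      # (the EC3-like contact, three beads from the binding tip) - the
      # latter couples the two bond clusters and lets them share load
      ec3 <- max(1L, N - n_b - 3L)
      permanent <- rbind(permanent,
                         c(a1 + 1L, a2 + 1L, 3, params$k_m),
                         c(a1 + ec3, a2 + ec3, 3, params$k_m),
                         c(N + n_b, off + n_b, 1, params$k_m))
    }
  }
  sys <- list(positions = pos, chain_starts = as.integer(chain_starts),
              chain_lengths = as.integer(chain_lengths),
              breakable = breakable, permanent = permanent,
              fixed = as.integer(fixed), pulled = pulled,
              tag = tag, n_b = as.integer(n_b))
  class(sys) <- "filament_system"
  validate_filament_system(sys)
  sys
}

validate_filament_system <- function(sys) {
  if (nrow(sys$breakable) > 0 &&
      any(sys$breakable[, 1] == sys$breakable[, 2]))
    stop("a breakable bond connects a bead to itself")
  if (nrow(sys$permanent) > 0 &&
      any(sys$permanent[, 1] == sys$permanent[, 2]))
    stop("a permanent link connects a bead to itself")
  n <- nrow(sys$positions)
  idx <- c(sys$breakable[, 1:2], sys$permanent[, 1:2], sys$fixed,
           sys$pulled[, 1])
  if (length(idx) && (min(idx) < 0 || max(idx) >= n))
    stop("bond/tether/pull index out of range")
  invisible(sys)
}

#' @export
print.filament_system <- function(x, ...) {
  cat(sprintf("Filament system '%s': %d chains x %d beads, %d breakable bonds, %d permanent links, %d tether(s)\n",
              x$tag, length(x$chain_starts), x$chain_lengths[1],
              nrow(x$breakable), nrow(x$permanent), length(x$fixed)))
  invisible(x)
}

sys_for_cpp <- function(sys) {
  list(chain_starts = sys$chain_starts, chain_lengths = sys$chain_lengths,
       breakable = sys$breakable, permanent = sys$permanent,
       fixed = sys$fixed, pulled = sys$pulled)
}

#' Advance a filament system by Langevin dynamics
#'
#' Underdamped Langevin (BAOAB splitting, unit mass, friction `alpha`) for
#' all unconstrained beads, with the constant external force applied to the
#' pulled beads and per-step stochastic rupture of surviving breakable
#' bonds (probability `1 - exp(-omega_off(f1) dt)`; ruptured bonds never
#' re-form). Trajectories are bitwise reproducible for a given seed.
#'
#' @param system A `"filament_system"`.
#' @param params A [langevin_params()].
#' @param n_steps Number of timesteps.
#' @param F_e External force magnitude, kBT/sigma.
#' @param seed Integer seed.
#' @param rupture Allow bond rupture? (`FALSE` freezes the bonds, e.g. for
#'   equilibration studies.)
#' @return The updated system (positions, plus `velocities`, `alive` bond
#'   flags and `time` attributes advanced).
#' @export
langevin_step <- function(system, params, n_steps = 1, F_e = 0, seed = NULL,
                          rupture = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sys <- sys_for_cpp(system)
  if (!rupture) sys$breakable <- empty_bonds()
  r <- .lgv_run(system$positions, sys, params, F_e,
                t_max = n_steps * params$dt, stop_when_all_broken = FALSE,
                n_equil = 0L, sample_every = 0L, record_ke = FALSE,
                ke_burnin = 0L)
  out <- system
  out$positions <- r$positions
  attr(out, "velocities") <- r$velocities
  if (rupture && nrow(system$breakable) > 0) {
    keep <- r$alive == 1L
    out$breakable <- system$breakable[keep, , drop = FALSE]
  }
  attr(out, "time") <- (attr(system, "time") %||% 0) + n_steps * params$dt
  out
}

#' Attachment lifetime of a filament arrangement under constant force
#'
#' Simulates until every breakable inter-filament bond has ruptured
#' (permanent cross-links do not count) and returns the elapsed time. The
#' system is first equilibrated under load with rupture disabled, then the
#' clock starts.
#'
#' @param system A `"filament_system"`.
#' @param params A [langevin_params()].
#' @param F_e External force, kBT/sigma.
#' @param seed Integer seed.
#' @param t_max Censoring cap, tau.
#' @param n_equil Equilibration steps before the rupture clock starts.
#' @return List: `lifetime` (tau), `censored`, `break_times` per bond.
#' @export
run_lifetime <- function(system, params, F_e, seed = 1, t_max = 5000,
                         n_equil = 2000) {
  set.seed(seed)
  if (nrow(system$breakable) == 0)
    return(list(lifetime = 0, censored = FALSE, break_times = numeric(0)))
  r <- .lgv_run(system$positions, sys_for_cpp(system), params, F_e,
                t_max = t_max, stop_when_all_broken = TRUE,
                n_equil = as.integer(n_equil), sample_every = 0L,
                record_ke = FALSE, ke_burnin = 0L)
  list(lifetime = r$lifetime, censored = r$censored,
       break_times = r$break_times)
}

#' Ensemble mean attachment lifetime versus force
#'
#' Runs `n_runs` independent lifetime simulations per force (fresh thermal
#' initial conditions each run) and reports ensemble means with standard
#' errors.
#'
#' @param tag Arrangement (see [build_arrangement()]).
#' @param forces External forces, kBT/sigma.
#' @param n_runs Independent runs per force (>= 2, for a standard error).
#' @param seed Integer base seed (run r at force i uses
#'   `seed + 1000*i + r`).
#' @param params A [langevin_params()].
#' @param n_b Breakable bonds per bonded overlap.
#' @param t_max Censoring cap per run, tau.
#' @param n_equil Equilibration steps per run.
#' @return An `"ensemble_result"` data.frame: `force`, `mean_lifetime`,
#'   `sem`, `n_runs`, `n_censored` (all lifetimes in tau).
#' @export
lifetime_vs_force <- function(tag, forces, n_runs, seed = 1,
                              params = langevin_params(), n_b = 10,
                              t_max = 5000, n_equil = 2000) {
  if (n_runs < 2) stop("need n_runs >= 2 to form a standard error")
  sys <- build_arrangement(tag, params, n_b)
  out <- data.frame(force = forces, mean_lifetime = NA_real_,
                    sem = NA_real_, n_runs = n_runs, n_censored = 0L)
  for (i in seq_along(forces)) {
    lt <- numeric(n_runs); cen <- logical(n_runs)
    for (r in seq_len(n_runs)) {
      res <- run_lifetime(sys, params, forces[i],
                          seed = seed + 1000 * i + r, t_max = t_max,
                          n_equil = n_equil)
      lt[r] <- res$lifetime; cen[r] <- res$censored
    }
    out$mean_lifetime[i] <- mean(lt)
    out$sem[i] <- sd(lt) / sqrt(n_runs)
    out$n_censored[i] <- sum(cen)
  }
  structure(out, tag = tag, seed = seed,
            class = c("ensemble_result", "data.frame"))
}

#' Mean kinetic energy per degree of freedom of a thermalized filament
#'
#' Equipartition diagnostic: for a correct thermostat the time-averaged
#' kinetic energy per degree of freedom is `kBT/2`.
#'
#' @param params A [langevin_params()].
#' @param n_steps Sampled steps.
#' @param seed Integer seed.
#' @param burnin Steps discarded before sampling.
#' @return Mean kinetic energy per degree of freedom, kBT.
#' @export
measure_equipartition <- function(params = langevin_params(),
                                  n_steps = 1e5, seed = 1,
                                  burnin = 5000) {
  set.seed(seed)
  pos <- cbind(seq_len(params$N) - 1, 0)
  sys <- single_chain_sys(params$N)
  r <- .lgv_run(pos, sys, params, 0, t_max = n_steps * params$dt,
                stop_when_all_broken = FALSE, n_equil = 0L,
                sample_every = 0L, record_ke = TRUE,
                ke_burnin = as.integer(burnin))
  mean(r$ke_samples) / (2 * params$N)   # 2 dof per bead in 2D
}

#' Tangent-correlation persistence length of a free filament
#'
#' Averages the tangent-tangent correlation `<t(i).t(i+d)>` over an
#' ensemble of independent Langevin runs of a single untethered filament
#' and fits `exp(-d/lambda)`. Each run starts from an exact equilibrium
#' draw of the discrete wormlike chain (successive bend angles sampled
#' from their Boltzmann distribution), so the sampled correlation is free
#' of slow-mode equilibration bias.
#'
#' In 2D the continuum wormlike-chain prediction is
#' `lambda = 2 kappa / kBT`; the discrete bead-spring chain decays with
#' `lambda_disc = -1 / log(I1(kappa/sigma) / I0(kappa/sigma))`
#' (see [discrete_persistence_length()]), which approaches the continuum
#' value as the discretization is refined.
#'
#' @param params A [langevin_params()].
#' @param n_runs Independent equilibrium draws.
#' @param n_steps Langevin steps per run.
#' @param sample_every Snapshot interval, steps.
#' @param burnin Steps discarded at the start of each run.
#' @param seed Integer seed.
#' @param max_sep Largest tangent separation used in the fit, bonds.
#' @return Fitted persistence length, sigma units.
#' @export
measure_persistence_length <- function(params = langevin_params(),
                                       n_runs = 30, n_steps = 4e4,
                                       sample_every = 5000, burnin = 10000,
                                       seed = 1, max_sep = 6) {
  sys <- single_chain_sys(params$N)
  corr <- numeric(max_sep + 1); cnt <- numeric(max_sep + 1)
  for (run in seq_len(n_runs)) {
    set.seed(seed + run)
    pos <- wlc_equilibrium_positions(params)
    r <- .lgv_run(pos, sys, params, 0, t_max = n_steps * params$dt,
                  stop_when_all_broken = FALSE, n_equil = 0L,
                  sample_every = as.integer(sample_every),
                  record_ke = FALSE, ke_burnin = 0L)
    first_kept <- ceiling(burnin / sample_every) + 1
    for (s in seq(first_kept, r$n_snapshots)) {
      xy <- r$snapshots[, c(2 * s - 1, 2 * s)]
      tg <- diff(xy)
      tg <- tg / sqrt(rowSums(tg^2))
      for (d in 0:max_sep) {
        m <- nrow(tg) - d
        corr[d + 1] <- corr[d + 1] +
          sum(rowSums(tg[1:m, , drop = FALSE] *
                        tg[(1 + d):(m + d), , drop = FALSE]))
        cnt[d + 1] <- cnt[d + 1] + m
      }
    }
  }
  cc <- corr / cnt
  sep <- 0:max_sep
  ok <- cc > 0
  fit <- lm(log(cc[ok]) ~ sep[ok])
  -1 / coef(fit)[[2]]
}

#' Exact persistence length of the discrete 2D wormlike chain
#'
#' For per-joint bending energy `(kappa/sigma)(1 - cos theta)` the joint
#' angles are independent with `<cos theta> = I1(k)/I0(k)`, `k =
#' kappa/(sigma kBT)`, so tangent correlations decay per bond by that
#' factor.
#'
#' @param params A [langevin_params()].
#' @return Decay length in bonds (sigma units).
#' @export
discrete_persistence_length <- function(params = langevin_params()) {
  k <- params$kappa / (params$sigma * params$kBT)
  -1 / log(besselI(k, 1) / besselI(k, 0))
}

# equilibrium draw of the discrete 2D wormlike chain: successive bend
# angles from the von Mises-type density exp(k cos dtheta) (rejection from
# a Gaussian envelope), bonds at rest length
wlc_equilibrium_positions <- function(params) {
  k <- params$kappa / (params$sigma * params$kBT)
  n <- params$N
  for (try in 1:500) {
    dth <- numeric(n - 2)
    for (i in seq_len(n - 2)) {
      repeat {
        x <- runif(1, -pi, pi)
        if (runif(1) <= exp(k * (cos(x) - 1))) break
      }
      dth[i] <- x
    }
    ang <- cumsum(c(0, dth))
    pos <- rbind(c(0, 0),
                 cbind(cumsum(params$sigma * cos(ang)),
                       cumsum(params$sigma * sin(ang))))
    # reject self-overlapping draws: excluded volume keeps non-consecutive
    # beads apart in the true (self-avoiding) equilibrium
    d2 <- as.matrix(dist(pos))
    diag(d2) <- Inf
    for (i in seq_len(n - 1)) d2[i, i + 1] <- d2[i + 1, i] <- Inf
    if (min(d2) > 0.95 * params$sigma) return(pos)
  }
  stop("could not draw a self-avoiding equilibrium configuration")
}

#' Sample single-bond rupture times at constant load
#'
#' The per-step rupture process used in the simulator, isolated: at fixed
#' bond load the number of survived steps is geometric with
#' `p = 1 - exp(-omega_off(f) dt)`, so rupture times are (discretized)
#' exponential with rate `omega_off(f)`. This is the rigid-filament,
#' direct-transmission limit used to verify the simulator's rupture
#' statistics.
#'
#' @param bond_force Constant bond load, kBT/sigma.
#' @param params A [langevin_params()].
#' @param n Number of rupture times.
#' @param seed Integer seed.
#' @return Rupture times, tau.
#' @export
sample_rupture_times <- function(bond_force, params = langevin_params(),
                                 n = 1000, seed = 1) {
  set.seed(seed)
  p <- 1 - exp(-catch_slip_rate(bond_force, params) * params$dt)
  (stats::rgeom(n, p) + 1) * params$dt
}
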