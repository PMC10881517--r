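# tipbond

Catch-bond kinetics and force-clamp survival analysis of tip-link adhesion
bonds.

Tip-links are cadherin filaments (cadherin-23 bound to protocadherin-15)
that connect stereocilia in inner-ear hair cells and transmit sound-induced
tension to mechanotransduction channels. Single-molecule force-clamp
spectroscopy holds one bond at constant force and measures its survival;
individual tip-link interfaces show *slip-catch-slip* lifetime-force curves
(lifetime falls, then rises above a critical force, then falls again),
while the intact heterotetrameric complex shows *slip-ideal-slip* behaviour
— a force-insensitive lifetime plateau interpreted as a force filter for
hearing. This package implements the computational machinery behind that
picture, for single-molecule biophysicists who want to fit, simulate and
stress-test it:

* **Kinetics** — a modified sliding-rebinding model of the interface:
  four occupation states (`P11, P10, P01, P00`), Bell off-rates
  `k_-1(f) = k_-1^0 exp(f x_beta / kBT)`,
  `k_-2(f) = 2 k_-1^0 exp(f x_beta / 2 kBT)`, and a force-gated rebinding
  probability `P_n = {0.5[1 - cos(pi f/F_C2)]}^n` between two critical
  forces (0 below `F_C1`, 1 above `F_C2`). Solved deterministically
  (stiff ODE), spectrally (exact mean first-passage times) and
  stochastically (exact Gillespie sampling). The deafness-associated
  mutant is the same scheme with `P_n = 0`.
* **Unfolding augmentation** — Bell-model domain unfolding of the long
  cadherin arm damps the dissociated-state probability,
  `P00_u(t) = P_U(t) P00(t)`, with `P_U` a count-weighted combination of
  the two dominant step classes (~5 and ~12 nm).
* **Clamp analysis** — product-limit survival estimation with censoring,
  mono/bi-exponential fits selected by F-test, Bell fits
  `tau = tau0 exp(-f/f*)` of slip/ideal regions, step detection in
  force/height traces, Gaussian-mixture fitting of step heights.
* **Model fitting** — bounded Levenberg-Marquardt with data-informed
  multi-start, parameter errors *and* correlation matrices, plus an
  end-to-end parameter-recovery harness.
* **Langevin simulator** (Rcpp) — 2D semiflexible bead-spring filaments
  coupled by breakable catch-slip bonds
  (`omega_off = omega0_1 e^{f/fd1} + omega0_2 e^{-f/fd2}`), in dimeric and
  tetrameric (optionally cross-linked) arrangements under constant force;
  measures attachment lifetimes and shows the flattening of the catch
  response under cross-linking.
* **Synthetic data** — seeded generators for per-force lifetime datasets
  and clamp traces with plateaus, force spikes and height steps, so the
  entire pipeline is testable without instrument data.

The published kinetic parameter sets (wild-type and mutant interface, the
four cadherin-23 length variants, and the per-step-class unfolding
kinetics) ship as JSON presets under `inst/extdata/params`.

## Worked example

```r
library(tipbond)

wt <- load_params("interface_wt")   # published wild-type interface fit
wt
#> Sliding-rebinding parameters (WT)
#>   k_-1^0 = 0.5 1/s   x_beta = 1 A   kBT = 41.14 pN.A
#>   k_+1 = 2.8 1/s   k_+2 = 30.2 1/s
#>   F_C1 = 58 pN   F_C2 = 100 pN   n = 2.3

# model lifetime-force curve at the seven experimental clamp forces
lifetime_force_curve(wt, c(28, 41, 58, 80, 103, 119, 143))
#>   force_pN lifetime_s
#> 1       28      3.235
#> 2       41      2.233
#> 3       58      2.086
#> 4       80      2.939
#> 5      103      3.126
#> 6      119      1.693
#> 7      143      0.742
```

The lifetime *falls* from 28 to 58 pN (slip), *rises* to a catch maximum
above the 58 pN switch, and falls again at high force — the slip-catch-slip
signature. Now a synthetic force-clamp experiment at 80 pN and its
analysis:

```r
ds <- generate_lifetime_dataset(wt, 80, 300, seed = 42)[[1]]
ds
#> Clamp dataset: 80 pN, 300 events (9 censored at 10 s)

sv <- empirical_survival(ds)                    # Kaplan-Meier
f1 <- fit_exponential(sv, 1)
f1
#> Mono-exponential survival fit: tau = 3.057 s (amplitudes 1), RSS = 0.05774, dof = 292
select_model_ftest(f1, fit_exponential(sv, 2))  # 1: the mono fit suffices
```

The fitted 3.06 s agrees with the model's exact mean lifetime at 80 pN
(2.94 s) within the sampling error of 300 events. Fitting the kinetic
model back to a model-generated curve returns the generating parameters
and flags what is (and is not) identifiable:

```r
fit <- fit_sliding_rebinding(lifetime_force_curve(wt, seq(10, 150, 10)),
                             "WT", seed = 1)
fit
#> Sliding-rebinding fit (WT), RSS = 4.832e-29, dof = 9
#>   k_minus1_0  =      0.5 +/- 1.86e-14
#>   x_beta      =        1 +/- 8.31e-15
#>   k_plus1     =      2.8 +/- 2.43e-13
#>   k_plus2     =     30.2 +/- 7.85e-13
#>   F_C2        =      100 +/- 3.29e-14
#>   n           =      2.3 +/- 8.64e-15
#>   fixed: F_C1 = 58
#>   strongly correlated: k_minus1_0~k_plus1, k_plus1~k_plus2, ...
```

Filament-level simulation (reduced units; ~1 s per run):

```r
sys <- build_arrangement("dimer")
run_lifetime(sys, langevin_params(), F_e = 45, seed = 7)$lifetime
ens <- lifetime_vs_force("tetramer_crosslinked", c(80, 150, 220),
                         n_runs = 20, seed = 1)
to_physical(ens$mean_lifetime, "time")   # seconds
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/tipbond.R` (subcommands `kinetics`, `synth`, `analyze`,
`fit`, `langevin`).

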