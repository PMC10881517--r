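---
title: "Models and methods: catch-bond kinetics and filament mechanics of tip-links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: catch-bond kinetics and filament mechanics of tip-links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipbond)
```

# The problem

Tip-links are filamentous cadherin complexes (cadherin-23 bound to
protocadherin-15) that connect neighbouring stereocilia of inner-ear hair
cells and convey sound-induced tension to mechanotransduction channels.
Single-molecule force-clamp spectroscopy holds one such bond at constant
tension and records the time until it ruptures; repeating this thousands of
times per clamp force yields survival curves and a mean bond lifetime as a
function of force. Three phenotypes matter:

* **slip bond** — lifetime falls monotonically with force (Bell behaviour);
* **catch bond** — lifetime *rises* with force over some window, here
  because tension reorients the binding interface and lets new contacts
  form;
* **ideal bond** — lifetime insensitive to force over a window, observed
  for the intact heterotetrameric tip-link complex and interpreted as a
  force filter for hearing.

`tipbond` implements the computational core of this programme: the
modified sliding-rebinding kinetic model of the individual interface, an
unfolding-augmented survival model for long multi-domain constructs, the
force-clamp survival-analysis pipeline, nonlinear model fitting with
recovery harnesses, a coarse-grained Langevin simulator of catch-bond-coupled
semiflexible filaments, and a synthetic-data generator that stands in for
the instrument so that every stage is testable end to end.

# The modified sliding-rebinding kinetic model

The interface is modelled as two identical pseudo-bonds. Four occupation
probabilities evolve at a fixed clamp force $f$:

* $P_{11}$ — both bonds formed (the initial state),
* $P_{10}$ — one bond broken,
* $P_{01}$ — the single bond of a force-induced, newly formed (tilted)
  interface,
* $P_{00}$ — fully dissociated (absorbing).

$$
\begin{aligned}
\dot P_{11} &= 2k_{+1}P_{10} + k_{+2}P_{01} - k_{-2}P_{11}\\
\dot P_{10} &= k_{-2}P_{11} - 2(k_{+1}+k_{-1})P_{10}\\
\dot P_{01} &= 2P_n k_{-1}P_{10} - (k_{+2}+k_{-1})P_{01}\\
\dot P_{00} &= 2(1-P_n)k_{-1}P_{10} + k_{-1}P_{01}
\end{aligned}
$$

with Bell-model off-rates
$k_{-1}(f) = k_{-1}^0 e^{f x_\beta / k_BT}$ and
$k_{-2}(f) = 2k_{-1}^0 e^{f x_\beta / 2k_BT}$ (the doubly bonded state
shares the load), and the force-gated rebinding probability

$$
P_n(f) = \begin{cases}
0 & f < F_{C1}\\
\left\{\tfrac12\left[1-\cos(\pi f/F_{C2})\right]\right\}^{n} &
  F_{C1}\le f\le F_{C2}\\
1 & f > F_{C2}.
\end{cases}
$$

Survival is $S(t) = P_{11}+P_{10}+P_{01} = 1 - P_{00}$. The rebinding
pathway ($P_n > 0$) is what produces catch behaviour; the deafness-associated
point mutant has lost the pivot that enables interface tilting, so the
mutant model is the same system with $P_n \equiv 0$ and only
$k_{-1}^0, x_\beta, k_{+1}$ free.

Bookkeeping notes, fixed here because the source equations leave them
open:

* the re-formed single-bond state is tracked as one state ($P_{01}$), and
  rebinding at $k_{+2}$ returns it to $P_{11}$; no separate "new doubly
  bonded" state is needed for the survival observable;
* the printed mutant absorption equation drains a state the mutant never
  populates; the mutant is therefore implemented as the full scheme with
  $P_n \equiv 0$, which preserves probability conservation and reproduces
  the two printed mutant equations;
* the initial condition is the fully bonded interface,
  $P_{11}(0) = 1$.

## Units: a caution

Rates are 1/s, forces pN, and $x_\beta$ is tabulated in Ångström. Thermal
energy at 298 K is $k_BT = 4.114$ pN·nm $= 41.14$ pN·Å; the package default
is therefore `kBT = 41.14` in pN·Å. Feeding the commonly quoted
4.114 (pN·nm value) with Å distances inflates every Bell exponent tenfold
and collapses lifetimes to milliseconds; with 41.14 the bundled parameter
sets reproduce the published few-second lifetime scale. `kBT` is exposed
everywhere for non-standard temperatures.

## Solvers and estimators

* `solve_survival()` integrates the four-state system with a stiff-capable
  integrator (`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$): at high
  force the rates span several orders of magnitude. Conservation
  $\sum P = 1$ holds to better than $10^{-8}$ on every output grid.
* `mean_lifetime()` defaults to the exact mean first-passage time, a
  linear solve on the transient generator; for this linear scheme it
  equals $\int_0^\infty S\,dt$. An `"expfit"` estimator instead fits a
  single exponential to $S(t)$, mirroring how experiments reduce survival
  curves to lifetimes; the two differ by a few percent when $S$ is not
  exactly exponential, and fits of experimental-style data should use the
  estimator matching how the data were reduced.
* `gillespie_lifetimes()` draws exact first-passage times of the same
  Markov chain by the direct (two-random-number) method. It is the
  stochastic oracle for the ODE solution (Kolmogorov–Smirnov distance
  below 0.02 at $n = 10^4$ across the force range) and the engine of the
  synthetic generator.

`rebinding_probability()` implements the switch exactly as printed,
including the discontinuity at $F_{C1}$ when the cosine branch is not
small there.

$F_{C1}$ does not appear in the published fit tables; the experimentally
observed slip-to-catch onset of 58 pN is used as the default, fixed during
fitting, with an option to free it under $0 < F_{C1} < F_{C2}$.

# Unfolding-augmented unbinding

Long cadherin arms expose non-interacting domains that can unfold under
load before the interface fails, each unfolding dissipating force and
extending survival. Per step-height class the unfolding rate is Bell,
$k_u(f) = k_u^0 e^{f x_\beta^u/k_BT}$, and
$P_u(t) = 1 - e^{-k_u t}$. The two dominant classes (~5 and ~12 nm steps)
are combined with weights from the observed per-force unfolding counts,
$P_U = (n_1 P_{1u} + n_2 P_{2u})/(n_1+n_2)$, and the dissociated-state
probability is damped as $P_{00}^u(t) = P_U(t)\,P_{00}(t)$, so the
observable survival $1 - P_U P_{00}$ dominates the unadjusted curve
pointwise. The 22 and 34 nm classes are fitted (their Bell parameters ship
with the package) but excluded from $P_U$, mirroring the published
simplification.

Two readings of the augmentation are provided. The default evaluates
$P_U$ at the same time as $P_{00}$ (time-consistent). A scalar
sensitivity mode freezes $P_U$ at the unadjusted mean lifetime; because a
constant $P_U < 1$ leaves survival bounded away from zero, that mode
integrates over the clamp window only. A zero-rate class input would pin
$P_U$ at zero forever (survival never decays); the implementation treats
that as an inert augmentation and returns the plain kinetic lifetime.

# The force-clamp analysis pipeline

* `empirical_survival()` — product-limit (Kaplan–Meier) estimator via the
  survival package. Events that outlast the clamp window (10 s standard,
  20 s long protocol) are right-censored; the source procedure does not
  state how such events were treated, and with no censoring the estimator
  reduces to the naive counting fraction.
* `fit_exponential()` / `select_model_ftest()` — least-squares mono- and
  bi-exponential fits of the survival curve (Levenberg–Marquardt on the
  residual function directly, which stays well-defined when the
  bi-exponential degenerates to one component), compared by the F-test
  $F = \frac{(RSS_1-RSS_2)/(dof_1-dof_2)}{RSS_2/dof_2}$ at
  $\alpha = 0.05$.
* `fit_bell_slip()` — Bell fits $\langle\tau\rangle = \tau_0 e^{-f/f^*}$
  of user-specified slip windows, or a constant fit for ideal windows.
  The percent fit error is defined as
  $100\cdot\mathrm{RMS(residual)}/\mathrm{mean(fitted)}$ over the window
  (the source quotes percentages without a formula). Force windows are
  user-supplied: no boundary-selection rule was published.
* `detect_steps()` — unfolding events appear as transient force dips
  (~0.16 s) accompanied by discrete height gains. Detection thresholds a
  median-smoothed force trace at `setpoint − 3·SD` (noise SD estimated
  robustly from first differences so spikes do not inflate it), requires
  ≥ 3 consecutive below-threshold samples, and quantifies each event by
  the difference of 0.05 s windowed height medians. All thresholds are
  arguments; the defaults give ≥ 95% sensitivity for ~5 nm steps at the
  default noise level with a < 1% false-positive rate on flat traces.
* `fit_step_height_mixture()` — Gaussian mixture fit of pooled step
  heights (mclust, unequal variances) returning the ordered component
  means. The default hierarchical initialization of mclust is unstable
  for well-separated one-dimensional mixtures with unequal weights, so
  the fit is initialized from equal-variance hierarchical pairing; with
  that choice four-component recovery of the published peak positions is
  within 0.2 nm at the published sample size.

# Model fitting

`fit_sliding_rebinding()` minimizes weighted squared lifetime residuals
(optionally log-lifetimes) by Levenberg–Marquardt under bounds, with
multi-start initialization: a data-informed block (zero-force intercept
and low-force slope of $\log\tau$ seed $k_{-1}^0$ and $x_\beta$; the
interior maximum seeds $F_{C2}$; rebinding rates gridded) plus
Latin-hypercube starts with rates sampled on a log scale. The fit reports
standard errors *and the parameter correlation matrix*: $k_{+1}$ and
$k_{+2}$ are only weakly identified from lifetime-force curves (the
published error bars on those columns exceed the estimates), and a point
estimate without the correlation structure would mislead. MINPACK
requires at least as many residuals as free parameters, and the fit
refuses under-determined problems outright. Self-consistency on noiseless
model curves recovers all free parameters to better than 1% for both
variants.

`recovery_experiment()` runs the full synthetic pipeline — stochastic
lifetimes, product-limit survival, exponential lifetime, curve, fit — and
reports per-parameter bias, RMSE and spread. At experimental scale (60
events per force, the seven published clamp forces) the off-rate and
barrier distance are recovered within two standard deviations of the
replicate spread, while the rebinding rates scatter widely, exactly as
the published uncertainties suggest.

# Coarse-grained Langevin model

Each filament is $N = 35$ beads in two dimensions connected by stiff
harmonic springs ($\epsilon_s = \sum \frac{A}{2\sigma}(|\vec b_i| -
\sigma)^2$, $A = 5\times10^3\,k_BT/\sigma$) with a discrete bending
energy $\epsilon_b = \sum \frac{\kappa}{2\sigma}|\hat t_{i+1}-\hat
t_i|^2$ ($\kappa = 5.1\,k_BT\sigma$, rigidity parameter $u = L/\lambda =
3.33$) and WCA excluded volume ($\epsilon = 1\,k_BT$; the energy scale is
not stated in the source and 1 $k_BT$ is the conventional choice) between
all non-bonded pairs. Two dimensions are used because the source quotes
the 2D persistence-length relation $\lambda = 2\kappa/k_BT$.

Inter-filament bonds are elastic springs of stiffness $k_m =
3\times10^{-3}A/\sigma$ whose load $f_1 = k_m|\Delta r|$ drives a
catch-slip detachment rate
$\omega_{off} = \omega_0^{(1)}e^{f_1/f_d^{(1)}} +
\omega_0^{(2)}e^{-f_1/f_d^{(2)}}$
($\omega_0^{(1)}\tau = 4\times10^{-6}$, $\omega_0^{(2)}\tau = 0.1$,
$f_d^{(1)} = 5$, $f_d^{(2)} = 10\,k_BT/\sigma$), minimal at
$f^* = \ln(\omega_0^{(2)}f_d^{(1)}/\omega_0^{(1)}f_d^{(2)})/(1/f_d^{(1)}+1/f_d^{(2)})
\approx 31.4\,k_BT/\sigma$. Each surviving bond ruptures per step with
probability $1-e^{-\omega_{off}\,dt}$ (valid since $\omega\,dt \ll 1$ at
the defaults); ruptured bonds never re-form. The attachment lifetime is
the time until every breakable bond is gone; permanent cross-links do not
count.

Dynamics are underdamped Langevin (unit mass, unit friction so the time
unit is $\tau = \alpha\sigma^2/k_BT$, Gaussian noise obeying
fluctuation-dissipation) integrated with the BAOAB splitting at
$dt = 10^{-3}\tau$, with a Verlet neighbour list for the WCA pairs. The
thermostat reproduces $k_BT/2$ per degree of freedom within 2% and
trajectories are bitwise reproducible under a fixed seed (single thread,
R's RNG).

## Arrangements

* **dimer** — an anchored filament (one end tethered as a hard
  constraint) and a pulled filament, antiparallel, overlapping over
  $n_b = 10$ consecutive bead pairs joined by breakable bonds at rest
  length $\sigma$; a constant force pulls the free end. The bond count
  and placement are not stated in the source ("partially attached"); 10
  consecutive overlap bonds is the package default and is configurable.
* **tetramer_free** — two dimers side by side with their pulled ends held
  together by a stiff permanent spring; the external force is shared
  between the two pulled ends, so the per-interface load at total force
  $F$ matches a dimer at $F/2$.
* **tetramer_crosslinked** — additionally joins (i) the two anchored
  filaments near the anchor (the membrane-proximal cis-dimerization
  contact) and just below the bonded overlap (the lateral contact three
  domains from the binding tip — this link couples the two bond clusters
  and lets them share load), and (ii) the two pulled filaments at the
  bead adjacent to their bonded region. Cross-link stiffness is $k_m$.
  Placing the second anchored-pair link mid-chain instead leaves the
  clusters mechanically independent and the flattening effect (below)
  disappears at desk-scale ensembles.

## What emerges, and how it is checked

At the default parameters the dimer's mean attachment lifetime is
non-monotonic in force: the interior catch maximum near
45–80 $k_BT/\sigma$ outlives both low-force probes (where the unloaded
catch channel at rate $\approx \omega_0^{(2)}$ kills bonds quickly) and
high-force probes (slip). Beyond the peak the dimer's lifetime falls
steadily, while the cross-linked tetramer holds an ideal-like plateau
over the same window — at 80/150/220 $k_BT/\sigma$ its max/min lifetime
ratio is ≈ 1.1–1.4 against ≈ 1.5–1.7 for the dimer (36 runs per point;
at these ensemble sizes each point carries a ~10% standard error and the
contrast varies with the seed). The
package's checks use ensembles of 16–36 runs per force and 3–4 forces
(minutes on one CPU); the published curves average 100 runs per point
and are not reproduced at that scale here.

One discretization fact documented rather than hidden: the tangent
correlation of the discrete 35-bead chain decays with
$-1/\ln(I_1(\kappa\beta/\sigma)/I_0(\kappa\beta/\sigma)) = 9.07\sigma$,
about 11% below the continuum $2\kappa/k_BT = 10.2\sigma$. The simulation
reproduces the exact discrete value within ~1% (measured from ensembles
initialized by exact equilibrium draws of the bend angles), and the
discrete law converges to the continuum one as the chain is refined;
`discrete_persistence_length()` exposes the closed form.

## Physical units

With $\sigma = 10$ nm, $k_BT = 0.0042$ pN·µm and drag
$\alpha = 3\pi\gamma\sigma$ rounded to 0.1 pN·s/µm (the rounding is kept
so printed conversions reproduce exactly): force unit 0.42 pN, time unit
$\tau \approx 2.38\times10^{-3}$ s, $\kappa = 2.142\times10^{-4}$
pN·µm², $A \approx 2.1\times10^3$ pN, $k_m = 0.63$ pN/nm,
$f_d^{(1)} = 2.1$ pN, $f_d^{(2)} = 4.2$ pN,
$\omega_0^{(1)} \approx 1.68\times10^{-3}$ s⁻¹,
$\omega_0^{(2)} = 42$ s⁻¹. The 5 $k_BT/\sigma$ detachment scale is
canonical; its physical value is 2.1 pN (a printed 2.2 pN reflects
inconsistent rounding).

# The synthetic-data generator

`generate_lifetime_dataset()` draws lifetimes from the kinetic model by
exact stochastic sampling and censors at the clamp window (10 s default).
Above 70 pN an optional mode mixes in a short-lived (~1 s) exponential
component with a force-increasing logistic weight (rising from zero at
the onset towards one half far above it — the functional form is a
package choice; only the qualitative force dependence was described),
reproducing the published emergence of bi-exponential survival at high
force.

`generate_trace()` builds time/force/height traces: a clamp plateau with
Gaussian force noise (default SD 2 pN at 500 Hz — representative
single-molecule AFM numbers, chosen once), unfolding events injected at
Bell-rate renewal times with height gains drawn per class and a
rectangular 0.16 s force dip (default depth 8 pN) per event, terminated
at a drawn dissociation time. `generate_unfolding_counts()` emits
per-force Poisson counts with means proportional to the class unfolding
probabilities.

What the generator does *not* emulate: cantilever ringing and feedback
dynamics, piezo creep and drift, baseline wander, non-specific adhesion
events, and instrument-specific noise spectra. Passing the round-trip
tests therefore demonstrates the *pipeline's* correctness on data with
the assumed statistical structure, not robustness to every artefact of
real traces.

# Problem sizes used by the test suite

The suite exercises: conservation and stochastic/deterministic agreement
at $n = 10^4$ samples across five clamp forces; end-to-end recovery at 60
events per force over the seven published forces with 20 replicates;
detection sensitivity over 200 seeded traces; mixture recovery at the
published pooled sample size ($n = 1788$); Langevin micro-oracles
(finite-difference force checks at $10^{-6}$, equipartition within 5%,
single-bond rupture rates within 5%) and the emergence comparison at
16–36 runs per force point. These sizes were chosen to give each check
clear statistical margin while the whole suite runs in minutes.

# Known limitations

* The kinetic model is fitted to mean lifetimes; a full
  maximum-likelihood treatment of raw (censored) lifetimes would use more
  information, and is provided only as a cross-check mode for the
  exponential fits.
* $k_{+1}$/$k_{+2}$ are weakly identified from lifetime-force data alone;
  inspect the reported correlation matrix before interpreting them.
* The filament model is two-dimensional and omits hydrodynamic
  interactions, bond re-formation, and oscillatory loading.
* The cross-link geometry follows the domain architecture qualitatively;
  bead indices are configurable and results at desk-scale ensembles carry
  ~10% standard errors per force point.
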