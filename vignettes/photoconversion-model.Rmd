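---
title: "Modeling photoconversion in light-sensing two-component systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling photoconversion in light-sensing two-component systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Engineered photoreversible two-component systems (TCSs) give bacteria
programmable, light-controlled gene expression. This vignette lays out the
model `phototcs` implements, the assumptions behind it, the numerical
choices made in the implementation, what the synthetic-data generator does
and does not emulate, and the design decisions taken where more than one
reasonable implementation existed.

## The sensing model

A photoreceptor is produced in a ground state $S_g$ at rate $k_s$ and both
states are diluted by growth at $k_{dil}$. Light converts ground to active
at rate $k_1$ and active to ground at $k_2$; the active state also reverts
thermally at the dark-reversion rate $k_{dr}$:

$$\frac{dS_g}{dt} = k_s + (k_2 + k_{dr})\,S_a - (k_1 + k_{dil})\,S_g,\qquad
  \frac{dS_a}{dt} = k_1\,S_g - (k_2 + k_{dil} + k_{dr})\,S_a.$$

The photoconversion rates are spectral overlap integrals of the per-state
photoconversion cross sections $\sigma_i(\lambda)$ with the light's
spectral flux density. Since sources of fixed spectral shape scale linearly
with intensity $I$, we write $k_i = I\,\hat k_i$ with
$\hat k_i = \int \sigma_i\,\hat n_{light}\,d\lambda$, and rates from
simultaneous sources add.

Substituting the active fraction $y = S_a/(S_g+S_a)$ collapses the system
to a single linear ODE, $dy/dt = k_1 - k_{tot}\,y$ with
$k_{tot} = k_1+k_2+k_{dil}+k_{dr}$, whose step response is an exponential
with fixed point $k_1/k_{tot}$ and time constant $1/k_{tot}$. Transitions
are therefore slowest in the dark and accelerate without bound with
intensity.

**Assumption worth stating explicitly:** the $y$-reduction is exact only
when the total sensor pool sits at its production/dilution steady state
$k_s/k_{dil}$. This holds under balanced growth, which the characterization
experiments are designed to maintain. Both engines are provided —
`simulate_active_fraction()` (the reduction, used everywhere by default)
and `simulate_two_state()` (the full two-state system, numerically
integrated) — and the test suite verifies their agreement at pool steady
state. For pools out of steady state the two-state engine is authoritative.
$k_s$ cancels in the reduction and is fixed at 1 by convention; it is
structurally unidentifiable from expression data.

## Signaling and output

TCS signaling (autophosphorylation, phosphotransfer, promoter binding) is
compressed phenomenologically into a pure transport delay $\tau$ and a Hill
function of the active ratio $R = S_a/S_g = y/(1-y)$:

$$k_G(t) = \hat b + \hat a\,\frac{R(t-\tau)^n}{K^n + R(t-\tau)^n}
\quad\text{(activating)},$$

with the repressing form using $K^n$ in the numerator. The reporter follows
first-order production/dilution, $dG/dt = k_G - k_{dil} G$, so the
steady-state output ranges from $b=\hat b/k_{dil}$ to
$(\hat b+\hat a)/k_{dil}$ — a fold range of $(\hat b+\hat a)/\hat b$.
A single $k_{dil}$ is shared between sensor and reporter dilution by
default (one growth rate sets both); `output_params()` accepts a different
value to decouple them.

### Parameters at a glance

| Parameter | Units | Meaning | Typical default |
|---|---|---|---|
| $\hat k_1,\hat k_2$ | min⁻¹ per (µmol m⁻² s⁻¹) | unit photoconversion rates per source | $10^{-3}$–$10^{-1}$ |
| $k_{dil}$ | min⁻¹ | growth dilution, ln 2 / doubling time | ln 2/37.4 |
| $k_{dr}$ | min⁻¹ | thermal dark reversion of $S_a$ | 0 (stable) or ln 2/5.5 |
| $\tau$ | min | pure signaling delay | 6–10 |
| $n$, $K$ | — | Hill coefficient and half-maximal ratio | 1.5–2, 0.02–0.35 |
| $\hat a,\hat b$ | MEFL (or MECY) min⁻¹ | added and basal production rate | set by fold range |

Time is minutes throughout; intensities stay in µmol m⁻² s⁻¹ with the
seconds-to-minutes conversion absorbed into $\hat k_i$.

## Numerical choices

* **Common wavelength grid.** 300–1100 nm at 0.5-nm steps — the
  spectroradiometer's native increment, spanning the LED bank (369–958 nm
  centroids) and the spline's 1050-nm anchor knot. Resampling is linear,
  zero outside measured support. All integrals use the trapezoid rule on
  this grid; halving the step moves smooth overlap rates by under $10^{-4}$
  relative (tested).
* **Exact kinetics.** Under piecewise-constant light the active fraction is
  propagated by the closed-form exponential chained across breakpoints — no
  integration error, verified against a generic stiff integrator to below
  $10^{-8}$ over randomized programs.
* **Delay.** Implemented as an exact shifted evaluation of the analytic
  $y(t)$ (history = the preconditioning steady state), not a
  delay-differential solver: the input is piecewise constant and $\tau$ is
  a pure transport delay. In the fitting path the shifted lookup is
  continuous in $\tau$, so the optimizer sees smooth gradients.
* **Expression integration.** $G$ is updated per grid step with the exact
  exponential kernel; $k_G$ within a step is interpolated quadratically
  through node and midpoint values (both evaluated analytically), giving a
  fourth-order scheme. The internal grid (0.5 min) also carries every
  breakpoint and breakpoint-plus-delay instant, where $k_G$ has kinks.
  Halving the grid moves trajectories by less than $10^{-6}$ relative
  (tested).
* **Active-ratio guard.** $y$ is clamped at $1-10^{-12}$ before forming
  $R$; a clamp emits a message.
* **Grayscale export.** Intensities map linearly onto the 12-bit (0–4095)
  hardware scale, rounding half away from zero; the level→intensity→level
  round trip is the identity on all 4096 levels.

## Model parameterization

`fit_global()` minimizes the summed squared *relative* error
$\sum_i ((G_i^{data}-G_i^{model})/G_i^{data})^2$ by Levenberg–Marquardt
(`minpack.lm`), jointly over per-LED $(\hat k_1,\hat k_2)$ pairs and the
global parameters $(\hat a,\hat b,n,K,\tau,k_{dil},k_{dr})$, all on a log
scale for positivity, inside generous physical box bounds. $K$ can be
frozen (`fixed = list(big_k = ...)`), the recommended practice because $K$
is weakly determined: a change in $K$ can be compensated by rescaling the
photoconversion rates, leaving predictions nearly unchanged.
`profile_k()` quantifies this by re-optimizing the other parameters at
fixed $K$ values, warm-started along that compensation direction — on
synthetic data the re-optimized objective at $2\times K$ is
indistinguishable from the optimum.

Start points are not knowable a priori, so the fit uses a seeded
multistart: a data-driven heuristic start (basal/maximal levels set
$\hat b,\hat a$; each LED's half-response intensity sets its $\hat k_1$)
plus log-normal jitters, with a deterministic early stop (at least four
starts; stop after two consecutive non-improving starts). Replicates enter
as individual residuals, unweighted. Standard errors come from the
regression covariance via the delta method from the log scale.

`refit_output_only()` handles recalibration to a new cellular context
(e.g., a dual-sensor strain): photoconversion and kinetic rates are
properties of the photoreceptors and stay frozen; only the four Hill
parameters per output are re-estimated against a two-dimensional
green×red steady-state grid, each output independently, missing cells
simply absent.

## Continuous cross-section estimation

`fit_pcs()` regresses a piecewise-cubic spline $\sigma^{est}(\lambda)$ so
that its overlap integral with each training LED's unit spectrum matches
that LED's fitted $\hat k$ — a weighted least-squares problem (weights
$1/\mathrm{se}^2$) under exact linear equality constraints: value, first-
and second-derivative continuity at interior knots, and natural (zero
second derivative) boundary conditions. One knot is pinned at 1050 nm and
the remaining knots are spread evenly over 350–800 nm. The constrained
system is the stationarity (Lagrange) system of the problem; it is solved
by eliminating the constraints through an orthogonal null-space basis and
backsolving the reduced weighted problem by SVD, which stays stable when
the weights span many orders of magnitude (near-zero infrared rates carry
tiny standard errors). A rank-deficient constraint set is rejected with
diagnostics; near-singular data directions are truncated at $10^{-10}$ of
the leading singular value.

Knot count is chosen by leave-one-out cross-validation over 5–20 knots
(`loocv_select()`); the CV score is the weighted mean squared held-out
residual in $\hat k$ space. Two open choices are documented and switchable:
natural boundary conditions (the literature states "boundary constraints"
without a formula) and the CV error metric. Negative excursions of
$\sigma^{est}$ are *not* forbidden — they are reported as a quality flag,
since nonnegativity is not part of the estimation contract.

`predict_rate()` then predicts $\hat k$ for any new source by the same
overlap integral; spectrum power outside the spline support contributes
zero and is flagged. Prediction is linear in the spectrum, so mixtures
behave additively.

## The light program generator

`design_program()` produces a piecewise-constant intensity schedule on one
controllable channel such that the simulated output tracks a reference
waveform. References are specified as ramp/hold/sinusoid segments on a
log-scaled fraction of the output range, $G(f) = G_{min}(G_{max}/G_{min})^f$.
The design inverts the model along the reference: the required production
rate $k_G = dG_{ref}/dt + k_{dil}G_{ref}$, advanced by $\tau$ and passed
through the inverse Hill function, gives the required active ratio; its
exact flow equation is solved pointwise for the channel intensity,
accounting for any external (fixed) light signal's contribution to both
photoconversion rates. Per-segment averages of this feedforward solution
(default 10-min segments, 2-min evaluation grid) seed a bounded
derivative-free coordinate refinement against the simulated
`rmse_log10()` tracking error. This optimizer is this package's own
design, documented as an interpretation of model-based function
generation, not a reproduction of any particular implementation.

Degenerate and infeasible cases are handled explicitly: reference levels
demanding production rates outside $[\hat b, \hat b+\hat a]$, or active
fractions beyond what the channel can reach at its intensity bound, are
clipped to the achievable envelope and the program is flagged infeasible
with its clip fraction. Preconditioning defaults to the constant light
whose steady state matches the reference's initial level, as in the
corresponding experiments. Exported programs are quantized through the
12-bit grayscale mapping and re-simulated so the reported error is the
error of the program the hardware can actually play.

`design_multiplexed()` composes two single-system designs for a
dual-sensor strain: the red program is designed first against the
red-controlled output (which responds minimally to green light), then the
green program is designed with the red program injected as external light
— the compensated approach. The swapped order is available but off by
default.

## The synthetic-data generator

`make_ground_truth()` fully specifies a synthetic system: cross sections as
Gaussian mixtures, a bank of 23 Gaussian LEDs (centroids even over 369–958
nm, FWHM 25 nm, calibrated maxima 20 µmol m⁻² s⁻¹) plus named green
(526 nm) and red (657 nm) channels, kinetic and Hill parameters, and a
multiplicative log-normal noise model (default CV 10%). Defaults were fixed
once, on spectroscopic and physiological grounds, and are the package's
study conditions:

* The activating system mirrors a green/red CcaSR-like tool: ground/active
  main bands at 535/672 nm, no detectable dark reversion, dilution
  ln 2/37.4 min⁻¹, 60-fold output range, $n=2$, $K=0.35$, $\tau=10$ min.
  Its ground-state red tail is kept weak so red light predominantly
  reverts the sensor — the push–pull orthogonality that makes red-light
  compensation feasible.
* The repressing system mirrors a red/far-red Cph8-like tool: bands at
  650/705 nm, dark-reversion half-life 5.5 min, dilution ln 2/37.9 min⁻¹,
  210-fold range, $n=1.5$, $\tau=6$ min; $K=0.02$ is calibrated so the
  brightest red drives near-complete repression, reproducing the observed
  ~200-fold dose-response span.
* Both cross-section sets carry UV/blue Soret-like shoulders and broad
  inter-band amplitude, as bilin chromophores do: both photostates absorb
  across the visible with amplitudes within factors of a few. Widths stay
  ≥ 70 nm so the shapes are representable by a 5–20-knot cubic spline.
* The dual truth pairs the two systems in one cell with the recalibrated
  mCherry output: 6-fold range and half-repression at 5.2-fold higher
  intensity; the green-controlled output keeps a 56-fold range.

`generate_characterization()` reproduces the four characterization
experiment classes — step-up from dark, step-down to dark, and forward and
reverse (fixed activating background, 526 nm at 1.25 µmol m⁻² s⁻¹)
steady-state spectral sweeps with intensity ladders spanning three orders
of magnitude, time points denser early and harvest at 8 h. The benchmark
LED panels come from `responsive_leds()`, which restricts to the band where
*both* unit rates exceed 8% of their maxima: a rate ratio is only
measurable where both photostates couple to the light.

**What the generator does not emulate:** day-to-day calibration drift,
plate-position and LED-unit variability, growth-rate perturbations from
intense UV, chromophore photodegradation, autofluorescence backgrounds,
and cytometry measurement error structure beyond a single multiplicative
log-normal term. Passing recovery tests on these data therefore
demonstrates the correctness and statistical behavior of the estimation
machinery under the stated noise model — not robustness to every artifact
of real flow-cytometry experiments.

## Known limitations

* Per-LED reverse-rate ratios are only weakly identified by scaled-down
  characterization designs: with 12 LEDs × 6 intensities × 2 sweep classes
  × 3 replicates at 10% CV, the fit covariance puts 15–85% standard errors
  on individual $\hat k_1/\hat k_2$ ratios, so individual ratios can
  deviate tens of percent even when every global parameter recovers within
  a few percent. Denser ladders and replicates (as in full designs) shrink
  this; the limitation is informational, not algorithmic.
* The $y$-reduction assumes the sensor pool is at steady state (above);
  strongly perturbed growth breaks it.
* The LPG's coordinate refinement is local; it polishes the
  model-inversion seed rather than searching globally, and the seed's
  quality degrades for references demanding faster decays than dilution
  allows (those stretches are flagged as clipped).
* Photodegradation under strong UV is not modeled.
* Simulation problem sizes used by the test-suite benchmarks: 0.5-min
  internal grids over 8-h horizons, 100 randomized programs for the
  kinetics cross-check, the 12-LED scaled-down characterization design,
  and 8 broad-spectrum validation sources — full-size designs (23 LEDs ×
  12 intensities) run identically, just longer.
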