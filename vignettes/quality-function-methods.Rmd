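---
title: "Microdosimetric quality functions: models, assumptions, and numerical choices"
author: "qlineal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdosimetric quality functions: models, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlineal)
```

## The problem

Health risks from densely ionizing radiation — heavy ions in space, high-LET
fields near accelerators — are quantified relative to photons through a
quality factor. The microdosimetric route to quality factors weights the
measured (or calculated) single-event lineal-energy distribution d(y) of a
radiation field with a biological weighting function Q(y):

    Q_bar = ∫ Q(y) d(y) dy,        H = D × Q_bar

where y is lineal energy (energy imparted by a single track divided by the
mean chord length of a microscopic site, keV/µm), D is absorbed dose (Gy)
and H the dose equivalent (Sv). Because d(y) can be measured continuously
with a tissue-equivalent proportional counter or silicon microdosimeter,
this gives an in-situ readout of biologically effective dose — provided a
weighting function is available.

`qlineal` implements the full estimation pipeline for an endpoint-specific
weighting function q(y): from heavy-ion tumor dose–response data to
unfolded TE and NTE weighting functions, and onward to predictions for
arbitrary mixed-field spectra. The reference endpoint built into the
packaged parameter tables is intestinal tumor yield in tumor-prone
APC^1638N/+^ mice exposed to γ rays and six ion beams (H, He, C, O, Si, Fe;
LET 0.22–148 keV/µm).

## Spectra

A `lineal_spectrum` stores a discretized density over a strictly
increasing, positive y grid, tagged as frequency-weighted f(y) or
dose-weighted d(y). The two are related by

    d(y) = y f(y) / ∫ y f(y) dy,

and every constructor and transform renormalizes so the trapezoid integral
over the stored grid is 1 (to 1e-9). Integration is always the trapezoid
rule on the spectrum's own grid; the integrator is grid-agnostic, so
spectra spanning decades should be supplied on log-spaced grids.

In place of full radiation-transport simulations, ion beams are represented
by a triangular chord-length surrogate: f(y) = 2y/y_max² on (0, y_max] with
y_max = (3/2)·LET. This is the unique triangular form that jointly
satisfies the two moment identities ȳ_F = LET (the mean chord of a sphere)
and ȳ_D = (9/8)·LET:

```{r}
sp <- triangular_spectrum(ion_beam("Si", let = 69, energy = 300))
c(yF = mean_lineal_energy(sp, "frequency"),
  yD = mean_lineal_energy(sp, "dose"))
```

The generated grid starts at y_max/n_bins rather than 0 so that the
dose-to-frequency transform (division by y) stays well defined; with the
default 512 bins the truncated mass is ~4×10⁻⁶ and both moments are exact
to better than 0.01%. The surrogate is deliberately diameter-independent:
the spherical-target diameter (2–16 µm) had only a moderate effect on
simulated spectra for this endpoint, and it is carried as metadata only.
What the surrogate does *not* emulate: the multi-peaked fine structure of
transport-simulated spectra, energy depositions from tracks that miss the
target, and secondary-particle build-up. Tests that pass on triangular
surrogates therefore validate the pipeline's mathematics, not the fidelity
of any particular spectrum.

## Dose–response model

Tumor yield at dose D of radiation type i is modeled as

    M(D) = B + T_i · D + N_i · (1 − exp(−s · D)),

the three terms being background, targeted effects (TE; linear, slope T_i
in 1/Gy) and non-targeted effects (NTE; saturating with plateau N_i,
unitless, at rate s in 1/Gy). Modeling choices:

* **Per-mouse Poisson counts.** Tumor multiplicity per mouse is Poisson
  with mean M(D). This makes group totals sufficient, so the likelihood
  aggregates to (group, dose) cells and evaluation is O(#cells).
* **Shared B and shared s.** The unirradiated controls are a single cohort,
  so one background serves all groups; the NTE rate s is common to all
  radiation types.
* **Ion constraint.** Ion TE slopes may not fall below the γ-ray slope.
  This is reparameterized as T_i = T_γ + δ_i with δ_i ≥ 0, turning the
  linear constraint into a box bound handled directly by `L-BFGS-B` with
  analytic gradients.
* **Multistart.** The likelihood is maximized from 50 seeded uniform-random
  starts plus one moment-based start (background from controls, slope from
  a crude γ regression, plateaus from high-dose excess); the best local
  optimum wins. In practice the moment start alone almost always finds the
  optimum; the restarts guard against the occasional saddle.
* **Doses are Gy internally**; TSV files carry cGy (the unit the
  experiments were reported in) and the readers convert.
* Dose-rate effects and overdispersion are out of scope (a
  negative-binomial knob exists in the generator for sensitivity checks,
  off by default).

Confidence intervals are profile-likelihood by default (deviance cutoff
`qchisq(0.95, 1)` = 3.84, stepping outward from the MLE with warm-started
re-optimizations and bisection on the crossing), or a within-group
case-resampling bootstrap. Profiles that run into the non-negativity bound
report the bound as the one-sided limit. Relative effect metrics are the
ratios E_TE,i = T_i/T_γ and E_NTE,i = N_i/N_γ; their CIs come from
bootstrap ratio percentiles or a delta-method fallback on the observed
information.

Because the raw per-mouse data are not deposited, the packaged tables
(`apc_dose_response_params()`, `apc_effect_metrics()`) carry the published
estimates and CIs; the exact likelihood weighting and CI method behind the
published CIs are not fully specified, so re-fits of synthetic data are
validated by parameter recovery and CI coverage, not by bit-identical CI
reproduction.

## Unfolding q(y)

The weighting function is the three-parameter form

    q(y) = exp[ k1 (y/100)^k2 − k3 (y/100)^(1+k2) ],   k1,k2,k3 ∈ [0, 10],

which is 1 at y = 0, rises smoothly, and peaks then flattens or declines at
high y (energy-deposition saturation); the interior stationary point is
y* = 100·k1·k2 / (k3·(1+k2)). Folding q against a normalized dose spectrum
predicts the relative effect metric (the Fredholm kernel constant is fixed
at 1; a γ-normalized ratio form is available via `fold_relative()` when a
reference spectrum is supplied).

Unfolding minimizes the CI-weighted objective

    F = Σ_i (E_pred,i − E_obs,i)² / (CI width)²

over the [0,10]³ box from 300 seeded uniform-random starts of a bounded
quasi-Newton optimizer (objective tolerance `factr = 1e2`, i.e. ~1e-14
relative). Design choices:

* The box bounds are the *only* smoothness control — no extra penalty —
  matching how excessively sharp peaks are excluded in this methodology.
* All restart solutions are retained, sorted; ties within 1e-8 break by
  first-found order. This is the multimodality diagnostic: the TE channel
  in the published tables pins k1 at the bound 10, so recovery claims are
  made about folded *predictions*, never about raw k values.
* q is evaluated pointwise on each spectrum's own grid; `rebin_spectrum()`
  provides the refinement path for convergence checks.
* Restarts are drawn row-wise from a seeded generator, so the first m
  start points coincide for any restart budget ≥ m: the best objective is
  non-increasing in the number of restarts at fixed seed, and every run is
  deterministic given its seed.
* Overflowing objective evaluations (exp of large arguments at extreme k)
  are mapped to a large finite penalty so line searches continue.

## Synthetic data: what the generators emulate

The generators reproduce the *statistical structure* the analysis assumes,
at the study's own design:

* `simulate_tumor_counts()` draws per-mouse Poisson counts under the TE+NTE
  mean at `default_study_design()`: controls 68 mice, H 40 (50–120 cGy),
  He 92 (5–50), C 60 (10–200), O 66 (5–50), Si 136 (5–140), Fe 90 (5–160),
  γ 127 (5–200 cGy). Only the dose *ranges* and cohort totals are
  published; the 3–5 dose levels per group and the near-even allocation of
  mice across levels are this package's choices, made once as a realistic
  design. The background B is likewise unpublished; the generator default
  B = 0.7 tumors/mouse is a typical background yield for this mouse model.
* `simulate_mixture_spectrum()` builds dose-weighted mixtures of triangular
  component spectra on a merged log grid, with optional log-normal
  smearing to mimic straggling — a caricature of a GCR field, not a
  transport calculation.
* `make_unfolding_problem()` folds a known (k1,k2,k3) with the beam
  spectra, optionally adds Gaussian noise, and attaches CI widths, so the
  inverse problem can be tested with known truth.

All generators are deterministic functions of their seed.

## Validation problem sizes

The test suite validates, among other things: the two triangular moment
identities and the printed dose-mean values for all six beams; the
published-parameter effect-metric ratios to two decimals; noiseless
unfolding self-consistency at the six experimental LETs (300 restarts,
objective < 1e-6, predictions recovered to 1e-4); and parameter recovery —
100 simulated datasets at the published-parameter truth and the default
design, fitted with 12 restarts plus the moment start, profiling T_Si and
N_Si only (the scored quantities). Observed behavior at these sizes:
median absolute relative errors of a few percent and profile-CI coverage
near nominal. Noisy unfolding (noise sd = CI width/3.92, i.e. observations
perturbed at the scale their CIs claim) is checked against a χ²
plausibility band.

## Known limitations

* Triangular surrogates deviate substantially from transport-simulated
  spectra for light ions (H, He), where the published comparison itself
  shows factor-of-several differences in dose-mean lineal energy; published
  k values, R²/RMSE and environment predictions depend on those unpublished
  spectra and are reproduced here only qualitatively (shapes, orderings).
* The Poisson likelihood understates uncertainty if tumor counts are
  overdispersed; the NB generator knob allows sensitivity analysis but the
  fitter itself is Poisson.
* Profile CIs are reported at bounds when profiles hit constraints; a flat
  profile yields a warning and the search bound, not an error.
* No consensus Q(y) across endpoints is attempted: the package estimates
  endpoint-specific q(y) and can *apply* a consensus curve via the
  tabulated-weighting path of `mean_quality_factor()` when one exists.
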