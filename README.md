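# qlineal

Microdosimetric characterization of radiation quality: from single-event
lineal-energy spectra and heavy-ion tumor dose–response data to biological
weighting functions, mean quality factors, and dose equivalents.

## Who this is for

Radiation biophysicists and space-radiation risk modelers who need to

* fit a **targeted + non-targeted effects (TE+NTE)** dose–response model to
  tumor-yield data across radiation types,
* **unfold** an endpoint-specific biological weighting function q(y) from
  relative-effect metrics and dose-weighted lineal-energy spectra d(y), and
* **fold** fitted weighting functions with arbitrary (e.g. measured
  mixed-field) spectra to obtain relative effect metrics, mean quality
  factors Q̄ = ∫Q(y)d(y)dy, and dose equivalents H = D·Q̄.

## The models

**Dose response.** Tumor yield at dose D of radiation i:

    M(D) = B + T_i·D + N_i·(1 − exp(−s·D))

with shared background B (tumors/mouse), TE slope T_i (1/Gy), NTE plateau
N_i (unitless), and a shared NTE saturation rate s (1/Gy). Per-mouse counts
are Poisson; ion slopes are constrained T_i ≥ T_γ. Low-dose relative effect
metrics are E_TE,i = T_i/T_γ and E_NTE,i = N_i/N_γ.

**Weighting function.** q(y) = exp[k1·(y/100)^k2 − k3·(y/100)^(1+k2)],
k1–k3 ∈ [0,10]; q(0)=1. Its fold with a normalized dose spectrum predicts
the effect metric. Unfolding minimizes the CI-weighted least-squares
objective Σ(E_pred−E_obs)²/CI_width² with 300-restart bounded optimization.

**Spectra.** Ion beams are represented by the triangular chord-length
surrogate f(y)=2y/y_max², y_max=(3/2)·LET, which has frequency-mean LET and
dose-mean (9/8)·LET exactly.

## Worked example

Unfold the NTE weighting function from the packaged published effect
metrics for the APC1638N/+ intestinal-tumor endpoint, using triangular
surrogate spectra for the six experimental beams (LET 0.22–148 keV/µm):

```r
library(qlineal)

met    <- apc_effect_metrics()
beams  <- nsrl_beams()
spectra <- lapply(beams[met$radiation],
                  function(b) frequency_to_dose(triangular_spectrum(b)))
prob <- unfolding_problem(met$radiation, spectra, met$E_NTE,
                          met$E_NTE_hi - met$E_NTE_lo, channel = "NTE")
res <- unfold(prob, n_restarts = 300, seed = 1)
print(res)
#> Unfolded NTE weighting function (299 restarts)
#>   k1 = 2.352, k2 = 0.2692, k3 = 0.5265
#>   objective = 0.1124, R2 = 0.951, RMSE = 0.356
#>   radiation observed predicted
#> 1         H     1.44      1.59
#> 2        He     2.15      2.20
#> 3         C     4.63      3.85
#> 4         O     4.31      4.55
#> 5        Si     5.77      6.01
#> 6        Fe     5.37      5.28
```

The best-fit function rises from q(0)=1, peaks near 70–80 keV/µm, and
reproduces the observed ion-to-ion ordering of NTE metrics (R² = 0.95,
RMSE = 0.36 on this surrogate-spectrum workflow). Apply it to a mixed
field and convert dose to dose equivalent:

```r
mix <- simulate_mixture_spectrum(beams, c(0.35, 0.2, 0.1, 0.1, 0.1, 0.15),
                                 smear_sigma = 0.1, label = "GCR-like")
predict_environment(quality_function(10, 4.84, 7.85, "TE"), res$qf, mix,
                    dose_Gy = 0.3, Q_weighting = res$qf)
#> Environment prediction: GCR-like
#>   E_TE = 1.322, E_NTE = 3.221
#>   Q_bar = 3.221
#>   D = 0.3 Gy -> H = 0.9662 Sv
```

The NTE metric is ~2.4× the TE metric on this field: intermediate lineal
energies (1–50 keV/µm) drive non-targeted effects much more strongly than
targeted ones.

Synthetic data for every stage (Poisson tumor counts at the experimental
design, mixture spectra, unfolding problems with known truth) come from the
seed-deterministic `simulate_*()` / `make_unfolding_problem()` generators;
`run_pipeline()` orchestrates simulate → fit → metrics → unfold → predict
end to end, and `inst/cli/qlineal.R` exposes the same stages as shell
subcommands.

## Documentation

The methods vignette (`vignettes/quality-function-methods.Rmd`) covers the
model assumptions, the numerical choices (grids, tolerances, constraint
handling, multistart determinism), what the synthetic generators do and do
not emulate, and known limitations.
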