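# relkin

Analysis toolkit for in-vitro drug-release experiments on fibrous
(electrospun) membranes, aimed at formulation and materials scientists
who measure cumulative release curves, membrane wettability and drug
photostability and want the standard models fitted reproducibly.

A cumulative release curve — percent of the loaded drug released up to
time *t* — typically shows a fast burst followed by a slow approach to a
plateau. `relkin` fits and compares the four classical dissolution laws
on that curve:

- zero order: *Q = K₀ t*
- Higuchi: *Q = K_H √t*
- Korsmeyer–Peppas: *Q = K_R tⁿ* (*n* ≤ 0.5 indicates Fickian diffusion
  from a thin film; *n* = 0.5 is exactly the Higuchi law)
- Gompertz: *Q = Q_max exp[−α exp(β log₁₀ t)]* — the sigmoid with plateau
  *Q_max* and per-decade shape parameter *β* (negative for release)

Fits are bounded nonlinear least squares with a fixed deterministic
initialisation rule, ranked by *R²* computed against the mean-of-observed
baseline (so a plateauing curve gives the unbounded one-parameter laws a
*negative* R², a diagnostic rather than a bug). Around the core fitting
the package estimates Fickian diffusion coefficients from the short-time
(√t) and long-time (single-exponential) plane-sheet asymptotics, models
UV photodegradation as a power law *Q = Q_max (1 + t_irr)ᵇ*, and provides
mean-line roughness metrics (Ra, RMS), gravimetric liquid retention,
contact-angle summaries and MTT viability normalisation. Seeded
generators simulate every input — including the exact plane-sheet
eigenfunction series used as the diffusion oracle — so the whole pipeline
is testable without laboratory data.

## Worked example

Simulate a noisy PBS-like release curve from a Gompertz parameterization
(plateau 83%, α = 0.83, β = −2.7), compare all four models, then estimate
diffusivity and photostability:

```r
library(relkin)

rc <- generate_release_curve(
  model = "gompertz", params = c(Qmax = 83, alpha = 0.83, beta = -2.7),
  sigma = 2, seed = 1, medium = "PBS"
)
compare_models(rc)
#> Model comparison (medium 'PBS'):
#>  rank            model n_params         r2 converged
#>     1         gompertz        3  0.9961375      TRUE
#>     2 korsmeyer_peppas        2  0.6506767      TRUE
#>     3          higuchi        1 -1.4246286      TRUE
#>     4       zero_order        1 -4.1419089      TRUE
```

The sigmoid wins decisively and recovers the generating parameters; the
two unbounded one-parameter laws fit worse than a flat mean line, hence
their negative R²:

```r
fit_release_model(rc, "gompertz")
#> gompertz fit (converged): R^2 = 0.9961, 12 points
#>      Qmax     alpha      beta
#> 83.891381  0.849890 -2.743493
```

Diffusion coefficients from the two asymptotic regimes of an exact
plane-sheet curve (D = 1e−8 cm²/s, half-thickness 0.01 cm):

```r
fk <- generate_fickian_series_curve(D = 1e-8, L = 0.01,
                                    times_h = seq(0.05, 8, by = 0.05))
estimate_D_short(fk, L = 0.01, m_inf = 100)
#> D (short_time regime) = 9.967e-09 cm2/s  [L = 0.01 cm, 15 points, fit R^2 = 1.0000]
estimate_D_long(fk, L = 0.01, m_inf = 100)
#> D (long_time regime) = 1e-08 cm2/s  [L = 0.01 cm, 154 points, fit R^2 = 1.0000]
```

Photodegradation: a membrane releasing 82% unirradiated and 57% after
10 h of UV has lost 25 percentage points of active drug:

```r
pf <- fit_photolaw(irradiation_series(c(0, 0.5, 1, 2, 5, 10),
                                      c(82, 77.3, 74.6, 71.2, 63.4, 57)))
pf
#> Photodegradation power law: Qmax = 82.6%, b = -0.1502, R^2 = 0.9944
loss_at(pf, 10)        # 25.0 percentage points
loss_at_relative(pf, 10)  # 30.2 % of Qmax
```

`run_pipeline()` chains the stages (kinetics, diffusion, photostability)
over CSV inputs and writes a CSV + JSON report bundle;
`inst/scripts/relkin-cli.R` is a thin command-line front end over the
same functions (`simulate`, `fit`, `compare`, `diffusion`, `photostab`,
`roughness`, `retention`, `viability`, `run`). The methods vignette
(`vignettes/membrane-release-analysis.Rmd`) documents the models,
conventions and numerical choices.

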