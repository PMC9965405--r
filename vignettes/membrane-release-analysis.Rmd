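---
title: "Modelling drug release from fibrous membranes with relkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug release from fibrous membranes with relkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkin)
```

## The measurement and the models

The central measurement in an in-vitro release experiment is a cumulative
release curve: a membrane loaded with a known amount of drug is immersed
in a stirred medium, aliquots are withdrawn at increasing times, and the
cumulative percent of the loaded drug found in the medium, $Q(t)$, is
recorded. Curves from fibrous (electrospun) carriers typically show a
rapid burst — surface-adsorbed and near-surface drug desorbing quickly —
followed by a slower diffusion-controlled stage that approaches a plateau
below 100% (part of the load stays trapped in the polymer).

`relkin` fits four classical dissolution laws to such a curve, all on the
percent scale:

| model | equation | parameters | shape |
|---|---|---|---|
| zero order | $Q = K_0 t$ | $K_0$ (%/h) | unbounded line |
| Higuchi | $Q = K_H \sqrt{t}$ | $K_H$ (%/h$^{1/2}$) | unbounded root |
| Korsmeyer–Peppas | $Q = K_R t^n$ | $K_R$ (%/h$^n$), $n$ | unbounded power law |
| Gompertz | $Q = Q_{max} e^{-\alpha e^{\beta \log_{10} t}}$ | $Q_{max}$ (%), $\alpha$, $\beta$ | sigmoid with plateau |

Only the Gompertz sigmoid can represent the burst-then-plateau shape; the
other three are included because their failure is informative. The
Korsmeyer–Peppas exponent diagnoses the transport mechanism ($n \le 0.5$:
Fickian diffusion from a thin film; $n = 0.5$ is exactly the Higuchi
law; $n = 1$ Case-II transport, hence the fitting bound $0 < n \le 1$).

**Log base in the Gompertz model.** The shape parameter $\beta$ acts per
decade of time: we use $\log_{10} t$, the dissolution-literature
convention. The choice is observable — with a plateau of 83%,
$\alpha = 0.83$ and $\beta = -2.7$, the base-10 form gives
$Q(50\,\mathrm{h}) = 82.3\%$, i.e. a curve still just below its plateau at
two days, while a natural-log form would be fully saturated there. All
parameter values quoted by this package assume base-10.

## Fitting and comparison

`fit_release_model()` minimises the residual sum of squares in the
original (percent) coordinates. The two nonlinear models use bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`); the zero-order and Higuchi
laws are linear in their single constant and are solved in closed form.
Starting values follow a fixed deterministic rule — $Q_{max,0} = \max q$,
$\alpha_0 = -\ln(q_1/Q_{max,0})$ at the earliest positive time,
$\beta_0 = -1$, rate constants by linear regression in the transformed
coordinate, $n_0 = 0.5$ — so a fit is a pure function of its inputs; there
are no random restarts. Bounds encode physics: positive rate constants,
$0 < Q_{max} \le 110$ (headroom above 100% for noisy plateaus),
$\alpha > 0$, $0 < n \le 1$; $\beta$ is unconstrained in sign. Points at
$t = 0$ are excluded from the Gompertz and Korsmeyer–Peppas fits (the log
term, respectively the log-space initialisation, is undefined there) and
the exclusion is recorded in the fit object.

Goodness of fit is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ always taken about the mean
of the observations, including for the no-intercept one-parameter models.
This convention is what makes $R^2 < 0$ meaningful and reproducible: a
zero-order or Higuchi curve fitted to plateauing data predicts worse than
a flat line at the observed mean, and its $R^2$ goes negative.

`compare_models()` ranks fits by decreasing $R^2$; exact ties are broken
by fewer parameters (parsimony), then model name. A model that cannot be
fitted (for example a three-parameter Gompertz on a three-point curve)
does not abort the comparison — it is ranked last and carries the error
message as its diagnostic.

## Diffusion coefficients from release asymptotics

For Fickian diffusion out of a plane sheet of half-thickness $L$ with
constant $D$, the released fraction has two classical asymptotic regimes:

$$\frac{M_t}{M_\infty} = \frac{2}{L}\sqrt{\frac{Dt}{\pi}}
\quad (\text{short time}), \qquad
1 - \frac{M_t}{M_\infty} = \frac{8}{\pi^2}
\exp\!\left(-\frac{\pi^2 D t}{4 L^2}\right) \quad (\text{long time}).$$

`estimate_D_short()` regresses $M_t/M_\infty$ on $\sqrt t$ through the
origin over the points with $M_t/M_\infty \le 0.6$ (the standard validity
range of the square-root law) and inverts the slope;
`estimate_D_long()` regresses $\ln[(M_\infty - M_t)/M_\infty]$ on $t$ over
the points above 0.4 and inverts that slope, reporting the intercept for
comparison with the theoretical $\ln(8/\pi^2) \approx -0.210$. Both
cutoffs are exposed as arguments.

Three conventions matter and are deliberate:

* **$L$ is the half-thickness.** The asymptotic formulas above hold for a
  sheet releasing from both faces when $L$ is half the mat thickness;
  `run_pipeline()` therefore halves the measured `thickness_cm` before
  estimating.
* **$M_\infty$ is not observable directly.** The default policy takes the
  fitted Gompertz plateau $Q_{max}$ as the total releasable amount; the
  last observed point or an explicit value can be chosen instead
  (`m_inf_value()`), and the policy used is recorded in the output.
* **Units.** Times are stored in hours and converted to seconds
  internally, so with $L$ in cm the estimate comes out in cm²/s, the
  customary unit for drug diffusivities (values around $10^{-8}$ cm²/s).

The independent check for both estimators is the exact eigenfunction
series for the same geometry,
$M_t/M_\infty = 1 - \sum_m \frac{8}{(2m+1)^2\pi^2}
e^{-(2m+1)^2\pi^2 D t/4L^2}$, implemented in
`generate_fickian_series_curve()` with automatic term-count escalation
(the dropped tail is kept below $10^{-10}$; $t=0$ returns exactly 0). On a
series-generated curve spanning both regimes the two asymptotic estimates
recover the generating $D$ within 5% and agree with each other within
10% — this is asserted in the test suite.

## Photodegradation

UV exposure degrades part of the loaded compound, so the amount released
in a fixed 24-h window declines with irradiation time $t_{irr}$. The
decline is modelled as $Q = Q_{max}(1 + t_{irr})^b$: the $+1$ anchors
$Q_{max}$ at zero irradiation, and $b < 0$ for a photodegrading drug.
`fit_photolaw()` is a closed-form least-squares fit in log–log
coordinates ($\log Q$ vs $\log(1+t_{irr})$), hence deterministic; an
optional Levenberg–Marquardt refinement in the original coordinates is
off by default because the log-space solution is exact on clean data and
the refinement changes weighting, not substance.

Loss is reported two ways to avoid an ambiguity: `loss_at()` is the
absolute drop in percentage points ($Q_{max} - Q$; an 82% release falling
to 57% is a 25-point loss), while `loss_at_relative()` expresses the same
drop relative to $Q_{max}$ (the same change is a 30.5% relative loss).

## Roughness, retention, viability

**Roughness.** $R_a$ and RMS are computed on deviations from the mean
line: although roughness formulas are often printed as integrals of the
raw profile, a flat but offset trace must have zero roughness, so the
mean line is subtracted first. On a uniform grid the integrals reduce to
plain arithmetic means (midpoint rule); no filtering, windowing or
waviness separation is applied. Image-derived intensity profiles are
treated as heights in gray-level units (0–255) with no nm calibration —
the metrics are then dimensionless gray-level roughnesses, which is how
SEM plot-profile roughness is usually reported. `rms >= ra` always, by
the power-mean inequality.

**Retention.** The gravimetric retention degree is reported with the
signed-uptake convention $(M_{eq} - M_0)/M_0 \times 100$: positive means
liquid uptake, negative means mass loss during soaking. The opposite
orientation ($M_0 - M_{eq}$), which some reports print, is available via
`convention = "dry_minus_wet"`; the two differ only in sign and the
package treats the uptake-positive reading as canonical because that is
how gains and losses are described in prose.

**Viability.** MTT absorbances are background-corrected per well
(595 nm − 655 nm; negative corrected signals are flagged, not clipped)
and each treated group is normalised to the mean of the untreated
control wells *of the same timepoint* — cell growth makes the control
signal drift between timepoints, so a single shared baseline would
confound time with treatment. The standard error is propagated from both
groups' replicate variances by the delta method. Significance testing is
deliberately left to general-purpose tools; the table layout exports
cleanly.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, seeded and
bit-reproducible:

* `generate_release_curve()` — model-evaluated curves plus additive
  Gaussian noise in percentage points (default $\sigma = 2$, a typical
  spectrophotometric replicate spread), optional proportional term and
  physical clipping. The default grid, 12 log-spaced times in
  0.5–170 h, mirrors a week-long experiment sampled densely during the
  burst.
* `generate_fickian_series_curve()` — the exact plane-sheet series above;
  used as the oracle for the diffusion estimators.
* `generate_surface_profile()` — white noise smoothed with a Gaussian
  kernel and linearly rescaled so the realised $R_a$ equals the target
  exactly.
* `generate_irradiation_series()`, `generate_plate()` — power-law decay
  series and MTT plates (baseline 0.70 absorbance over a 0.05
  background) with seeded well noise.

These emulate the statistical structure the estimators assume — additive,
roughly homoscedastic noise around a smooth generating law. Real release
data can violate that structure: non-monotone artefacts from medium
replacement, correlated errors within a run, drug degradation during the
experiment itself. Passing the recovery tests therefore demonstrates the
estimators are correct and stable under the stated noise model, not that
any particular laboratory dataset satisfies the model.

## Numerical choices and degenerate inputs

* Levenberg–Marquardt tolerances are tightened (`ftol = ptol = 1e-13`,
  500 iterations) so noiseless self-recovery reaches at least 1e-4
  relative accuracy on all four models.
* Curves with all observations identical are rejected for multi-parameter
  models, and $R^2$ is reported as `NA` wherever the total sum of squares
  is zero, rather than dividing by zero.
* Points at $M_t \ge M_\infty$ are excluded (with a warning) from the
  long-time log regression, where they would be undefined.
* Non-positive regression slopes in either diffusion regime are flagged
  as non-physical rather than silently returning a negative $D$.
* The release-curve CSV writer prints 17 significant digits so a
  write/read cycle reproduces doubles bit-exactly.

## Problem sizes

The test suite and the bundled acceptance script run entirely on
synthetic data at modest sizes — 50 replicate curves of 12 points per
medium for the Monte-Carlo recovery study, 160-point series curves for
the diffusion checks, 1000-sample profiles for the roughness
properties — which a laptop executes in a few seconds while leaving the
Monte-Carlo means with comfortably small standard errors.

## Known limitations

* Model selection is by $R^2$ only; no information criteria or
  uncertainty on the ranking. With models of different parameter counts,
  $R^2$ favours the larger model on equal footing — ties are broken by
  parsimony, but near-ties are not.
* No confidence intervals on fitted parameters (no bootstrap or profile
  likelihood); the Monte-Carlo machinery in the generators can be used to
  build them externally.
* The diffusion analysis assumes plane-sheet geometry, constant $D$ and a
  known $M_\infty$; cylindrical/spherical geometries and
  concentration-dependent diffusivity are out of scope, and errors in the
  $M_\infty$ policy propagate quadratically into $D$.
* The photodegradation law is empirical; it describes the decline, not
  the photochemistry.
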