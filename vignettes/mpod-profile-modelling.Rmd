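---
title: "Modelling MPOD spatial profiles: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MPOD spatial profiles: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpodfit)
```

This vignette is the package's own account of its science: the two profile
models, the derived-parameter machinery, the numerical conventions, the
synthetic-data generator, and the places where the design was genuinely
open and a choice had to be made.

## The models

Macular pigment optical density (MPOD) along a radial path from the
foveolar centre is modelled as a function of eccentricity $x$ (degrees of
visual angle; MPOD in arbitrary optical-density units).

The three-Gaussian model is

$$M_{3G}(x) = \sum_{i=1}^{3} N_i\, e^{-q_i (x-g_i)^2},$$

with amplitudes $N_i \ge 0$ (a.u.), spreads $q_i$ (deg$^{-2}$) and centres
$g_i$ (deg). The component roles — 1 central peak, 2 intermediate
shoulder/eccentric peak, 3 peripheral tail — are not properties of the
algebra but of the *fitting bounds* (below). The tail spread $q_3$ is
allowed to be slightly negative: fitted populations show a small negative
mean, meaning the third component grows very slowly away from its distant
centre over the fitted window. This is a fitted-tail artefact, not
biology, and every consumer of the model (evaluation, differentiation,
integration) handles $q_3 \le 0$ explicitly.

The legacy two-component model,

$$M_{EG}(x) = A_1 e^{-p_1 x} + A_2 e^{-p_2 (x-x_2)^2},$$

is retained for comparison. It is expressed in base $e$; the original
base-10 formulation differs only by dividing the amplitudes by $\ln 10$
(`meg_to_base10()` / `meg_to_base_e()` are exact inverses). Its structural
weakness — one term must serve as both central peak and tail — is exactly
what the cross-window transfer analysis (`transfer_evaluation()`) makes
visible.

Both models are entire functions, so all derivatives exist everywhere;
the package implements orders 1–3 in closed form (for a Gaussian term,
$f' = -2qNu\,e^{-qu^2}$, $f'' = Ne^{-qu^2}(4q^2u^2-2q)$,
$f''' = Ne^{-qu^2}(12q^2u - 8q^3u^3)$ with $u = x-g$; for the exponential
term, $(-p)^k A e^{-px}$).

## Critical points and derived parameters

The second derivative of a canonically shaped declining profile traces a
fixed chain of features as $x$ increases from 0: it starts negative
(central-peak curvature), rises through a zero (**dd1**) to a maximum
(**dd2**), falls through a second zero (**dd3**) to an eccentric minimum
(**dd4**, the locus of a shoulder or eccentric peak), and rises again
through a third zero (**dd5**) to a second maximum (**dd6**, the outer
boundary of the pigment distribution).

`critical_points()` scans $M''$ on a dense grid (default step $10^{-3}$
deg), brackets sign changes of $M''$ (zeros) and of $M'''$ (extrema), and
refines each by bisection to $|\Delta x| < 10^{-6}$; reported zeros
satisfy $|M''| < 10^{-8}$ in practice. Two conventions matter:

* **The first minimum is unreported.** The curvature minimum adjacent to
  0° — often sitting on the domain boundary itself — is counted as the
  chain's first minimum, so dd4 is always the *eccentric* minimum.
* **Labels are assigned order-preservingly along the chain.** Each
  detected feature takes the earliest unfilled chain slot of its type
  (zero / max / min) at or beyond the current position. On canonical
  profiles this reproduces the count-based definitions exactly ("dd3 is
  the 2nd zero"), but on non-canonical shapes — e.g. a pure eccentric-peak
  profile whose $M''$ chain is zero, min, zero, max — it keeps the
  reported labels strictly ascending in $x$ (here dd1, dd4, dd5, dd6,
  with dd2 and dd3 absent) instead of producing a "first maximum" that
  lies beyond the "third zero". Absence is a value (`NA`), not an error.
  Features closer than twice the scan step are treated as a degenerate
  double root and merged, the extremum winning the tie.

Derived scalars (`derive_all()`):

* `A0` $= M(0)$, the central amplitude;
* `A_ecc` $= M(dd_4)$ when dd4 exists;
* `AUC02`, `AUC5`: $\int_0^{0.2} M$ and $\int_0^{5} M$ (a.u.·deg).
  Gaussian terms with $q > 0$ integrate in closed form via the error
  function; $q \le 0$ terms fall back to adaptive quadrature with absolute
  tolerance $10^{-9}$; the two routes agree to $10^{-9}$ where both apply.
  `model_volume()` similarly computes $2\pi\int_0^R M(r)\,r\,dr$, the
  relative pigment volume under the radially symmetric surface
  (instrument volume calibrations are machine-specific and deliberately
  not reproduced);
* `HHr`, the half-height radius: the eccentricity where the curve falls
  to $A_0/2$. In a non-monotonic profile the half level can be crossed
  several times, so the default convention is the *last sustained
  down-crossing* — the largest $x$ after which the curve stays below
  $A_0/2$ through the end of the domain. The half-height notion is
  intrinsically ambiguous for shouldered profiles, which is why the
  convention is configurable (`convention = "first"` gives the first
  down-crossing) and why the dd landmarks are preferable for
  non-monotonic shapes.

### Monotonicity and the central tolerance zone

A profile is classified `eccentric_peak` if $M'$ is positive anywhere
*beyond a central tolerance zone* (default 0.1°), `shoulder` if it is
monotone declining but dd4 exists, and `central_peak_monotonic`
otherwise. The tolerance zone exists because the fitted centre of the
central component may sit anywhere in $|g_1| \le 0.1°$: a central peak
displaced a few hundredths of a degree from zero makes $M'$ positive on a
sliver next to the origin, and calling that an "eccentric peak" would be
wrong — the grand-mean parameter set itself, rounded to 3 decimals, shows
exactly this artefact ($g_1 = -0.017$ puts a 0.012°-wide rising sliver at
the origin) while plainly being a monotone shouldered profile.

### Rounding sensitivity of published grand-mean values

Reconstructing the model from 3-decimal printed parameters reproduces the
published landmark eccentricities to well under ±0.02° and the half-height
radius to ±0.001°, but the amplitude/area quantities carry a systematic
~2–3% gap (A0 0.633 vs 0.649, AUC5 1.021 vs 1.048). The gap is dominated
by the tail term $0.039\,e^{0.020\,(x-10)^2}$, whose value at the origin,
$0.039\,e^{2}$, changes by ~2% when $q_3$ moves by half a printed decimal.
The published values evidently come from unrounded fit parameters; the
package's tests therefore assert eccentricities at ±0.02° and
amplitudes/areas at 3%, and treat those tolerances as input-rounding
limits, not accuracy claims.

## Fitting

`fit_mpod()` minimises the unweighted in-window sum of squared residuals
subject to box bounds, using Levenberg–Marquardt (`minpack.lm::nls.lm`).
Choices:

* **Bounds** (`default_bounds()`): $N_i \in [0,2]$, $q_1 \in [2,180]$,
  $q_2 \in [0.1,10]$, $q_3 \in [-0.1,0.1]$, $g_1 \in [-0.1,0.1]$,
  $g_2 \in [0,1.5]$, $g_3 \in [-2,10]$ (MEG: $A_i \in [0,2]$,
  $p_1, p_2 \in [0.1,20]$, $x_2 \in [0,2]$). The boxes implement the
  component-role separation; the extreme values mirror the clamps visible
  in fitted-population ranges (e.g. spread ceilings at 180 deg$^{-2}$,
  tail centres at 10°). All are user-overridable.
* **Multi-start**: one deterministic data-driven start (central value,
  tail level, residual-peak location) plus `n_starts = 8` Latin-hypercube
  starts over the box, seeded; the lowest-SSE run wins, ties broken by
  lowest start index, so fits are exactly reproducible. Multi-start
  replaces the manual parameter control an interactive fitting session
  would provide. If the winning run ends on its evaluation budget it is
  polished by a second run from its endpoint.
* **Loss**: unweighted least squares by default. Instruments report a
  circumferential SD per eccentricity, and `weighted = TRUE` uses
  $1/\mathrm{sd}$ residual weights, but the reference analyses give no
  indication of weighting, so off is the default.
* Convergence is `ftol = ptol = 1e-10`, `max_iter = 200`. A fit in which
  no start converges raises a condition of class `mpod_nonconvergence`
  that still carries the best-effort result.

`compute_sse()` reports raw a.u.²; the conventional tabulated scale is
×10⁻³. `transfer_evaluation()` fits on each window and evaluates on every
window at least as wide (fit 2°/eval 2°, fit 2°/eval 5°, fit 5°/eval 5°),
which is the design that exposes the narrow-window parameter sets'
failure to extrapolate.

## The synthetic-data generator

No individual-eye measurements are publicly available, so the package
carries a generator (`cohort_spec()`, `sample_cohort()`) whose defaults
*are* the published cohort conditions: 48 eyes; per-parameter means and
SDs of the fitted three-Gaussian population (e.g. $N_1$: 0.224 ± 0.102,
$q_2$: 1.938 ± 0.792, $g_2$: 0.547 ± 0.265); additive profile noise of
0.01 a.u.; morphometry FAZer 0.91 ± 0.19°, bwlht 123 ± 22 µm, Pr
3.96 ± 0.44°; and a dd6 linkage with standardized coefficients
(0.605, 0.426, 0.190) and population $R^2 = 0.81$.

Mechanics and their consequences:

* Parameters are drawn **independently**, truncated to the fitting box by
  rejection. Real fitted parameters are surely correlated, but no
  covariance structure is published; independence is an explicit
  limitation, and end-to-end results on synthetic cohorts must not be
  read as biology. Truncation slightly shifts sampled moments away from
  the nominal mean/SD (strongly for the heavy-tailed $q_1$ and $g_3$);
  the generator's tests therefore verify moments against the analytic
  truncated-normal values.
* Each eye's **dd6 is computed from its own parameters**, and the
  morphometry triplet (FAZer, bwlht, Pr) is then drawn *conditional on
  standardized dd6*: an equicorrelated predictor correlation matrix is
  chosen so that the stated betas achieve the stated $R^2$
  ($\rho \approx 0.25$ at $R^2 = 0.81$ — with independent predictors the
  stated betas could only reach $R^2 = 0.583$), and the predictors are
  generated as their conditional mean given dd6 plus the matching
  residual covariance. At `target_r2 = 1` the standardized dd6 is exactly
  the stated linear combination. A few percent of random draws have no
  dd6 (the second curvature maximum does not exist for every parameter
  combination — published per-variable counts show the same); those eyes
  receive unlinked morphometry and drop out of linkage analyses
  listwise.
* FAZ diameter metrics (FAZf, FAZm) share a common factor with FAZer
  (pairwise correlation ≈ 0.98), mirroring the near-total collinearity of
  FAZ measures in real cohorts; remaining morphometry fields are
  independent normals. The generator emulates parameter distributions,
  noise and the dd6 linkage — it does **not** simulate image formation,
  fixation jitter, optics, or any instrument volume calibration, so
  passing recovery tests demonstrate correctness of the estimation
  machinery, not robustness to real-world imaging artefacts.

Profiles are rendered on a default grid of 0.02°–6° in 0.02° steps
(oversampling the narrowest admissible central peak); maps are rendered
as radially symmetric pixel fields and profiles extracted back by
circular-path averaging with bilinear interpolation (360 angles), which
closes the loop to ~2.5×10⁻⁴ a.u. on a 0.02°/px map.

## The cohort statistics workflow

`factor_analysis()` is principal components on the correlation matrix;
loadings are eigenvectors scaled by $\sqrt{\lambda}$, so the full loading
matrix reconstructs the correlation matrix exactly. Retention is by the
Kaiser rule (eigenvalue > 1) unless fixed; the significance threshold is
|FL| > 0.7. No rotation is applied by default (none is documented for the
reference analysis); varimax is available, and matters: with uncorrelated
variables the eigenvalues are near-degenerate and the *unrotated* axes
are arbitrary rotations, so chance co-loadings above 0.7 appear in a
third of pure-noise replicates — after varimax they essentially never do.
Conclusions about variable grouping should be drawn from rotated
loadings, or from well-separated eigenvalues.

`multiple_regression()` and `stepwise_forward()` work on z-scored
variables (sample SD, $n-1$), report standardized betas and flag
$R^2 < 0.5$ as unlikely to be useful for prediction. Forward selection
enters the candidate with the largest F-to-enter while $p <$
`alpha_enter` (default 0.05 — the reference entry criterion is
undocumented); per-step $R^2$ increments telescope exactly to the final
$R^2$. At the default $\alpha$, a pure-noise candidate enters ~5% of the
time per step; that is a property of forward selection, not a defect.
Rows missing a derived feature (e.g. eyes without dd4) drop listwise per
analysis, matching per-variable cohort counts.

## Problem sizes used in validation

The test-suite and acceptance script use: 50 noisy profiles for
parameter recovery (noise 0.01 a.u., full default grid); a 48-eye
synthetic cohort for the model-comparison and transfer experiment; 200
simulated 48-eye cohorts for the regression-workflow recovery; 10⁴ eyes
for generator moment and $R^2$ convergence checks; and a 601×601 px,
0.02°/px map for pipeline closure. These sizes were chosen so that every
stochastic check has comfortable statistical margin while the whole suite
runs in a couple of minutes on one core.

## Known limitations

* Parameter independence in the generator (no published covariance).
* The dd6–morphometry linkage is imposed, not emergent; it validates the
  regression machinery, not the biology.
* Published numeric SSE tables for the real 48-eye cohort cannot be
  reproduced without the measured data; the package reproduces the
  orderings and magnitude relations those tables demonstrate.
* The half-height radius is convention-dependent on non-monotonic
  profiles; both conventions are provided and the dd landmarks are
  preferred.
* 2D map handling assumes a known foveolar centre and scale; no centre
  detection, registration or dual-wavelength image arithmetic is
  included.
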