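# mpodfit

Modelling the spatial profile of human macular pigment optical density.

Macular pigment (lutein, zeaxanthin and meso-zeaxanthin) concentrates in
the central retina and protects against age-related macular degeneration.
Dual-wavelength autofluorescence imaging measures its optical density
(MPOD, in arbitrary optical-density units) as a function of retinal
eccentricity `x` (degrees of visual angle), producing a radial *spatial
density profile*. Profiles vary between eyes: some decline monotonically
from a central peak, some carry an eccentric *shoulder*, and some a true
eccentric peak (a ring in the 2D map).

`mpodfit` is a toolkit for researchers who work with such profiles. It
fits, interrogates and simulates two analytic profile models:

* the three-Gaussian model

  M3G(x) = Σᵢ₌₁³ Nᵢ · exp(−qᵢ (x − gᵢ)²),

  in which component 1 carries the central peak, component 2 any shoulder
  or eccentric peak, and component 3 the peripheral tail-off (the fitted
  tail spread q₃ may be slightly negative);

* the legacy exponential-plus-Gaussian model

  MEG(x) = A₁ e^(−p₁ x) + A₂ e^(−p₂ (x − x₂)²),

  kept for comparison — it cannot capture the central peak, an eccentric
  shoulder and the tail simultaneously over a 0–5° window.

Because both models are analytic, the fitted curve can be differentiated
and integrated exactly. The zeros and turning points of the second
derivative define up to six landmark eccentricities `dd1`–`dd6`
(inflections and curvature turning points); `dd4` is the locus of an
eccentric peak or shoulder, and `dd6` marks the radial extent of the
pigment and correlates strongly with foveal morphometry (foveal avascular
zone equivalent radius, foveal bowl height, foveal pit radius). Derived
scalars include the central amplitude `A0 = M(0)`, the eccentric amplitude
`A_ecc = M(dd4)`, areas under the curve to 0.2° and 5°, and the
half-height radius.

## What is in the package

* `m3g()`, `meg()` — model constructors; `predict()` evaluates the curve
  or its analytic derivatives (orders 1–3).
* `fit_mpod()` — bounded Levenberg–Marquardt least squares over a
  configurable eccentricity window, with a deterministic heuristic start
  plus Latin-hypercube multi-starts; returns an `mpod_fit` with `print`,
  `summary`, `coef`, `predict`, `plot`, `residuals`, `simulate` methods.
* `critical_points()`, `derive_all()`, `half_height_radius()`,
  `model_auc()`, `model_volume()`, `classify_profile()` — second-derivative
  landmarks and derived parameters.
* `read_profile()`, `write_profile()`, `resample_profile()`,
  `extract_radial_profile()` — profile I/O and circular-path extraction
  from 2D MPOD maps (bilinear interpolation, circumferential mean ± SD).
* `cohort_spec()`, `sample_cohort()`, `render_profile()`, `render_map()` —
  a synthetic-data generator reproducing published parameter and
  morphometry distributions, with a dd6–morphometry linkage of chosen
  strength.
* `factor_analysis()`, `multiple_regression()`, `stepwise_forward()` — the
  variable-reduction and regression workflow used to relate profile shape
  to morphometry.
* `inst/cli/mpod.R` — a thin command-line wrapper
  (`extract`, `fit`, `derive`, `simulate`, `cohort-stats`).

## Worked example

Fit a noisy synthetic profile generated from the published grand-mean
parameters and extract its derived parameters:

```r
library(mpodfit)

gm <- m3g(N = c(0.200, 0.250, 0.039),
          q = c(14.515, 1.700, -0.020),
          g = c(-0.017, 0.562, 10.000))
prof <- render_profile(gm, noise_sd = 0.01, seed = 7)
fit  <- fit_mpod(prof, "m3g", window = c(0, 5))
summary(fit)
```

```
MPOD profile fit (m3g), window 0-5 deg, n = 250
  SSE: 0.02151 a.u.^2 (x1e3: 21.51)
  converged: TRUE  iterations: 216  winning start: 4
     N1      N2      N3      q1      q2      q3      g1      g2      g3
 0.2523  0.2214  0.0428  6.5374  2.1434 -0.0244 -0.1000  0.6551  9.0574
  residual sd: 0.009447 a.u.

derived MPOD profile parameters (domain 0 - 5 deg)
    A0  A_ecc  AUC02   AUC5    HHr
0.6422 0.4408 0.1222 1.0260 1.1699
  monotone decline: TRUE   class: shoulder
second-derivative critical points (deg), domain 0 - 5
   dd1    dd2    dd3    dd4    dd5    dd6
0.1717 0.3371 0.5706 0.7936 1.1202 1.4883
```

The SSE is the in-window sum of squared residuals (0.0215 a.u.² here is
essentially the injected noise floor: 250 points × 0.01²). The residual
sd recovers the simulated noise. The profile is classified as a
*shoulder*: it declines monotonically but has an eccentric curvature
minimum at `dd4 = 0.79°` where the model amplitude is `A_ecc = 0.44`.
`dd6 = 1.49°` marks the outer boundary of the pigment distribution —
recovered to 0.01° of the generating model's value despite the noise.
`plot(fit, derivatives = TRUE)` draws the data, the fitted curve with its
three components, and the first/second derivatives.

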