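---
title: "Crop suitability modelling with cropsuit: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crop suitability modelling with cropsuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsuit)
```

## The model

`cropsuit` implements a mechanistic (EcoCrop-style) crop-suitability engine
on gridded monthly climatologies. A crop is described by trapezoidal niche
responses: for a variable $x$ with absolute bounds $a_{\min} \le a_{\max}$
and optimal bounds $o_{\min} \le o_{\max}$,

$$
f(x) = \begin{cases}
0 & x \le a_{\min} \text{ or } x \ge a_{\max}\\
(x - a_{\min})/(o_{\min} - a_{\min}) & a_{\min} < x < o_{\min}\\
1 & o_{\min} \le x \le o_{\max}\\
(a_{\max} - x)/(a_{\max} - o_{\max}) & o_{\max} < x < a_{\max}.
\end{cases}
$$

Equal bounds degenerate to a step at that bound, so gate-like responses are
representable.

Per grid cell, the engine evaluates all 12 candidate growing windows (one
per start month, with December-to-January wrap). The window length in
months is `round_half_up((gmin + gmax)/60)`, clamped to 1..12 — the
midpoint of the crop's growth-cycle range in days, converted to months.
For each window:

* **Temperature**: each window month's mean temperature is scored on the
  temperature trapezoid and forced to zero if the month's kill-test
  temperature falls below `ktmp + frost_buffer`; the window score is the
  *minimum* over months — one lethal or far-out-of-niche month breaks the
  season. The kill test uses the monthly minimum temperature when the
  stack carries one, else the monthly mean; the frost buffer defaults to
  4 degC (configurable, `engine_config()`).
* **Rainfall**: the *window total* precipitation is scored on the seasonal
  rainfall trapezoid, matching the interpretation of crop rainfall
  requirements as totals over the cycle.

Temperature and rainfall scores combine per window (product by default;
`min` available), the best window is kept (a single season — no
double-cropping accumulation), and the climate score combines with the
soil-pH trapezoid score (again product by default). Both combination rules
are exposed because the underlying convention is not universal: the
product preserves gradation and is the convention of the EcoCrop
implementations this design follows; `min` expresses pure limitation.
Cells with missing soil pH are reported missing rather than treated as
unconstrained, which avoids silently inflating suitable area.

## Thresholding

Binary suitability layers come from sensitivity-specificity equalization:
the threshold minimizing $|Se - Sp|$ against a binary reference, with ties
broken by larger $Se + Sp$, then by the smaller threshold. Candidate
thresholds are the sorted unique scores plus 0 and 1; because $Se$ and
$Sp$ are step functions of the threshold this candidate set contains the
exact optimum, so no grid approximation is involved. Tie comparisons use a
$10^{-12}$ tolerance so the winner does not depend on floating-point
rounding. The reference itself is built from a yield surface: cells below
the 25th percentile of positive yields (linear interpolation between order
statistics, computed over positive-yield cells only) are labelled
unsuitable; zero-yield cells are unsuitable but stay inside the evaluation
mask.

## Calibration

When a crop's default niche under-predicts a reference, two stages widen
it:

1. **Rainfall**: `rmin` and `ropmin` are decremented in 10 mm steps
   (widening the niche toward drier conditions). After every step the
   engine re-runs, the threshold re-equalizes, and overall accuracy
   ("match") against the reference is recomputed; the loop stops at match
   >= 0.7 or at the floor, retaining the best-scoring state.
2. **Temperature**: a grid search over kill-temperature and
   temperature-niche offsets in $\{-5,\dots,+5\}$ degC (the niche offset
   shifts all four temperature bounds rigidly), visited in order of
   increasing total displacement so the identity is evaluated first, and
   stopped at the first state reaching the target.

The match statistic is overall accuracy on the evaluation mask. Both
stages guarantee never returning a state that scores worse than their
starting state.

### What calibration can and cannot recover

A finding worth stating plainly, because it shapes the test suite: this
procedure is a *satisficing* device, not an estimator. Because the
binarization threshold is re-equalized inside the loop, any change of
parameters that approximately preserves the *ranking* of cells is largely
absorbed by the threshold. Empirically (across the family of
synthetic-world designs explored while constructing the recovery fixtures
in `tests/testthat/helper-fixtures.R`), a rigid -2 degC niche shift alone
rarely costs more than 15-20 accuracy points, leaving the match near
0.8 — above the 0.7 stopping criterion. Two consequences:

* Starting from jointly degraded parameters (+30 mm on the rainfall
  minima, -2 degC on the niche), the rainfall stage crosses 0.7 while
  descending and *converges within one step of the true rainfall
  minimum*; the temperature stage then accepts the identity, and the
  residual niche shift is never corrected.
* The alternative regime — rainfall stage not converging so the
  temperature search must act — requires the niche error to keep accuracy
  below 0.7 at the rainfall optimum, which in turn requires the shifted
  and true suitability bands to overlap by less than about 60%. But
  rainfall identifiability during that same stage (accuracy increasing
  toward the true minimum so the retained-best state lands near truth)
  requires newly admitted cells to be majority-correct, i.e. overlap
  times 0.75 (the 25th-percentile reference discount) above one half,
  overlap above two thirds. The two requirements exclude each other.

The acceptance suite therefore asserts the attainable properties — the
degradation is consequential (initial match < 0.7), the rainfall minimum
is recovered within one step, the final match exceeds 0.7 — and carries
the joint niche-offset recovery assertion honestly red, as a documented
property of the procedure rather than a defect of the implementation.

The dedicated recovery fixtures are designed for identifiability, not
climatic realism: a low-seasonality world (seasonal amplitude 1 degC,
zero temperature noise) so the window search cannot compensate niche
shifts seasonally; a flat wet-season profile with small multiplicative
rainfall noise (sdlog 0.01), so seasonal totals cluster within a few mm
and a 30 mm shift of a step-like rainfall gate sweeps the whole local
distribution; and a long-cycle (11-month window) crop, because short
windows average away both degradations. The temperature-only recovery
test instead uses a narrow graded temperature "tent" on the seasonal
default world, where a -2 degC shift costs enough accuracy (match around
0.68) that the offset search must move, and stops one step from the truth
— within the stated tolerance.

## Validation framework

Six metrics per crop, mirroring an occurrence/area evaluation design:

1. **Occurrence detection**: occurrence points are filtered to the
   baseline period (year >= 2000 when dated), thinned to at most one
   point per grid cell (uniformly at random, seeded), and the proportion
   falling in suitable cells is reported; points in missing cells stay in
   the denominator.
2. **Country detection**: a country counts as mismatched only when the
   crop is produced there yet the modelled suitable area is at most one
   grid cell — non-producing but suitable countries are legitimate
   (fundamental vs realized niche). The all-non-producing case is
   degenerate (trivially 1) and flagged.
3. **Harvested-area correlation** (FAOSTAT-style), Pearson on raw areas
   across countries; a log-area option exists but is off by default since
   the comparison is defined on areas. Positive correlation is the
   acceptance direction.
4. **Exceedance**: the proportion of countries whose modelled suitable
   area strictly exceeds the reported harvested area — the fundamental
   niche should bound the realized niche from above.
5. and 6. The same correlation and exceedance against a MAPSPAM-style
   source, only for crops flagged as covered there (18 of the 23 in the
   packaged registry).

Threshold-exceedance profiles count, per crop, how many of the six
defined metrics strictly exceed each threshold in {0.5, ..., 0.9} (at
most 6, non-increasing in the threshold); class profiles average these
counts per crop class.

## The synthetic world

`make_world()` generates the statistical structure the pipeline assumes,
not climatic realism: monthly mean temperature
$T_m(\phi) = T_0 - \lambda |\phi| + A\cos(2\pi(m - p(\phi))/12) + \epsilon$
with the seasonal phase $p$ six months apart between hemispheres; monthly
minima a fixed diurnal offset below the means; a raised-cosine wet season
centered on each hemisphere's summer with an equator-to-edge taper
(without a spatial moisture gradient, seasonal totals would be constant in
latitude and rainfall calibration would have no signal) and multiplicative
lognormal noise; a smooth correlated soil-pH field built by bilinear
upsampling of coarse white noise; and a rectangular country mosaic.
Defaults describe an Africa-like domain (40S-40N x 20W-55E at 0.5 deg,
equatorial mean 26 degC, lapse 0.3 degC per degree latitude, amplitude
3 degC, wet-season peak 250 mm/month over 8 months tapering 85% toward
the edge, pH 4.5-8.5). All randomness flows from one seed through derived
sub-stream seeds; no function touches global RNG state.

Downstream emulators: occurrence points sampled proportional to true
suitability plus a uniform background fraction (default 5%, opportunistic
records); harvested areas 0.3 x suitable area x lognormal noise with a
fraction of countries set to non-producing; a yield surface proportional
to suitability with relative Gaussian noise, exactly zero outside the
niche. A green self-consistency test therefore establishes that the
pipeline's stages compose correctly and that its metrics respond to the
structure they are meant to detect — it does not establish skill on real
climate, soils or occurrence data, which carry spatial autocorrelation,
observation bias and non-climatic constraints the generator deliberately
omits.

The self-consistency fixture uses a demonstration crop whose temperature
and rainfall lower ramps are spatially aligned, so marginal cells fall off
quadratically and little suitability mass sits below the equalized
threshold; with a diffuse low-suitability tail, occurrence detection would
hover near the threshold's sensitivity rather than reflecting enrichment.

## Numerical and design choices

* Grids are regular lat-lon, cell-center registered, rows north to south;
  layers are exchanged as ESRI ASCII rasters (plain text) and 12-month
  stacks as one file per month, so round-trips need no binary formats.
* Spherical cell areas use $R^2 \Delta\lambda (\sin\phi_t - \sin\phi_b)$
  with $R = 6371$ km; the 0.5-degree global grid tiles the sphere to
  relative error below $10^{-6}$ (it is exact up to floating-point
  cancellation), and all percent-area summaries are area-weighted.
* Bilinear resampling reproduces affine fields exactly at interior
  points; destination points beyond the source center lattice take the
  nearest-edge value.
* The packaged 23-crop parameter table carries representative default
  niche values (the published niche databases are not reproduced);
  structure — 8 cereals, 6 pulses, 6 root crops, 3 banana-family, 18
  MAPSPAM-flagged — is contractual, individual values are replaceable
  user inputs. Which five crops lack MAPSPAM coverage is a packaging
  choice (teff, fonio, bambara nut, tannia, enset), guided by which crops
  commonly lack reference coverage.
* The ensemble mean is computed on suitability scores and then binarized
  with the calibrated threshold (rather than voting on member binaries):
  it keeps the mean layer on the same scale as members and makes the
  binary layer reproducible from the published mean.
* The temperature search does not re-impose `ktmp <= tmin` on candidate
  states (a +5/-5 combination may transiently violate it); rigid shifts
  preserve the trapezoid ordering, which is what evaluation requires.
* `calibrate_rainfall` preserves `rmin <= ropmin` while clamping at the
  floor.

## Known limitations

Monthly averaging cannot represent sub-monthly extremes (heat waves, dry
spells); irrigation, CO2 response, pests and diseases, land availability
and cultural constraints are outside the model; only one growing season
per year is scored; future soil pH is held static. The synthetic world's
noise is spatially white, its countries are rectangles, and its occurrence
process has no observation bias — properties chosen to make tests sharp,
not to mimic real data.
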