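---
title: "Models and numerical choices in paleoprod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in paleoprod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoprod)
```

`paleoprod` reconstructs whole-lake primary production histories from
dated sediment cores and relates them to an industrial-deposition
gradient and to climate.  This vignette is the package's account of the
models it implements, the tunable parameters that matter, the numerical
conventions, and what the synthetic-data tests do and do not
demonstrate about real data.

## The ²¹⁰Pb CRS chronology

Unsupported (excess) ²¹⁰Pb is atmospherically delivered and decays with
burial time; supported ²¹⁰Pb is in equilibrium with in-situ ²²⁶Ra.
`compute_unsupported()` subtracts the ²²⁶Ra proxy from total ²¹⁰Pb,
clips negatives to zero with a flag, and combines the two counting SDs
in quadrature.

The constant-rate-of-supply model assumes the flux of unsupported
²¹⁰Pb to the sediment surface is constant while the mass accumulation
rate may vary.  With cumulative unsupported inventory beneath depth
\(x\), \(A(x)\), and total inventory \(A(0)\),

\[ t(x) = \frac{1}{\lambda}\ln\frac{A(0)}{A(x)}, \qquad
   r(x) = \frac{\lambda A(x)}{C(x)}, \qquad
   \lambda = \frac{\ln 2}{22.3\ \mathrm{yr}} . \]

Numerical conventions:

* Activities are treated as constant within an interval; boundary
  inventories are sums of activity × interval dry mass, and interval
  dates use the inventory linearly interpolated to the interval's mass
  midpoint.  Depths are 0-based cm below the sediment–water interface,
  intervals half-open `[top, bottom)`.
* Inventories sum over *every* measured interval, including those below
  the detected background, and the residual inventory beneath the core
  bottom is estimated by regressing log unsupported activity on
  cumulative mass over the deepest fifth of the core and integrating
  the fitted exponential.  Without this tail term CRS ages near
  background are biased old whenever coring stops close to background
  depth — on noiseless synthetics the bias reaches decades; with it the
  closed-form ages are recovered to better than 1%.
* Background is the shallowest depth from which unsupported activity
  stays at or below `max(k·SD, floor)` for all deeper intervals
  (`k = 2`, `floor = 0.01` Bq/g by default; the absolute floor is what
  terminates noiseless profiles whose SDs are zero).
* Age uncertainty is Monte-Carlo: activities are resampled from their
  counting SDs (1000 draws by default, seeded), the full chronology —
  including the bottom-tail regression, which dominates deep-age
  uncertainty — is recomputed per draw, and 2 SDs of the date
  distribution are reported.  First-order analytic propagation was
  rejected because the log transform is strongly nonlinear near
  background.  On 200 simulated noisy cores the 2-SD envelopes cover
  the true ages for ≈97% of intervals, uniformly with depth.

Ages below background extend linearly in cumulative mass at the mean
CRS accumulation rate of the deepest third of dated intervals.  A
polynomial in midpoint depth (orders 2–4) with the depth-0 intercept
constrained to the coring year then assigns a smoothed date to every
interval; the selected order is the lowest one that is monotone over
the data range and within 0.005 adjusted R² of the next order — a
declared operationalization of "lowest order giving a reasonable fit",
since no standard criterion exists.  If no candidate is monotone the
model falls back to piecewise-linear interpolation with a warning.

`locate_cs137_peak()` validates a chronology against the 1963 fallout
maximum.  The peak is located only to within one sampling interval, so
the validation tolerance is the Monte-Carlo 2-SD *plus half the
interval's own age span*; with fine chronologies the discrete-sampling
term can exceed the counting-noise term, and omitting it would fail
cores whose dating is in fact exact.  Ties in the ¹³⁷Cs maximum break
toward the shallower interval.

## Spectral chlorophyll-a inference

Sedimentary chlorophyll-a (including its diagenetic products) is
inferred from visible reflectance spectra: absorbance
\(A = \log_{10}(1/R)\), then the area between the absorbance curve and
the straight chord joining its values at 650 and 700 nm (negative
residuals clipped), integrated by the trapezoid rule with endpoints
interpolated if unsampled.  Chord subtraction makes the metric exactly
invariant to any linear-in-wavelength absorbance offset and makes a
flat spectrum integrate to zero.  A linear calibration converts
nm·AU to mg/g dry weight; values below the 0.01 mg/g detection limit
are reported at the limit with a censoring flag.  The default
calibration (slope 1, intercept 0) is a placeholder — coefficients are
instrument- and calibration-study-specific and must be supplied for
physical units; every relative quantity downstream (enrichment
factors, Z scores, breakpoint timing) is invariant to the calibration
slope.

## Production trends

* **Enrichment factors** are mean chl-a post-2000 (window closed, the
  year 2000 included) over mean chl-a in 1955–1970, a window ending
  about 15 years before regional industrial development.  Sensitivity
  variants replace one window by the 2 or 3 most-recent intervals or
  the 2 or 3 intervals immediately preceding 1970.  EFs are invariant
  to rescaling the profile.
* **DBT classification.** Total dibenzothiophenes (parent + C1–C4
  homologues) are the regional indicator of bitumen-derived
  deposition.  Sites with DBT EF above 2 are "highly" enriched, at or
  below 2 "minimally" (a tie at exactly 2 classifies as minimally —
  documented tie-break), and sites whose DBT record does not reach the
  baseline window are "undetermined" and excluded from grouping.
* **Z scores** standardize each lake by its own full-series mean and
  sample SD; **5-year bins** are anchored at calendar multiples of 5
  (`[5k, 5k+4]`), each interval assigned by its midpoint date,
  intervals spanning more than 5 years retained.  Anchoring at
  multiples of 5 is a declared convention.
* **Breakpoint regression** fits the continuous two-segment model by
  exact conditional OLS at every admissible interior observed year
  (at least `min_edge = 3` points strictly on each side), breaking RSS
  ties toward the earliest year, then refines τ continuously between
  the neighbouring candidates.  SE(τ) combines the Gauss–Newton
  inverse-Jacobian term with a resolution term — the variance of a
  uniform distribution over one local observation gap — added in
  quadrature; simulation shows the combined SE is calibrated (92–95%
  coverage of ±2 SE at the weakest detectable effect, four noise-SDs
  per decade) where the Gauss–Newton term alone is optimistic.  The F
  test compares against an intercept-only null with df (3, n − 4); a
  single-line null is available by argument.  Whether a lake is
  *suitable* for breakpoint analysis (stable baseline, no outlier-driven
  timing) is caller-supplied metadata, not auto-detected — inventing a
  detection rule would put an undocumented analysis choice inside the
  package.
* **Group tests.** Welch's unequal-variance t-test compares mean chl-a
  EF between DBT groups (group sizes are very unequal, so pooled
  variance would be inappropriate); Pearson correlations with the
  usual t-based p relate binned Z scores to binned climate series.
  Both wrap the standard R implementations; the package's tests check
  them against hand computations and a permutation oracle.  Seasons
  are meteorological (winter = Dec–Feb, spring = MAM, summer = JJA,
  fall = SON).

## Deposition mapping

Loading (mg/m²) is concentration (mg/L) × snow-water equivalent (mm),
since 1 mm SWE is 1 L/m².  The empirical semivariogram (mean of half
squared differences per distance bin, default 15 bins to half the
maximum pair distance) is fitted by least squares weighted by pair
counts.  For robustness the fit profiles over the range parameter: at
fixed range the curve is linear in (nugget, partial sill), solved by
constrained WLS, with a log-spaced grid plus golden-section refinement
over range — this avoids the wild range estimates a general-purpose
optimizer produces on fluctuating empirical variograms.  Models:
exponential (range = e-folding distance; the default), spherical,
gaussian.  Coordinates are projected metres; geographic coordinates
must be projected before kriging.

Ordinary kriging solves the standard system with weights constrained
to sum to 1 via a Lagrange multiplier, per grid-cell centre (default
1-km cells).  Duplicate site coordinates are averaged with a warning.
Exactness at data sites holds with a zero nugget.  Leave-one-out
cross-validation re-predicts each site with the fixed variogram.
Radial integration sums cells whose *centre* lies inside the disc
(no partial-cell weighting — simple, testable, and convergent: halving
the cell size twice at least halves the error on smooth fields, and at
1-km cells analytic disc integrals are matched within 0.1%), clipping
negative predictions to zero since loadings are physical masses.
Day-count normalization scales a seasonal load by the ratio of
snow-accumulation days under a constant daily-deposition assumption.

A single-realization caveat: variogram parameters estimated from one
300-site field carry large sampling error (the range especially), so
the package's recovery check simulates many independent fields from a
known exponential model — 100 locations sampled in triplicate, the way
snow surveys use duplicate QC samples, which is also what identifies
the nugget — and requires the *median* of the estimates to recover the
truth within 25%.  A per-realization requirement at that tolerance is
not statistically attainable and would test luck, not code.

## The synthetic-data generators

`simulate_core()` is the forward model of everything above: constant
²¹⁰Pb flux over a constant or piecewise mass-accumulation history
(unsupported activity \(f e^{-\lambda t}/r\) evaluated at interval
mass midpoints), multiplicative Gaussian counting noise with a
configurable CV (a counting-statistics approximation; detector physics
is out of scope), a Gaussian-in-age ¹³⁷Cs pulse (SD 3 yr) centred on
the interval nearest the fallout year, a flat-baseline chl-a history
with a linear post-breakpoint rise and additive Gaussian noise
(optionally AR(1); the default is white noise since within-lake noise
autocorrelation is uncharacterized), reflectance spectra whose
triangular 675-nm absorbance peak inverts the configured calibration
exactly, and a step-function DBT history.  `simulate_snow_grid()`
places jittered grid sites around an exponentially decaying
industry-centred plume with nugget noise; `simulate_climate()` makes
linearly warming annual and seasonal temperature series and trendless
precipitation.  Every generator takes an explicit seed and restores
the caller's RNG state.

Default study conditions: cores of 110 × 0.5-cm intervals at
0.1 g/cm² and 0.05 g/cm²/yr (2 yr per interval, ~220 yr of record,
background reached around 190 yr), flux 0.2 Bq/cm²/yr over 0.05 Bq/g
supported activity, 8–10% counting CV, chl-a baseline 0.03 mg/g with
0.0012 mg/g/yr post-breakpoint slope and 0.0015 mg/g noise; snow
grids of 80–100 sites over a 200-km square with a 25-km plume decay
length.  These are values a field program in a boreal
oil-sands-region setting would recognize; they were fixed once when
the generators were written.  In the default pipeline configuration
the DBT onset year is 1971 so that the 1955–1970 baseline window is
genuinely pre-industrial — with an instantaneous step onset inside the
baseline window, the configured enrichment ratio would not equal the
measured EF (real DBT histories ramp up; the generator's step
function is the simplification documented in its help page).

What passing tests show — and do not.  The generators share the
estimators' structural assumptions (constant flux, single pulse,
single breakpoint, isotropic plume, Gaussian noise).  Recovery
therefore demonstrates correctness of the numerics and calibration of
the uncertainty statements *under those assumptions*; it cannot
demonstrate robustness to focusing, bioturbation, compaction beyond
the supplied dry-mass profile, multi-source plumes, anisotropy, or
non-Gaussian counting error, none of which are modelled.

## Problem sizes used by the checks

The shipped checks run at sizes chosen to make sampling error small
relative to the tolerances: 200 simulated cores (1000 Monte-Carlo
draws each) for envelope coverage, 100 cores for ¹³⁷Cs validation, 200
simulations for breakpoint SE calibration, 25 fields of 300 sites for
variogram recovery, and a 120-km × 120-km 1-km grid for the disc
integrals.  A 350-interval noiseless core verifies the CRS closed form
(deep enough that the residual unsupported activity is below 1% of the
surface value, so quadrature rather than truncation limits accuracy).

## Known limitations

* CIC / CF:CS alternative ²¹⁰Pb models are not implemented.
* Breakpoint SE assumes the dates are exact; when dates come from a
  CRS chronology the dating 2-SD at the breakpoint should be added in
  quadrature by the user (the pipeline's tests do exactly that).
* The kriging neighbourhood is global (all sites per node), suitable
  for the ~100–300-site surveys targeted here, not for thousands of
  sites.
* Calibration coefficients for the spectral inference must come from
  an external calibration study; only relative results are meaningful
  under the placeholder defaults.
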