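---
title: "Measuring carnivore niche overlap: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring carnivore niche overlap: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympatric)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
data emulate (and what they do not), and the numerical decisions taken where
the methods literature leaves room.

## The question and the study design

Interference competition between a dominant and a subordinate carnivore —
wolves and coyotes here — is inferred from overlap in three niche axes:
diel activity timing, diet, and space use. All three are compared across
three calendar periods tied to white-tailed deer fawn availability:

* **PPP** (preparturition), May 1–26: only adult deer on the landscape;
* **LMP** (fawn limited mobility), May 27–June 30: immobile fawns within the
  coyote's optimal prey size;
* **SMP** (fawn social mobility), July 1–August 31: fawns mobile and grown
  past coyote-optimal size.

Both period boundaries are inclusive and year-independent
(`assign_period()`); dates are taken in local study time with no time-zone
conversion. Deer enter the pipeline only as occurrence-probability rasters;
when deer collar data are available, `fit_vhf_od()` builds those rasters, and
adult deer require at least 20 relocations (fawns 5 — demanding adult-level
counts of animals with high early mortality would bias the average toward
survivors). Wolves and coyotes are never count-filtered: their inclusion is
decided by collar data recovery, not location counts.

## Movement model

### The Brownian bridge and its motion variance

The occurrence distribution (OD) treats the animal's path between consecutive
fixes as a Brownian bridge. With fixes $z_0$ at $t_0$ and $z_1$ at $t_1$
($T = t_1 - t_0$ minutes), the position at fractional time $a$ is bivariate
normal with mean $z_0 + a(z_1 - z_0)$ and per-axis variance

$$\sigma^2(a) = T\,a(1-a)\,\sigma^2_m + \big((1-a)\,\delta_0\big)^2 +
\big(a\,\delta_1\big)^2,$$

where $\sigma^2_m$ is the Brownian motion variance in m²/min (the package's
time unit throughout — movement-model software often leaves this implicit)
and $\delta$ are the fixes' location-error SDs.

$\sigma^2_m$ is estimated by leave-one-out likelihood over *alternate*
interior fixes: every second interior fix is predicted from the bridge
spanned by its two neighbors, so prediction triples share no fixes and their
residuals are independent. The predicted variance for the left-out fix adds
its own measurement error $\delta_i^2$ to $\sigma^2(a)$ — omitting either
ingredient has measurable consequences. Using all interior fixes makes
neighboring residuals strongly correlated and badly miscalibrates the
windowed model comparison below (spurious break rates near 44% on
constant-variance tracks in our experiments); omitting $\delta_i^2$ inflates
$\hat\sigma^2_m$ by $\delta_i^2 / (T a(1-a))$, which at 15-min fixes with
5-m error turns a true 2 m²/min into about 5.3. The likelihood is maximized
by bounded one-dimensional search on the log scale over
$[10^{-6}, 10^{3}]$ m²/min.

### Dynamic variance and breakpoints

Behavior changes the diffusion rate, so the dynamic model slides a window of
23 fixes (5.75 h at 15-min fixes) one fix at a time, comparing a no-break
model against single-break models at every position at least 5 fixes
(the *margin*) from either window edge. The criterion is BIC on the window's
leave-one-out likelihood, counting the break model's parameters honestly: two
variances *plus the estimated break position* (three) against one. Each
window contributes estimates only for segments at least a margin from its
edges (edge-adjacent estimates rest on too few triples), and a segment's
$\sigma^2_m$ is the mean over contributing windows. Tracks shorter than the
window fall back to the static fit with a warning.

Two honest statistical limits are worth knowing. First, a window's
$\hat\sigma^2_m$ rests on roughly 10 independent triples (20 observations),
so its relative SD is bounded below by $\sqrt{2/20} \approx 32\%$; a
"constant" track's profile therefore fluctuates segment-to-segment by design,
while its *mean* tracks the static estimate within a few percent — that mean
is what the package's tests check. Second, individual window break positions
are noisy for the same reason, so `profile_breakpoint()` estimates the
change position from the whole profile with a rank-CUSUM changepoint
(ranks tame the heavy-tailed per-segment estimates; the CUSUM peak is the
least-squares single changepoint). On two-phase tracks
(0.5 → 8 m²/min at fix 300 of 600) this lands within one fix of the truth
across seeds.

### From bridges to the occurrence distribution

Each retained segment's bridge density is integrated over fractional time by
Gauss–Legendre quadrature with 10 nodes (configurable). The integrand — the
probability mass falling in each grid cell as a function of $a$ — is smooth,
so a handful of nodes is effectively exact; we verified 3-significant-figure
agreement against a 2000-step quadrature oracle. Cell masses are computed as
exact normal-CDF integrals over cell rectangles (separable by axis), not as
center-density × area: the cell-integrated form is bounded by 1 and remains
well-defined when the bridge variance shrinks toward zero at segment
endpoints, where the center-density form diverges non-integrably for
coincident fixes. (A `method = "center"` option retains the cruder form.)
Mass beyond 6 bridge SDs of each evaluation point is truncated; the tests
bound the total truncated mass below $10^{-3}$.

Heights are normalized to sum to one, and the $99\%$ contour mask — the
smallest set of cells whose summed height reaches the level, ties at the
threshold included — defines the area *available* to the individual for the
resource-use regression. Segment state assignment is strict: an "active" OD
uses only segments whose both endpoint fixes are active (mixed segments are
dropped), since the behavioral state of a mixed segment is genuinely
ambiguous at 15-min resolution. VHF deer ODs use a single static
$\sigma^2_m$ and skip any segment (or estimation triple) spanning more than
48 h, so that only plausibly related movements connect fixes.

The analysis grid is the landscape raster's 30 × 30 m grid; free-standing ODs
(`od_grid()`) buffer the track's bounding box by three times the 99th
percentile of bridge SDs.

## Resource utilization functions

Each individual × period × state OD is regressed by ordinary least squares on
the covariate stack over its in-mask cells: distances to road, water, and
land-cover edge (m), patch size (ha), hare and grouse densities, adult and
fawn deer occurrence, and — for coyotes only — the predicted wolf surface.
Continuous covariates are z-scored *per individual over that individual's
in-mask cells*, so standardized coefficients are comparable across
individuals before averaging; land cover is dummy-coded against deciduous
forest (the most common class). OD heights enter untransformed. Plain OLS is
used rather than a spatially-correlated-error variant: the population-level
inference below consumes only between-individual coefficient variance, never
the cell-level standard errors that spatial correlation would distort.

Before fitting, covariate pairs with $|r| > 0.7$ (strict; pairs at exactly
0.7 are kept) are resolved by dropping the member lower in a configurable
ecological-priority order; land cover is always retained.

Population-level coefficients are the across-individual mean with the
$n-1$-denominator sample variance — deliberately conservative, since it
carries both intra- and inter-individual variation — and t-based intervals
with $n-1$ degrees of freedom at $\alpha = 0.05$. The wolf prediction surface
is the min–max-rescaled linear predictor of the pooled wolf population RUF
for the period, computed from unstandardized coefficients; coyote RUFs refuse
to fit without it, enforcing the wolf-before-coyote pipeline ordering.

Cross-validation withholds one individual per fold, rebuilds the population
RUF from the rest, predicts over the grid, pairs predictions with the
withheld OD's in-mask heights, sorts by prediction, and splits into 8 bins of
equal cell counts with remainder cells in the last bin. Bin sums of OD are
regressed on bin sums of prediction; fold slopes and $R^2$ are averaged,
unweighted. One subtlety the tests exposed: because the remainder lands in
the *highest-prediction* bin, cell counts not divisible by 8 add a small
positive slope bias (more cells means more summed OD mass). At landscape
scale ($10^4$–$10^5$ cells) this is negligible; our null-behavior tests use
grids with cell counts divisible by the bin count so the artifact cannot
masquerade as predictive skill. Where the withheld OD and the training
prediction cover different extents, they are intersected.

## Activity

A 5-min interval is active when its summed accelerometer reading is at least
30.7 (unitless, inclusive boundary). Fixes take the state of the
nearest-in-time interval midpoint, earlier interval on ties, and `unknown`
(excluded from both state-filtered ODs) when no interval lies within one fix
interval — missing accelerometer coverage must not silently become
"inactive".

Species-level activity densities pool the start times of all active
intervals, one unweighted event each (individuals contribute in proportion
to their data volume, the pooling the species-level Δ implies). The density
is a von Mises kernel estimate on the 24-h clock with the plug-in reference
concentration $\nu = \big[3 n \hat\kappa^2 I_2(2\hat\kappa) / (4 \sqrt{\pi}
I_1(\hat\kappa)^2)\big]^{2/5}$, $\hat\kappa$ the ML von Mises concentration
of the data; a bandwidth multiplier is exposed. Densities are evaluated on a
512-point grid in clock time (sunrise/sunset anchoring is out of scope), and

$$\hat\Delta = \int_0^{24} \min\{\hat f_1(t), \hat f_2(t)\}\,dt$$

is computed by the rectangle rule, which on a periodic uniform grid equals
the trapezoid rule; 3-decimal agreement against a $10^6$-point oracle is
tested. This is the smoothed-density min-integration estimator — the form
recommended for small samples in the activity-overlap literature. Welch's
one-tailed unequal-variance t test compares per-individual proportions of
time active between species; a zero-variance degenerate case is flagged
`NA` rather than tested.

## Diet

Track-confirmed scats take the track's species; track-free scats are coyote
at diameter ≤ 28.1 mm, wolf at ≥ 29.0 mm, and excluded strictly between
(between the coyote third quartile and the wolf first quartile, where the
species cannot be told apart). Diet proportions are the mean over scats of
per-scat volume fractions, renormalized — matching how per-item percent
volumes are reported in the field literature; a pooled-volume alternative is
a single code path away but not the default. The item taxonomy is fixed at
seven classes (adult deer, fawn, snowshoe hare, ruffed grouse, rodents,
seeds, other), with "other" absorbing unknowns.

Dietary breadth is $B = 1/\sum p_i^2$ and food-niche overlap is Pianka's
symmetric

$$\alpha = \frac{\sum p_i q_i}{\sqrt{\sum p_i^2 \sum q_i^2}}.$$

The radical in the denominator matters: without it the index is neither
bounded by one nor scale-symmetric, contradicting the index's defining 0–1
range. Per-item volumes are compared between species by one-way ANOVA on
per-scat fractions, with means reported as percents and the coyote:wolf mean
ratio alongside.

## What the synthetic data emulate — and what they do not

`synthetic_scenario()` encodes the study conditions as defaults: 11 wolves
and 13 coyotes with usable collars, 15-min fixes, 5-min accelerometer
intervals, a two-peak (dawn 5.5 h, dusk 20.5 h, concentration 3) crepuscular
schedule scaled to a mean 35% of intervals active, GPS error 10 m and VHF
error 100 m, scat diameters Normal(25.2, 4.4) mm for coyotes and
Normal(33.3, 6.1) mm for wolves, and per-scat Dirichlet compositions with
concentration 10 around species/period diet vectors (wolf deer-heavy and
narrowest during LMP; coyote broader, more rodents and hare). Movement is a
two-state Brownian walk (active 8, inactive 0.5 m²/min) whose states follow
the simulated accelerometer series, giving the dynamic variance model a
recoverable signal. True state sequences are emitted for recovery tests but
never consumed by the pipeline.

What is deliberately absent: territoriality and home-range structure,
avoidance or attraction between individuals, movement responses to the
landscape (so pipeline RUFs on simulated tracks estimate near-zero effects —
coefficient recovery is instead validated on constructed occurrence surfaces
with known effects), autocorrelated behavior bouts, fix loss, and habitat-
dependent detection. Passing tests therefore demonstrate that the estimators
recover what they are defined to estimate under the models' own assumptions —
not that those assumptions hold in any particular field system.

Test and example problem sizes (20–40-cell grids, 100–600-fix tracks, 3–5
individuals per species, tens of scats per cell) are the package's choice of
desk-scale defaults; every size is an argument, and the field-scale defaults
remain in the scenario object.

## Numerical choices and degenerate inputs

* Optimizer: `stats::optimize` on $\log\sigma^2_m$, tolerance $10^{-8}$;
  agreement with a 6000-point grid search is tested to 1%.
* Quadrature: 10 Gauss–Legendre nodes per segment (configurable).
* Zero-variance bridge evaluations (coincident noiseless fixes) place their
  mass in the containing cell.
* Contour ties at the threshold height are all included; a level of 1 returns
  every positive-height cell.
* Constant covariates are dropped from RUF designs with a warning, as are
  rank-deficient land-cover dummies; fewer in-mask cells than parameters is
  an error for a single fit and a skip-with-warning inside the pipeline.
* Correlation screening compares $|r|$ against the cutoff with a $10^{-9}$
  epsilon so floating-point equality at the boundary keeps both covariates.
* The Welch test is flagged `NA` when both groups have zero variance; ANOVA
  on identical groups reports $F = 0$, $p = 1$.
* All generators are pure functions of (scenario, seed); the pipeline seeds
  once from the config and reproduces byte-identical tables.

## Known limitations

* OLS on OD heights ignores spatial autocorrelation of residuals;
  population-level inference is insulated by using only between-individual
  variance, but individual-level standard errors are optimistic.
* The dBBMM profile is a windowed average, not a changepoint reconstruction:
  abrupt transitions are smeared over roughly a window width, and
  per-segment values carry irreducible sampling noise (see the information
  bound above).
* Δ carries no confidence interval (point estimates only, matching the
  reporting convention of the field); bootstrap CIs would require resampling
  individuals, not intervals.
* The diameter rule misassigns the overlapping tails of the two species'
  diameter distributions outside the exclusion band; with track confirmation
  on a subset this is the accepted field trade-off.
* Simulated landscapes use Voronoi patches and smooth prey fields — useful
  geometry for testing distance transforms and regressions, far simpler than
  real land-cover mosaics.
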