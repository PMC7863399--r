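# sympatric

Quantifying niche overlap between sympatric carnivores — wolves (*Canis
lupus*) and coyotes (*C. latrans*) — from accelerometer-enabled GPS collars,
scat contents, and landscape covariates. The package asks the interference-
competition question: across the three periods defined by white-tailed deer
fawn availability (preparturition, PPP, May 1–26; limited mobility, LMP,
May 27–June 30; social mobility, SMP, July 1–August 31), how much do the two
species overlap in *when* they are active, *what* they eat, and *where* they
occur?

It is written for movement ecologists who have collar, scat, and raster data
in hand (or want to validate the analysis chain on simulated data first):
everything is a tibble in and a tibble (or a small S3 result with
`tidy()`/`glance()`/`autoplot()` methods) out.

## The methods at its core

**Occurrence distributions (dBBMM).** Between consecutive fixes z₀ (time t₀)
and z₁ (time t₁) the animal's position at fractional time *a* is treated as a
Brownian bridge: Normal with mean z₀ + a(z₁ − z₀) and per-axis variance
T·a(1−a)·σ²ₘ + ((1−a)δ₀)² + (aδ₁)², where σ²ₘ is the Brownian motion
variance (m²/min) and δ are location-error SDs. σ²ₘ is estimated by
maximizing the leave-one-out likelihood of interior fixes; the *dynamic*
model lets σ²ₘ vary along the path via a sliding window (23 fixes, margin 5)
with BIC breakpoint detection. Integrating each bridge over time onto a
30 × 30 m grid and normalizing gives the occurrence distribution (OD); the
99% contour is the availability boundary.

**Resource utilization functions (RUF).** Each individual's OD height is
regressed (OLS) on z-scored prey and landscape covariates over its in-mask
cells, with land cover dummy-coded against deciduous forest. Population-level
coefficients average individuals,

&nbsp;&nbsp;β̄ᵢ = (1/n) Σⱼ β̂ᵢⱼ,&nbsp;&nbsp;&nbsp;
Var(β̄ᵢ) = 1/(n−1) Σⱼ (β̂ᵢⱼ − β̄ᵢ)²,

with t-based inference at α = 0.05. The population wolf surface (min-max
rescaled linear predictor) enters each coyote RUF as an avoidance covariate.
Fit is validated by leave-one-individual-out cross-validation: predictions
paired with the withheld OD, sorted, binned into 8 equal-count groups, bin
sums regressed, slope and R² averaged over folds.

**Activity overlap (Δ).** 5-min accelerometer sums at or above 30.7 mark
active intervals. Active start times are pooled per species, smoothed with a
von Mises kernel density on the 24-h clock (plug-in reference bandwidth), and
compared by the coefficient of overlapping Δ = ∫ min(f̂₁, f̂₂) — 0 is no
overlap, 1 identical timing. A one-tailed Welch t test compares per-individual
proportions of time active.

**Diet (B, α).** Scats are assigned by tracks when present, otherwise by
diameter (≤ 28.1 mm coyote, ≥ 29.0 mm wolf, the band between excluded).
Per-item percent-volume proportions pᵢ give dietary breadth B = 1/Σpᵢ² and
Pianka's food-niche overlap α = Σpᵢqᵢ/√(Σpᵢ²·Σqᵢ²); per-item volumes are
compared between species by one-way ANOVA.

**Synthetic data.** `synthetic_scenario()` + `simulate_scenario()` generate
landscapes (Voronoi land-cover patches, exact distance transforms, smooth
prey fields), two-state Brownian tracks driven by a crepuscular activity
schedule, accelerometer streams, and Dirichlet scat compositions — so the
full pipeline runs and is tested with no field data.

## Worked example

```r
library(sympatric)
sc <- synthetic_scenario(n_wolves = 2, n_coyotes = 2, rng_seed = 42)

# activity overlap between the two species during the preparturition period
series <- dplyr::bind_rows(
  simulate_activity(sc, "W1", "wolf",   "2014-05-01", 4000, seed = 1),
  simulate_activity(sc, "W2", "wolf",   "2014-05-01", 4000, seed = 2),
  simulate_activity(sc, "C1", "coyote", "2014-05-01", 4000, seed = 3),
  simulate_activity(sc, "C2", "coyote", "2014-05-01", 4000, seed = 4)
) |> classify_activity(threshold = 30.7)
activity_overlap(series, period = "PPP")
#> <overlap_result> Delta(wolf, coyote) = 0.970 [kernel min-integration (Dhat1)]

# diet breadth and overlap from simulated scats
scats <- dplyr::bind_rows(
  simulate_scats(sc, "wolf",   "LMP", 150, seed = 5),
  simulate_scats(sc, "coyote", "LMP", 150, seed = 6)
)
diet_overlap_table(scats, periods = "LMP")
#> # A tibble: 1 × 6
#>   period n_wolf n_coyote B_wolf B_coyote alpha
#>   <chr>   <int>    <int>  <dbl>    <dbl> <dbl>
#> 1 LMP       145      141   3.39     4.66 0.961

# dynamic Brownian bridge occurrence distribution for one collared wolf
tr <- simulate_track(sc, "W1", "wolf", "2014-05-01", 300, error_sd = 10,
                     seed = 7)$track
prof <- fit_dynamic_motion_variance(tr, window = 23, margin = 5)
od <- occurrence_distribution(tr, prof, od_grid(tr, prof), level = 0.99)
od
#> <occurrence_dist> 10 x 11 cells of 30 m; 99% mask: 23 cells
```

Both species share the simulated crepuscular schedule, so Δ is high; the
simulated wolf is the deer specialist (smaller B) and the coyote the
generalist (larger B), with the diet overlap α near its observed field range.
`autoplot(od)` maps the OD; `run_full_analysis(out_dir)` chains every stage
(ODs → wolf RUFs → wolf surface → coyote RUFs → CV → diet → activity) and
writes all result tables.

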