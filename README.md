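# paleoprod

Tools for asking a recurring question in aquatic ecology: when lakes
across an industrializing region become more productive, is the driver
local industrial deposition or regional climate?  `paleoprod`
implements the full inference chain used to answer it from lake
sediments and snowpack surveys:

1. **²¹⁰Pb chronologies.** The constant-rate-of-supply (CRS) model
   dates each sediment interval from cumulative unsupported ²¹⁰Pb
   inventories, `t(x) = λ⁻¹ ln[A(0)/A(x)]` with `λ = ln 2 / 22.3 yr⁻¹`,
   with ¹³⁷Cs 1963 fallout-peak validation, Monte-Carlo 2-SD age
   envelopes, extrapolation below the ²¹⁰Pb background, and a
   polynomial age-depth model constrained through the coring year.
2. **Spectral chlorophyll-a.** Whole-lake primary production inferred
   from sediment visible-reflectance spectra: the chord-subtracted
   absorbance peak area over 650–700 nm, mapped to mg chl-a per g dry
   sediment by a linear calibration with a 0.01 mg/g detection limit.
3. **Production trends.** Enrichment factors (post-2000 mean over the
   1955–1970 pre-industrial baseline mean, with interval-count
   sensitivity variants), dibenzothiophene (DBT) enrichment factors and
   threshold-2 site classification, per-lake Z scores, 5-year binning,
   continuous two-segment breakpoint regression with an F test, Welch
   t-tests and Pearson correlations against climate series.
4. **Deposition mapping.** Snowpack nutrient loadings (mg/m² =
   concentration mg/L × snow-water equivalent mm), empirical
   semivariograms with weighted-least-squares model fits, ordinary
   kriging with leave-one-out cross-validation, radius-integrated
   deposition in tonnes, and day-count normalization between snow
   seasons.
5. **Synthetic data.** Generators for cores, snow grids and climate
   series with the statistical structure the analysis assumes, so the
   entire chain is testable without field data.

## Worked example

```r
library(paleoprod)

## simulate a core, date it, and recover the production breakpoint
cfg <- core_sim_config(coring_year = 2012, n_intervals = 110,
                       dry_mass_per_interval = 0.1, mass_accum_rate = 0.05,
                       chla_breakpoint_year = 1975, chla_post_slope = 0.0012,
                       counting_error_cv = 0.08, seed = 2)
core <- simulate_core(cfg)
prof <- as_radionuclide_profile(core$intervals)
chron <- crs_age_model(prof, coring_year = 2012, seed = 1)
chron <- fit_age_depth_polynomial(extrapolate_below_background(chron))
chron
#> 210Pb CRS age-depth model
#>   coring year: 2012   total inventory A(0): 6.514 Bq/cm2
#>   background depth: 54 cm
#>    108 CRS-dated + 2 extrapolated intervals, 1813.7 - 2011.1 CE
#>   smoothed: polynomial order 2

locate_cs137_peak(core$intervals, chron)$year
#> [1] 1962.211      # CRS date at the 137Cs maximum; true fallout peak 1963

fit_breakpoint(chron$year, core$intervals$chla_mg_g, lake_id = "demo")
#> Two-segment fit [demo]: breakpoint 1975.7 +/- 1.0 yr
#>   slopes 8.058e-06 (pre) -> 0.001216 (post);  F(3, 106) = 965, p = 9.13e-77
```

The configured breakpoint (1975) is recovered within one standard
error, with a flat pre-industrial baseline and the configured
post-breakpoint slope (0.0012 mg/g/yr).

The whole chain, including deposition mapping and climate
correlations, runs from one call:

```r
res <- run_pipeline(default_run_config(seed = 1))
print(res)          # enrichment factors by DBT group, breakpoint
                    # timeline, climate correlations, tonnes deposited
```

The bundled 23-site enrichment-factor table ships with the package:

```r
table1_summary()$chla_ef_mean   # 1.760870 -> mean chl-a enrichment 1.8
table1_summary()$welch          # groups not significantly different
```

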