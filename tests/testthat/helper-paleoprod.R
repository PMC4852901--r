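# Shared fixture builders.  All cores use the constant-flux forward model;
# the "oracle" core is deep, finely sliced and noiseless so the CRS
# closed form t = m/r applies almost exactly.

oracle_core_config <- function(seed = 1L) {
  core_sim_config(
    coring_year = 2011, n_intervals = 350,
    interval_thickness_cm = 0.5, dry_mass_per_interval = 0.05,
    pb210_flux = 0.2, supported_activity = 0.05, mass_accum_rate = 0.05,
    counting_error_cv = 0, chla_noise_sd = 0, seed = seed
  )
}

# moderately noisy field-like core: 0.5-cm slices, 2 yr per interval,
# background reached around 190 yr depth
noisy_core_config <- function(seed, cv = 0.1) {
  core_sim_config(
    coring_year = 2012, n_intervals = 110,
    interval_thickness_cm = 0.5, dry_mass_per_interval = 0.1,
    pb210_flux = 0.2, supported_activity = 0.05, mass_accum_rate = 0.05,
    cs137_peak_activity = 0.25,
    counting_error_cv = cv, chla_noise_sd = 0.0015, seed = seed
  )
}

# simple dated profile for enrichment-factor tests
ef_profile <- function(baseline_years = c(1955, 1960, 1965, 1970),
                       modern_years = c(2001, 2003, 2005, 2007, 2009, 2011),
                       baseline_value = 1, modern_value = 2) {
  data.frame(year = c(modern_years, baseline_years),
             chla_mg_g = c(rep(modern_value, length(modern_years)),
                           rep(baseline_value, length(baseline_years))))
}

# two-segment test series
segment_series <- function(years = 1950:2000, tau = 1970,
                           base = 1, slope = 0.1) {
  list(year = years, value = base + pmax(years - tau, 0) * slope)
}
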