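#' Configuration for a synthetic sediment core
#'
#' Parameters of the forward model used by [simulate_core()].  The core is
#' generated under the constant-rate-of-supply assumption: unsupported
#' 210Pb arrives at a constant flux `pb210_flux` (Bq/cm2/yr) while sediment
#' accumulates at `mass_accum_rate` (g/cm2/yr, a scalar or one value per
#' interval for a piecewise history), so the unsupported activity at a
#' mass depth corresponding to age t is `pb210_flux * exp(-lambda * t) /
#' rate`.  Chlorophyll-a follows a flat baseline until
#' `chla_breakpoint_year` and then rises linearly at `chla_post_slope`;
#' total dibenzothiophenes sit at `dbt_background` until `dbt_onset_year`
#' and at `dbt_background * dbt_enrichment_ratio` afterwards.
#'
#' @param coring_year Calendar year the core was collected.
#' @param n_intervals Number of sediment intervals (surface downward).
#' @param interval_thickness_cm Thickness of each interval, cm.
#' @param dry_mass_per_interval Dry mass per interval, g/cm2 (scalar or
#'   vector of length `n_intervals`).
#' @param pb210_flux Unsupported 210Pb supply rate, Bq/cm2/yr.
#' @param supported_activity Supported (226Ra-equilibrium) activity, Bq/g.
#' @param mass_accum_rate Dry-mass accumulation rate, g/cm2/yr; scalar or
#'   per-interval vector (piecewise history).
#' @param cs137_peak_year Calendar year of the fallout maximum (1963).
#' @param cs137_peak_activity Peak 137Cs activity, Bq/g.
#' @param cs137_pulse_sd Width (SD, years) of the Gaussian fallout pulse.
#' @param chla_baseline Pre-breakpoint chlorophyll-a, mg/g dry weight.
#' @param chla_breakpoint_year Calendar year production starts rising.
#' @param chla_post_slope Post-breakpoint trend, mg/g per yr.
#' @param chla_noise_sd Additive Gaussian noise on chlorophyll-a, mg/g.
#' @param chla_ar1 Lag-1 autocorrelation of the chlorophyll-a noise
#'   (default 0, i.e. white noise).
#' @param dbt_background Pre-industrial total DBT concentration, ng/g.
#' @param dbt_onset_year Calendar year industrial DBT deposition begins.
#' @param dbt_enrichment_ratio Post-onset / background DBT ratio.
#' @param counting_error_cv Coefficient of variation of radiometric
#'   counting noise (multiplicative Gaussian on activities).
#' @param calibration Spectral calibration used to synthesize reflectance
#'   spectra; see [chla_calibration()].
#' @param lake_id Identifier attached to the core.
#' @param seed Integer seed; all randomness in [simulate_core()] flows
#'   from it.
#'
#' @return An object of class `core_sim_config` (a list).
#' @export
core_sim_config <- function(coring_year = 2011,
                            n_intervals = 40,
                            interval_thickness_cm = 0.5,
                            dry_mass_per_interval = 0.125,
                            pb210_flux = 0.2,
                            supported_activity = 0.05,
                            mass_accum_rate = 0.05,
                            cs137_peak_year = 1963,
                            cs137_peak_activity = 0.2,
                            cs137_pulse_sd = 3,
                            chla_baseline = 0.02,
                            chla_breakpoint_year = 1980,
                            chla_post_slope = 0.002,
                            chla_noise_sd = 0.002,
                            chla_ar1 = 0,
                            dbt_background = 20,
                            dbt_onset_year = 1967,
                            dbt_enrichment_ratio = 5,
                            counting_error_cv = 0.1,
                            calibration = chla_calibration(),
                            lake_id = "SIM-1",
                            seed = 1L) {
  check_positive(n_intervals, "n_intervals")
  check_positive(interval_thickness_cm, "interval_thickness_cm")
  check_positive(dry_mass_per_interval, "dry_mass_per_interval")
  check_positive(pb210_flux, "pb210_flux")
  check_positive(supported_activity, "supported_activity")
  check_positive(mass_accum_rate, "mass_accum_rate")
  check_positive(dbt_background, "dbt_background")
  check_positive(dbt_enrichment_ratio, "dbt_enrichment_ratio")
  check_positive(chla_baseline, "chla_baseline")
  if (chla_noise_sd < 0 || counting_error_cv < 0) {
    stop_invalid("noise parameters must be non-negative")
  }
  if (chla_breakpoint_year >= coring_year) {
    stop_invalid("chla_breakpoint_year must precede coring_year")
  }
  cfg <- as.list(environment())
  class(cfg) <- "core_sim_config"
  cfg
}

#' Simulate a sediment core under the CRS forward model
#'
#' Generates one lake's core: radionuclide activities (total 210Pb, 226Ra,
#' 137Cs) with multiplicative counting noise, a chlorophyll-a history with
#' its reflectance spectra, total-DBT concentrations, and the true ages of
#' every interval for recovery tests.
#'
#' Interval i (surface downward) spans true ages determined by the
#' accumulation history: the age of its mass midpoint is
#' `t_mid = t_top + (dm/2)/r_i`.  The true unsupported activity there is
#' `pb210_flux * exp(-lambda * t_mid) / r_i`; the 137Cs pulse is a
#' Gaussian in age centred on the interval whose true year is closest to
#' `cs137_peak_year`.  Reflectance spectra carry a triangular 675-nm
#' absorbance peak whose chord-subtracted area inverts the configured
#' calibration, so the spectral inference round-trips exactly when noise
#' is off.
#'
#' @param config A [core_sim_config()].
#' @return An object of class `sediment_core`: a list with elements
#'   `lake_id`, `coring_year`, `intervals` (data frame: depths, dry mass,
#'   activities with SDs, chlorophyll-a, DBT analytes, true ages/years)
#'   and `spectra` (long data frame: interval, wavelength_nm,
#'   reflectance), plus the generating `config`.
#' @export
simulate_core <- function(config) {
  stopifnot(inherits(config, "core_sim_config"))
  n <- config$n_intervals
  dm <- rep_len(config$dry_mass_per_interval, n)
  r <- rep_len(config$mass_accum_rate, n)
  lam <- PB210_LAMBDA

  top <- (seq_len(n) - 1L) * config$interval_thickness_cm
  bottom <- top + config$interval_thickness_cm
  ## boundary and mass-midpoint true ages from the accumulation history
  t_bound <- cumsum(dm / r)
  t_top <- c(0, t_bound[-n])
  t_mid <- t_top + (dm / 2) / r
  true_year <- config$coring_year - t_mid

  unsupported <- config$pb210_flux * exp(-lam * t_mid) / r
  supported <- rep(config$supported_activity, n)

  cv <- config$counting_error_cv
  with_seed(config$seed, {
    noise <- function(x) pmax(x * (1 + stats::rnorm(n, 0, cv)), 0)
    pb210 <- noise(unsupported + supported)
    ra226 <- noise(supported)
    ## 137Cs: Gaussian pulse in age centred on the interval closest to the
    ## fallout year
    i_peak <- which.min(abs(true_year - config$cs137_peak_year))
    cs_true <- config$cs137_peak_activity *
      exp(-(true_year - true_year[i_peak])^2 / (2 * config$cs137_pulse_sd^2))
    cs137 <- noise(cs_true)

    ## chlorophyll-a history: flat baseline, post-breakpoint linear rise
    chla_true <- config$chla_baseline +
      pmax(true_year - config$chla_breakpoint_year, 0) * config$chla_post_slope
    eps <- stats::rnorm(n, 0, config$chla_noise_sd)
    if (config$chla_ar1 != 0) {
      phi <- config$chla_ar1
      for (i in 2:n) eps[i] <- phi * eps[i - 1] +
          sqrt(1 - phi^2) * eps[i]
    }
    chla <- pmax(chla_true + eps, 0)
  })

  ## total DBTs split over the five analytes in fixed proportions
  dbt_total <- ifelse(true_year >= config$dbt_onset_year,
                      config$dbt_background * config$dbt_enrichment_ratio,
                      config$dbt_background)
  prop <- c(dbt = 0.1, c1 = 0.2, c2 = 0.3, c3 = 0.2, c4 = 0.2)
  dbt <- outer(dbt_total, prop)
  colnames(dbt) <- c("dbt_ng_g", "c1_dbt_ng_g", "c2_dbt_ng_g",
                     "c3_dbt_ng_g", "c4_dbt_ng_g")

  intervals <- data.frame(
    lake_id = config$lake_id,
    top_cm = top, bottom_cm = bottom,
    dry_mass_g_cm2 = dm,
    pb210_Bq_g = pb210, pb210_sd = cv * (unsupported + supported),
    ra226_Bq_g = ra226, ra226_sd = cv * supported,
    cs137_Bq_g = cs137, cs137_sd = cv * cs_true,
    chla_mg_g = chla,
    dbt, check.names = FALSE,
    true_age_yr = t_mid, true_year = true_year,
    true_unsupported = unsupported, true_chla = chla_true,
    stringsAsFactors = FALSE
  )

  spectra <- synth_spectra(chla, config$calibration)
  structure(list(lake_id = config$lake_id,
                 coring_year = config$coring_year,
                 intervals = intervals, spectra = spectra,
                 config = config),
            class = "sediment_core")
}

## Build per-interval reflectance spectra (640-710 nm, 1-nm steps) with a
## baseline absorbance of 0.5 and a triangular 675-nm peak whose
## chord-subtracted area equals (chla - intercept)/slope.
synth_spectra <- function(chla, calibration) {
  wl <- 640:710
  shape <- pmax(1 - abs(wl - 675) / 25, 0)  # unit-height triangle on 650-700
  out <- lapply(seq_along(chla), function(i) {
    area <- max((chla[i] - calibration$intercept) / calibration$slope, 0)
    height <- area / 25   # triangle area = 0.5 * 50 * height
    absorb <- 0.5 + height * shape
    data.frame(interval = i, wavelength_nm = wl,
               reflectance = 10^(-absorb))
  })
  do.call(rbind, out)
}

#' @export
print.sediment_core <- function(x, ...) {
  cat("Synthetic sediment core", x$lake_id, "\n")
  cat("  cored", x$coring_year, "-", nrow(x$intervals), "intervals to",
      max(x$intervals$bottom_cm), "cm\n")
  cat("  true ages", round(min(x$intervals$true_age_yr), 1), "-",
      round(max(x$intervals$true_age_yr), 1), "yr\n")
  invisible(x)
}

#' Configuration for a synthetic snow-sampling grid
#'
#' Parameters for [simulate_snow_grid()]: a quasi-regular grid of snow
#' sites around an industrial source whose nutrient loading decays
#' exponentially with distance (an isotropic plume) on top of a regional
#' background, plus unstructured (nugget) noise.
#'
#' @param n_sites Number of snow sites (at least 5).
#' @param extent_km Half-width of the square sampling domain, km.
#' @param center Numeric length 2, x/y of the industrial source, km.
#' @param background_loading Regional background loading, mg/m2.
#' @param plume_amplitude Loading excess at the source, mg/m2.
#' @param plume_decay_km e-folding distance of the plume, km.
#' @param nugget_sd SD of unstructured site noise, mg/m2.
#' @param swe_mean,swe_sd Snow-water equivalence distribution, mm.
#' @param analyte Label for the simulated nutrient.
#' @param seed Integer seed.
#' @return An object of class `snow_sim_config`.
#' @export
snow_sim_config <- function(n_sites = 100,
                            extent_km = 100,
                            center = c(0, 0),
                            background_loading = 5,
                            plume_amplitude = 30,
                            plume_decay_km = 25,
                            nugget_sd = 1,
                            swe_mean = 100, swe_sd = 15,
                            analyte = "TN",
                            seed = 1L) {
  if (n_sites < 5) stop_invalid("n_sites must be at least 5 (variogram unfittable)")
  check_positive(extent_km, "extent_km")
  check_positive(plume_decay_km, "plume_decay_km")
  check_positive(swe_mean, "swe_mean")
  if (background_loading < 0 || plume_amplitude < 0 || nugget_sd < 0) {
    stop_invalid("loadings and noise must be non-negative")
  }
  cfg <- as.list(environment())
  class(cfg) <- "snow_sim_config"
  cfg
}

#' Simulate a snowpack nutrient-sampling grid
#'
#' Places `n_sites` on a jittered regular grid over the square domain and
#' draws a loading at each as background + plume + nugget noise, truncated
#' at zero.  Concentrations are back-computed as loading / SWE so that
#' [site_loading()] round-trips.
#'
#' @param config A [snow_sim_config()].
#' @return A data frame of class `snow_sites`: `site_id`, `x_m`, `y_m`
#'   (projected metres), `swe_mm`, `conc_mg_L`, `loading_mg_m2`,
#'   `true_loading_mg_m2`, with the analyte label as attribute.
#' @export
simulate_snow_grid <- function(config) {
  stopifnot(inherits(config, "snow_sim_config"))
  n <- config$n_sites
  side <- ceiling(sqrt(n))
  cell <- 2 * config$extent_km / side
  gx <- seq(-config$extent_km + cell / 2, config$extent_km - cell / 2,
            length.out = side)
  grid <- expand.grid(x = gx, y = gx)[seq_len(n), ]
  with_seed(config$seed, {
    grid$x <- grid$x + stats::runif(n, -cell / 4, cell / 4)
    grid$y <- grid$y + stats::runif(n, -cell / 4, cell / 4)
    d <- sqrt((grid$x - config$center[1])^2 + (grid$y - config$center[2])^2)
    loading <- config$background_loading +
      config$plume_amplitude * exp(-d / config$plume_decay_km) +
      stats::rnorm(n, 0, config$nugget_sd)
    loading <- pmax(loading, 0)
    swe <- pmax(stats::rnorm(n, config$swe_mean, config$swe_sd),
                config$swe_mean / 10)
  })
  out <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                    x_m = grid$x * 1000, y_m = grid$y * 1000,
                    swe_mm = swe,
                    conc_mg_L = loading / swe,
                    loading_mg_m2 = loading,
                    true_loading_mg_m2 = config$background_loading +
                      config$plume_amplitude * exp(-d / config$plume_decay_km),
                    stringsAsFactors = FALSE)
  attr(out, "analyte") <- config$analyte
  class(out) <- c("snow_sites", "data.frame")
  out
}

#' Configuration for synthetic climate series
#'
#' @param start_year,end_year Calendar span (end after start).
#' @param base_temp Mean annual temperature at `start_year`, deg C.
#' @param trend Linear warming trend, deg C per yr (applied to the annual
#'   and all seasonal series).
#' @param noise_sd Interannual SD of temperatures, deg C.
#' @param precip_mean,precip_sd Annual precipitation distribution, mm
#'   (trendless).
#' @param season_offsets Named numeric offsets of the four meteorological
#'   seasons (winter = Dec-Feb, spring = MAM, summer = JJA, fall = SON)
#'   from the annual mean, deg C.
#' @param seed Integer seed.
#' @return An object of class `climate_sim_config`.
#' @export
climate_sim_config <- function(start_year = 1916, end_year = 2014,
                               base_temp = 0.5, trend = 0.02,
                               noise_sd = 0.8,
                               precip_mean = 450, precip_sd = 70,
                               season_offsets = c(winter = -17, spring = 1,
                                                  summer = 15, fall = 2),
                               seed = 1L) {
  if (end_year <= start_year) stop_invalid("end_year must exceed start_year")
  if (noise_sd < 0 || precip_sd < 0) stop_invalid("noise SDs must be non-negative")
  check_positive(precip_mean, "precip_mean")
  cfg <- as.list(environment())
  class(cfg) <- "climate_sim_config"
  cfg
}

#' Simulate annual and seasonal climate series
#'
#' Annual and four seasonal temperature series share the configured linear
#' trend with independent Gaussian noise; precipitation is trendless
#' noise truncated at zero.
#'
#' @param config A [climate_sim_config()].
#' @return A data frame of class `climate_series`: `year`, `temp_annual`,
#'   `temp_winter`, `temp_spring`, `temp_summer`, `temp_fall`,
#'   `precip_mm`.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "climate_sim_config"))
  yr <- config$start_year:config$end_year
  n <- length(yr)
  drift <- config$trend * (yr - config$start_year)
  with_seed(config$seed, {
    out <- data.frame(
      year = yr,
      temp_annual = config$base_temp + drift + stats::rnorm(n, 0, config$noise_sd)
    )
    for (s in names(config$season_offsets)) {
      out[[paste0("temp_", s)]] <- config$base_temp +
        config$season_offsets[[s]] + drift + stats::rnorm(n, 0, config$noise_sd)
    }
    out$precip_mm <- pmax(stats::rnorm(n, config$precip_mean, config$precip_sd), 0)
  })
  class(out) <- c("climate_series", "data.frame")
  out
}
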