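#' Default pipeline configuration
#'
#' Builds a complete simulation-mode configuration for [run_pipeline()]:
#' a set of synthetic lakes spanning minimally and highly DBT-enriched
#' conditions with staggered production breakpoints, a snow-sampling
#' grid with an industry-centred plume, a warming climate series, and
#' the analysis settings (enrichment windows, DBT threshold, breakpoint
#' edge rule, variogram family, integration radius).
#'
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_lakes Number of simulated lakes (default 6).
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, n_lakes = 6L) {
  dbt_ratios <- rep_len(c(0.9, 1.5, 1.9, 3, 7, 20), n_lakes)
  bp_years <- rep_len(c(1950, 1968, 1975, 1982, 1990, 1996), n_lakes)
  lakes <- lapply(seq_len(n_lakes), function(i) {
    core_sim_config(
      coring_year = 2012, n_intervals = 110,
      interval_thickness_cm = 0.5, dry_mass_per_interval = 0.1,
      pb210_flux = 0.2, supported_activity = 0.05, mass_accum_rate = 0.05,
      chla_baseline = 0.03, chla_breakpoint_year = bp_years[i],
      chla_post_slope = 0.0012, chla_noise_sd = 0.0015,
      dbt_background = 25, dbt_onset_year = 1971,
      dbt_enrichment_ratio = dbt_ratios[i],
      counting_error_cv = 0.08,
      lake_id = sprintf("LAKE-%02d", i),
      seed = seed * 131L + i
    )
  })
  structure(list(
    seed = as.integer(seed),
    lakes = lakes,
    calibration = chla_calibration(),
    ef = list(modern = c(2000, Inf), baseline = c(1955, 1970)),
    dbt_threshold = 2,
    breakpoint = list(min_edge = 3),
    dating = list(n_mc = 500, k = 2, floor = 0.01),
    snow = snow_sim_config(n_sites = 80, extent_km = 100,
                           plume_decay_km = 25, nugget_sd = 1,
                           seed = seed * 977L + 7L),
    variogram = list(model = "exponential", n_lags = 12),
    deposition = list(cell_size = 2000, radius = 50000, center = c(0, 0),
                      days_source = 117.5, days_target = 117.5),
    climate = climate_sim_config(start_year = 1916, end_year = 2012,
                                 trend = 0.02, noise_sd = 0.8,
                                 seed = seed * 313L + 3L),
    bin_width = 5
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep the [default_run_config()] values;
#' `lakes`, `snow` and `climate` entries are lists of arguments to the
#' corresponding `*_sim_config()` constructors, and `calibration` to
#' [chla_calibration()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(y$seed)) y$seed else 1L)
  if (!is.null(y$lakes)) {
    cfg$lakes <- lapply(y$lakes, function(a) do.call(core_sim_config, a))
  }
  if (!is.null(y$snow)) cfg$snow <- do.call(snow_sim_config, y$snow)
  if (!is.null(y$climate)) cfg$climate <- do.call(climate_sim_config, y$climate)
  if (!is.null(y$calibration)) {
    cfg$calibration <- do.call(chla_calibration, y$calibration)
  }
  for (nm in intersect(names(y), c("ef", "breakpoint", "dating",
                                   "variogram", "deposition"))) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], y[[nm]])
  }
  for (nm in intersect(names(y), c("dbt_threshold", "bin_width"))) {
    cfg[[nm]] <- y[[nm]]
  }
  cfg
}

## md5 of the deparsed config, for provenance stamping
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> date -> infer chlorophyll-a -> trends
#' -> deposition and returns a result bundle.  Each stage halts with the
#' stage name and offending lake/site on failure.  Re-running with an
#' identical configuration reproduces the bundle exactly: all randomness
#' flows from seeds recorded in the configuration.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional directory; when given, the chronology,
#'   chlorophyll-a, enrichment/breakpoint/classification, correlation
#'   and deposition tables are written there as delimited text.
#' @param quiet Suppress per-stage messages.
#' @return A list of class `pipeline_result`: `chronologies` (per-lake
#'   `age_depth_model`s), `chla_profiles`, `ef_table`, `ef_variants`,
#'   `breakpoints`, `classification`, `correlations`, `cs137`,
#'   `deposition` (variogram, field, cv, tonnes), `climate`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for ", id, ": ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- simulate cores -------------------------------------------------
  say("simulating ", length(config$lakes), " cores")
  cores <- lapply(config$lakes, function(cf) {
    stage("simulate", cf$lake_id, simulate_core(cf))
  })
  names(cores) <- vapply(cores, `[[`, "", "lake_id")

  ## --- dating ---------------------------------------------------------
  say("dating cores (CRS + extrapolation + polynomial)")
  chronologies <- lapply(cores, function(co) {
    stage("date", co$lake_id, {
      prof <- as_radionuclide_profile(co$intervals)
      m <- crs_age_model(prof, co$coring_year,
                         n_mc = config$dating$n_mc,
                         seed = config$seed + match(co$lake_id, names(cores)),
                         k = config$dating$k, floor = config$dating$floor)
      m <- extrapolate_below_background(m, prof)
      fit_age_depth_polynomial(m)
    })
  })
  cs137 <- lapply(names(cores), function(id) {
    stage("cs137", id,
          locate_cs137_peak(cores[[id]]$intervals, chronologies[[id]]))
  })
  names(cs137) <- names(cores)

  ## --- spectral chl-a -------------------------------------------------
  say("inferring chlorophyll-a from spectra")
  chla_profiles <- lapply(names(cores), function(id) {
    stage("chla", id, {
      co <- cores[[id]]
      sp <- split(co$spectra, co$spectra$interval)
      inf <- do.call(rbind, lapply(sp, chla_from_spectrum,
                                   calibration = config$calibration))
      prof <- data.frame(lake_id = id,
                         year = chronologies[[id]]$year,
                         chla_mg_g = inf$chla_mg_g,
                         censored = inf$censored)
      attr(prof, "lake_id") <- id
      prof
    })
  })
  names(chla_profiles) <- names(cores)

  ## --- production trends ----------------------------------------------
  say("computing enrichment factors, classification, breakpoints")
  variants <- c("primary", "last2", "last3", "pre1970_2", "pre1970_3")
  ef_variants <- do.call(rbind, lapply(chla_profiles, function(p) {
    do.call(rbind, lapply(variants, function(v) {
      e <- stage("trends", attr(p, "lake_id"),
                 enrichment_factor(p, modern = config$ef$modern,
                                   baseline = config$ef$baseline, variant = v))
      data.frame(lake_id = e$lake_id, variant = v, ef = e$ef,
                 n_modern = e$n_modern, n_baseline = e$n_baseline)
    }))
  }))
  rownames(ef_variants) <- NULL

  dbt_efs <- vapply(names(cores), function(id) {
    co <- cores[[id]]
    prof <- data.frame(year = chronologies[[id]]$year,
                       dbt_total_ng_g = total_dbt(
                         co$intervals$dbt_ng_g, co$intervals$c1_dbt_ng_g,
                         co$intervals$c2_dbt_ng_g, co$intervals$c3_dbt_ng_g,
                         co$intervals$c4_dbt_ng_g))
    r <- dbt_enrichment_factor(prof, modern = config$ef$modern,
                               baseline = config$ef$baseline, lake_id = id)
    r$ef
  }, numeric(1))

  ef_table <- data.frame(
    lake_id = names(cores),
    chla_ef = ef_variants$ef[ef_variants$variant == "primary"],
    dbt_ef = dbt_efs
  )
  classification <- classify_sites(ef_table, threshold = config$dbt_threshold)

  breakpoints <- lapply(chla_profiles, function(p) {
    stage("breakpoint", attr(p, "lake_id"),
          fit_breakpoint(p$year, p$chla_mg_g,
                         min_edge = config$breakpoint$min_edge,
                         lake_id = attr(p, "lake_id")))
  })

  ## --- climate correlations -------------------------------------------
  say("climate correlations on 5-yr binned Z scores")
  climate <- simulate_climate(config$climate)
  correlations <- stage("correlate", "climate",
                        climate_correlations(chla_profiles, classification,
                                             climate, config$bin_width))

  ## --- deposition mapping ---------------------------------------------
  say("snow loadings, variogram, kriging, radial integration")
  deposition <- stage("deposition", attr(config$snow, "analyte"), {
    sites <- simulate_snow_grid(config$snow)
    vg <- fit_variogram(sites, model = config$variogram$model,
                        n_lags = config$variogram$n_lags)
    ext_m <- config$snow$extent_km * 1000
    field <- ordinary_kriging(sites, vg,
                              cell_size = config$deposition$cell_size,
                              extent = c(-ext_m, ext_m, -ext_m, ext_m))
    cv <- cross_validate(sites, vg)
    tonnes <- integrate_radius(field, config$deposition$center,
                               config$deposition$radius)
    tonnes_norm <- day_normalize(as.numeric(tonnes),
                                 config$deposition$days_source,
                                 config$deposition$days_target)
    list(sites = sites, variogram = vg, field = field, cv = cv,
         radius = config$deposition$radius,
         tonnes = as.numeric(tonnes), tonnes_day_normalized = tonnes_norm)
  })

  res <- structure(list(
    cores = cores, chronologies = chronologies, cs137 = cs137,
    chla_profiles = chla_profiles, ef_table = ef_table,
    ef_variants = ef_variants, classification = classification,
    breakpoints = breakpoints, correlations = correlations,
    climate = climate, deposition = deposition,
    provenance = list(seed = config$seed, config_md5 = config_hash(config))
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir)
  res
}

## Pearson correlations of group-pooled, 5-yr-binned chl-a Z scores
## against binned annual and seasonal temperatures.
climate_correlations <- function(chla_profiles, classification, climate,
                                 bin_width = 5) {
  temp_cols <- grep("^temp_", names(climate), value = TRUE)
  groups <- list(
    highly = classification$lake_id[classification$group == "highly"],
    minimally = classification$lake_id[classification$group == "minimally"],
    all = classification$lake_id
  )
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (!length(ids)) next
    pooled <- do.call(rbind, lapply(chla_profiles[ids], function(p) {
      data.frame(year = p$year, z = zscores_keep(p$chla_mg_g))
    }))
    zb <- bin_5yr(pooled$year, pooled$z, width = bin_width)
    for (cc in temp_cols) {
      tb <- bin_5yr(climate$year, climate[[cc]], width = bin_width)
      m <- merge(zb, tb, by = "bin_start", suffixes = c("_z", "_t"))
      if (nrow(m) >= 3 && stats::sd(m$mean_z) > 0 && stats::sd(m$mean_t) > 0) {
        r <- pearson_with_p(m$mean_z, m$mean_t)
        out[[length(out) + 1]] <- data.frame(
          group = g, series = sub("^temp_", "", cc),
          r = r$r, p = r$p, n = r$n)
      }
    }
  }
  do.call(rbind, out)
}

## zscores() aligned to the input length (NA-preserving)
zscores_keep <- function(x) {
  z <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  z[ok] <- zscores(x[ok])
  z
}

write_pipeline_tables <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$chronologies)) {
    write_chronology_table(res$chronologies[[id]],
                           file.path(out_dir, paste0("chronology_", id, ".tsv")),
                           lake_id = id)
  }
  chla <- do.call(rbind, res$chla_profiles)
  write_table_(chla, file.path(out_dir, "chla_profiles.tsv"))
  write_table_(res$ef_variants, file.path(out_dir, "ef_variants.tsv"))
  write_table_(res$classification, file.path(out_dir, "classification.tsv"))
  bp <- do.call(rbind, lapply(res$breakpoints, function(b) {
    data.frame(lake_id = if (is.null(b$lake_id)) NA else b$lake_id,
               tau = b$tau, tau_se = b$tau_se,
               slope_pre = b$coefficients["slope_pre"],
               slope_post = b$coefficients["slope_post"],
               F = b$F, p = b$p, n = b$n, applicable = b$applicable)
  }))
  write_table_(bp, file.path(out_dir, "breakpoints.tsv"))
  if (!is.null(res$correlations)) {
    write_table_(res$correlations, file.path(out_dir, "correlations.tsv"))
  }
  write_snow_table(res$deposition$sites, file.path(out_dir, "snow_sites.tsv"))
  write_field_csv(res$deposition$field, file.path(out_dir, "loading_field.csv"))
  writeLines(report_summary(res), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Summarize a pipeline result
#'
#' A plain-text report: enrichment-factor mean and range by DBT group,
#' the breakpoint timeline ordered by DBT enrichment, the climate
#' correlation matrix, and the deposition tonnage; stages without
#' results are marked "not run".
#'
#' @param res A `pipeline_result` from [run_pipeline()].
#' @return Character vector of report lines (invisibly printed with
#'   `cat`-style newlines by the caller).
#' @export
report_summary <- function(res) {
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  cls <- res$classification
  add("== Enrichment factors by DBT group ==")
  for (g in levels(cls$group)) {
    sel <- cls$group == g
    if (!any(sel)) { add("%-12s n=0", g); next }
    add("%-12s n=%-2d chl-a EF mean %.2f (range %.2f-%.2f)",
        g, sum(sel), mean(cls$chla_ef[sel]),
        min(cls$chla_ef[sel]), max(cls$chla_ef[sel]))
  }
  add("")
  add("== Breakpoint timeline (ordered by DBT EF) ==")
  ord <- order(cls$dbt_ef)
  for (i in ord) {
    b <- res$breakpoints[[cls$lake_id[i]]]
    if (is.null(b)) next
    if (b$applicable) {
      add("%-12s DBT EF %5.1f  breakpoint %.1f +/- %.1f", cls$lake_id[i],
          cls$dbt_ef[i], b$tau, b$tau_se)
    } else {
      add("%-12s DBT EF %5.1f  breakpoint not applicable (%s)",
          cls$lake_id[i], cls$dbt_ef[i], b$reason)
    }
  }
  add("")
  add("== Climate correlations (5-yr bins) ==")
  if (is.null(res$correlations)) {
    add("not run")
  } else {
    for (i in seq_len(nrow(res$correlations))) {
      cr <- res$correlations[i, ]
      add("%-10s %-8s r = %5.2f  p = %.3g  (n = %d)",
          cr$group, cr$series, cr$r, cr$p, cr$n)
    }
  }
  add("")
  add("== Deposition ==")
  if (is.null(res$deposition)) {
    add("not run")
  } else {
    add("%s within %.0f km: %.1f t (day-normalized %.1f t)",
        res$deposition$field$analyte,
        res$deposition$radius / 1000, res$deposition$tonnes,
        res$deposition$tonnes_day_normalized)
  }
  L
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(report_summary(x), sep = "\n")
  invisible(x)
}

#' Summary statistics of the shipped 23-site table
#'
#' Recomputes the headline numbers from [table1_fixture()]: the mean and
#' range of the chlorophyll-a enrichment factors, the DBT
#' enrichment-factor range, the threshold-2 classification counts, the
#' counts of breakpoint-eligible sites per group, and the Welch t-test
#' comparing chlorophyll-a enrichment between the minimally and highly
#' DBT-enriched groups.
#'
#' @return A list of those statistics.
#' @export
table1_summary <- function() {
  t1 <- table1_fixture()
  grp <- table(t1$group)
  elig <- table(t1$group[t1$breakpoint_applicable])
  wt <- welch_ttest(t1$chla_ef[t1$group == "minimally"],
                    t1$chla_ef[t1$group == "highly"])
  list(
    n_sites = nrow(t1),
    chla_ef_mean = mean(t1$chla_ef),
    chla_ef_mean_printed_rows = mean(t1$chla_ef[!is.na(t1$dbt_ef)]),
    chla_ef_range = range(t1$chla_ef),
    dbt_ef_range = range(t1$dbt_ef, na.rm = TRUE),
    n_minimally = unname(grp["minimally"]),
    n_highly = unname(grp["highly"]),
    n_undetermined = unname(grp["undetermined"]),
    n_breakpoint_minimally = unname(elig["minimally"]),
    n_breakpoint_highly = unname(elig["highly"]),
    welch = wt
  )
}
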