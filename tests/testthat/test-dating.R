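make_profile <- function(total, supported = 1, sd_total = 0, sd_supp = 0,
                         dm = 0.1) {
  n <- length(total)
  as_radionuclide_profile(data.frame(
    top_cm = (0:(n - 1)) * 0.5, bottom_cm = (1:n) * 0.5,
    dry_mass_g_cm2 = dm,
    pb210_Bq_g = total, pb210_sd = sd_total,
    ra226_Bq_g = supported, ra226_sd = sd_supp
  ))
}

test_that("unsupported activity is total minus supported with quadrature SDs", {
  p <- make_profile(c(10, 5, 2, 1, 1), supported = 1,
                    sd_total = 0.3, sd_supp = 0.4)
  u <- compute_unsupported(p)
  expect_equal(u$unsupported, c(9, 4, 1, 0, 0))
  expect_equal(u$sd, rep(0.5, 5))                       # 3-4-5 quadrature
  expect_false(any(u$clipped))
  ## total below supported clips to zero with a flag, never negative
  p2 <- make_profile(c(10, 5, 0.5, 1), supported = 1)
  u2 <- compute_unsupported(p2)
  expect_equal(u2$unsupported[3], 0)
  expect_true(u2$clipped[3])
  ## missing activity names the interval
  p3 <- make_profile(c(10, 5, NA, 1))
  expect_error(compute_unsupported(p3), "interval.*3")
})

test_that("background depth solves the exponential decline against the floor", {
  co <- simulate_core(oracle_core_config())
  prof <- as_radionuclide_profile(co$intervals)
  bg <- find_background_depth(prof, floor = 0.01)
  ## direct evaluation of the forward model against the same floor
  expected_idx <- which(co$intervals$true_unsupported <= 0.01)[1]
  expect_equal(bg$index, expected_idx)
  expect_true(bg$reached)
  expect_equal(bg$depth_cm, prof$top_cm[expected_idx])
})

test_that("background lands where unsupported vanishes, and edge cases flag", {
  p <- make_profile(c(9, 5, 3, 2, 1.5, 1, 1, 1, 1) , supported = 1)
  bg <- find_background_depth(p, floor = 0.01)
  expect_equal(bg$index, 6)                    # all-zero from interval 6
  expect_equal(bg$depth_cm, p$top_cm[6])
  ## never reaching background warns and uses the deepest interval
  p2 <- make_profile(c(9, 8, 7, 6, 5, 4), supported = 1)
  expect_warning(bg2 <- find_background_depth(p2, floor = 0.01), "never")
  expect_false(bg2$reached)
  ## background at the surface is a no-inventory error
  p3 <- make_profile(rep(1, 5), supported = 1)
  expect_error(find_background_depth(p3, floor = 0.01), "inventory")
})

test_that("CRS recovers the constant-rate closed form t = m/r", {
  co <- simulate_core(oracle_core_config())
  prof <- as_radionuclide_profile(co$intervals)
  m <- crs_age_model(prof, 2011, n_mc = 0)
  nd <- nrow(m)
  true_age <- co$intervals$true_age_yr[seq_len(nd)]
  expect_lt(max(abs(m$age_yr - true_age) / true_age), 0.01)
  expect_lt(max(abs(m$mar_g_cm2_yr - 0.05) / 0.05), 0.02)
  ## dates decrease with depth, ages increase
  expect_true(all(diff(m$year) < 0))
  expect_true(all(diff(m$age_yr) > 0))
  ## surface interval dated essentially at coring
  expect_lt(2011 - m$year[1], 1.5)
})

test_that("extrapolation continues the constant-rate ages below background", {
  co <- simulate_core(oracle_core_config())
  prof <- as_radionuclide_profile(co$intervals)
  m <- crs_age_model(prof, 2011, n_mc = 0)
  ext <- extrapolate_below_background(m, prof)
  expect_equal(nrow(ext), nrow(prof))
  expect_lt(max(abs(ext$age_yr - co$intervals$true_age_yr)), 1)
  expect_true(all(ext$age_yr[ext$extrapolated] > max(m$age_yr)))
  ## nothing below background leaves the model unchanged
  short <- as_radionuclide_profile(co$intervals[seq_len(nrow(m)), ])
  m2 <- crs_age_model(short, 2011, background = attr(m, "background"),
                      n_mc = 0)
  expect_identical(nrow(extrapolate_below_background(m2, short)), nrow(m2))
})

test_that("polynomial smoothing honours the coring-year constraint", {
  ## exactly linear chronology: quadratic term vanishes, dates reproduced
  n <- 30
  fake <- structure(
    data.frame(top_cm = (0:(n - 1)) * 0.5, bottom_cm = (1:n) * 0.5,
               mid_depth_cm = (0:(n - 1)) * 0.5 + 0.25,
               dry_mass_g_cm2 = 0.1,
               age_yr = ((0:(n - 1)) * 0.5 + 0.25) * 4,
               year = 2010 - ((0:(n - 1)) * 0.5 + 0.25) * 4,
               sd2_yr = NA_real_, mar_g_cm2_yr = 0.05,
               extrapolated = FALSE, method = "CRS"),
    class = c("age_depth_model", "data.frame"),
    coring_year = 2010, lambda = pb210_lambda())
  sm <- fit_age_depth_polynomial(fake)
  expect_equal(attr(sm, "poly_order"), 2)
  expect_lt(max(abs(sm$year_smoothed - fake$year)), 0.1)
  expect_equal(predict(sm, 0), 2010)           # constrained intercept, exact
})

test_that("piecewise-accumulation cores smooth to within 2 yr of truth", {
  rates <- c(rep(0.054, 60), rep(0.046, 50))
  cfg <- core_sim_config(coring_year = 2012, n_intervals = 110,
                         dry_mass_per_interval = 0.1, mass_accum_rate = rates,
                         counting_error_cv = 0, chla_noise_sd = 0, seed = 1)
  co <- simulate_core(cfg)
  prof <- as_radionuclide_profile(co$intervals)
  m <- fit_age_depth_polynomial(
    extrapolate_below_background(crs_age_model(prof, 2012, n_mc = 0), prof))
  expect_lt(max(abs(m$year_smoothed - co$intervals$true_year)), 2)
  expect_equal(predict(m, 0), 2012)
})

test_that("137Cs peak is located, validated, and tie-breaks shallow", {
  co <- simulate_core(noisy_core_config(seed = 11, cv = 0.05))
  prof <- as_radionuclide_profile(co$intervals)
  m <- crs_age_model(prof, 2012, n_mc = 500, seed = 2)
  pk <- locate_cs137_peak(co$intervals, m)
  expect_false(pk$no_peak)
  expect_true(pk$valid)
  ## monotone profile has no peak
  flat <- co$intervals
  flat$cs137_Bq_g <- rev(sort(flat$cs137_Bq_g))
  expect_true(locate_cs137_peak(flat, m)$no_peak)
  ## exact tie between adjacent maxima reports the shallower interval
  tie <- co$intervals
  tie$cs137_Bq_g <- c(0, 1, 5, 5, 1, rep(0, nrow(tie) - 5))
  expect_equal(locate_cs137_peak(tie, m)$index, 3L)
})

test_that("Monte-Carlo envelopes are reproducible and positive", {
  co <- simulate_core(noisy_core_config(seed = 21))
  prof <- as_radionuclide_profile(co$intervals)
  m1 <- crs_age_model(prof, 2012, n_mc = 300, seed = 5)
  m2 <- crs_age_model(prof, 2012, n_mc = 300, seed = 5)
  expect_identical(m1$sd2_yr, m2$sd2_yr)
  expect_true(all(m1$sd2_yr > 0))
  ## uncertainty grows with depth overall
  expect_gt(mean(m1$sd2_yr[(nrow(m1) - 9):nrow(m1)]),
            mean(m1$sd2_yr[1:10]))
})
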