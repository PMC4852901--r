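test_that("site loading is concentration times SWE", {
  expect_equal(site_loading(2, 100), 200)
  expect_equal(site_loading(0, 150), 0)
  expect_equal(site_loading(0.5, 117.5), 58.75)
  expect_error(site_loading(-1, 100), ">= 0")
  expect_error(site_loading(1, 0), "positive")
})

test_that("empirical semivariance matches a hand computation on a 5-site toy", {
  s <- data.frame(x_m = c(0, 1000, 2000, 3000, 4000), y_m = 0,
                  loading_mg_m2 = c(2, 4, 3, 5, 1))
  s <- rbind(s, s, s)                       # >= 10 sites for the fitter
  s$x_m <- s$x_m + rep(c(0, 20000, 40000), each = 5)
  vg <- fit_variogram(s, n_lags = 4, max_lag = 4200)
  ## lag-1000 pairs within each block: (2,4),(4,3),(3,5),(5,1) x 3 blocks
  hand <- mean(0.5 * c(2, -1, 2, -4)^2)
  i <- which.min(abs(vg$empirical$lag - 1000))
  expect_equal(vg$empirical$gamma[i], hand, tolerance = 1e-12)
  expect_equal(vg$empirical$np[i], 12L)
})

test_that("a spatially flat field degenerates to a pure-nugget model", {
  s <- data.frame(x_m = runif(20, 0, 1e4), y_m = runif(20, 0, 1e4),
                  loading_mg_m2 = 5)
  vg <- fit_variogram(s)
  expect_true(vg$degenerate)
  expect_equal(vg$sill, 0)
})

test_that("kriging with zero nugget interpolates the data exactly", {
  vg <- variogram_model("exponential", nugget = 0, sill = 2, range = 2e4)
  set.seed(3)
  s <- data.frame(x_m = runif(20, 0, 5e4), y_m = runif(20, 0, 5e4),
                  loading_mg_m2 = runif(20, 1, 9))
  kw <- kriging_weights(s, vg, s$x_m, s$y_m)
  expect_lt(max(abs(kw$pred - s$loading_mg_m2)), 1e-8)
  expect_lt(max(kw$var), 1e-8)
  expect_equal(colSums(kw$weights), rep(1, 20), tolerance = 1e-10)
})

test_that("constant data krige to the constant everywhere", {
  vg <- variogram_model("spherical", nugget = 0.1, sill = 1, range = 1e4)
  set.seed(6)
  s <- data.frame(x_m = runif(12, 0, 3e4), y_m = runif(12, 0, 3e4),
                  loading_mg_m2 = 4.2)
  fld <- ordinary_kriging(s, vg, cell_size = 3000,
                          extent = c(0, 3e4, 0, 3e4))
  expect_equal(as.vector(fld$pred), rep(4.2, length(fld$pred)),
               tolerance = 1e-10)
})

test_that("two-site weights solve the hand-built 3x3 kriging system", {
  vg <- variogram_model("exponential", nugget = 0.2, sill = 1.2, range = 1e4)
  s <- data.frame(x_m = c(0, 2e4), y_m = 0, loading_mg_m2 = c(3, 5))
  kw <- kriging_weights(s, vg, 5e3, 0)
  g <- function(h) ifelse(h > 0, 0.2 + (1 - exp(-h / 1e4)), 0)
  A <- rbind(c(0, g(2e4), 1), c(g(2e4), 0, 1), c(1, 1, 0))
  b <- c(g(5e3), g(1.5e4), 1)
  sol <- solve(A, b)
  expect_equal(as.vector(kw$weights), sol[1:2], tolerance = 1e-12)
  expect_equal(kw$mu, sol[3], tolerance = 1e-12)
  expect_equal(kw$pred, sum(sol[1:2] * c(3, 5)), tolerance = 1e-12)
})

test_that("duplicate coordinates are averaged with a warning", {
  vg <- variogram_model("exponential", nugget = 0, sill = 1, range = 1e4)
  s <- data.frame(x_m = c(0, 0, 1e4, 2e4, 3e4), y_m = 0,
                  loading_mg_m2 = c(2, 4, 5, 6, 7))
  expect_warning(kw <- kriging_weights(s, vg, 0, 0), "duplicate")
  expect_equal(kw$pred, 3)                  # mean of the co-located pair
})

test_that("leave-one-out CV equals an independent removal loop", {
  vg <- variogram_model("exponential", nugget = 0.3, sill = 2, range = 1.5e4)
  set.seed(10)
  s <- data.frame(x_m = runif(15, 0, 4e4), y_m = runif(15, 0, 4e4),
                  loading_mg_m2 = rnorm(15, 10, 2))
  cv <- cross_validate(s, vg)
  for (i in c(1, 7, 15)) {
    loop <- kriging_weights(s[-i, ], vg, s$x_m[i], s$y_m[i])
    expect_equal(cv$results$predicted[i], loop$pred, tolerance = 1e-12)
  }
  expect_equal(cv$me, mean(cv$results$error), tolerance = 1e-12)
  expect_equal(cv$rmse, sqrt(mean(cv$results$error^2)), tolerance = 1e-12)
})

test_that("cross-validation of a smooth noiseless plume is nearly unbiased", {
  cfg <- snow_sim_config(n_sites = 64, extent_km = 80, nugget_sd = 0.5,
                         plume_amplitude = 30, plume_decay_km = 25, seed = 2)
  s <- simulate_snow_grid(cfg)
  vg <- fit_variogram(s, n_lags = 12)
  cv <- cross_validate(s, vg)
  expect_lt(abs(cv$me), cv$rmse / 2)
  expect_lt(cv$rmse, diff(range(s$loading_mg_m2)) / 3)
})

test_that("radial integration converges to disc integrals", {
  gx <- seq(-6e4 + 500, 6e4, by = 1000)
  uniform <- loading_field(gx, gx, matrix(13, length(gx), length(gx)))
  t_unif <- as.numeric(integrate_radius(uniform, c(0, 0), 5e4))
  analytic_unif <- 13 * pi * 5e4^2 * 1e-9          # ~102.1 t
  expect_lt(abs(t_unif - analytic_unif) / analytic_unif, 0.01)
  expect_equal(as.numeric(integrate_radius(
    loading_field(gx, gx, matrix(0, length(gx), length(gx))), c(0, 0), 5e4)), 0)
  ## radial plume against its analytic integral, 1-km cells
  b <- 5; a <- 30; l <- 2.5e4; R <- 5e4
  plume <- loading_field(gx, gx, outer(gx, gx, function(x, y)
    b + a * exp(-sqrt(x^2 + y^2) / l)))
  t_plume <- as.numeric(integrate_radius(plume, c(0, 0), R))
  analytic <- (b * pi * R^2 + 2 * pi * a * (l^2 - (l^2 + l * R) * exp(-R / l))) * 1e-9
  expect_lt(abs(t_plume - analytic) / analytic, 0.01)
  ## refining the grid shrinks the discretization error: halving twice
  ## at least halves it
  gx2 <- seq(-6e4 + 125, 6e4, by = 250)
  plume2 <- loading_field(gx2, gx2, outer(gx2, gx2, function(x, y)
    b + a * exp(-sqrt(x^2 + y^2) / l)))
  err1 <- abs(t_plume - analytic)
  err2 <- abs(as.numeric(integrate_radius(plume2, c(0, 0), R)) - analytic)
  expect_lt(err2, err1 / 2)
  expect_error(integrate_radius(plume, c(0, 0), -1), "positive")
})

test_that("negative predictions are clipped and partial coverage warns", {
  gx <- seq(-1e4 + 500, 1e4, by = 1000)
  m <- matrix(1, length(gx), length(gx)); m[1, 1] <- -5
  fld <- loading_field(gx, gx, m)
  t0 <- suppressWarnings(integrate_radius(fld, c(-9500, -9500), 2000))
  expect_gte(as.numeric(t0), 0)
  expect_gte(attr(t0, "n_clipped"), 1)
  expect_warning(integrate_radius(fld, c(0, 0), 5e4), "beyond")
})

test_that("day normalization is proportional and invertible", {
  expect_equal(day_normalize(120, 117.5, 85.5), 87.31915, tolerance = 1e-6)
  expect_equal(day_normalize(50, 90, 90), 50)
  expect_equal(day_normalize(day_normalize(77, 117.5, 85.5), 85.5, 117.5), 77)
  expect_error(day_normalize(10, 0, 90), "positive")
})

test_that("kriged plume surfaces peak near the configured source", {
  hits <- 0
  for (s in 1:50) {
    sites <- simulate_snow_grid(snow_sim_config(n_sites = 60, extent_km = 100,
                                                plume_decay_km = 25,
                                                nugget_sd = 2, seed = s))
    vg <- fit_variogram(sites, n_lags = 12)
    fld <- ordinary_kriging(sites, vg, cell_size = 5000,
                            extent = c(-1e5, 1e5, -1e5, 1e5))
    i <- which(fld$pred == max(fld$pred), arr.ind = TRUE)[1, ]
    hits <- hits + (sqrt(fld$x[i[1]]^2 + fld$y[i[2]]^2) <= 2.5e4)
  }
  expect_gte(hits, 48)
})
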