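#' Snowpack nutrient loading at a site
#'
#' 1 mm of snow-water equivalence is 1 L of water per m2, so
#' loading (mg/m2) = concentration (mg/L) x SWE (mm).
#'
#' @param concentration mg/L (>= 0).
#' @param swe mm (> 0).
#' @return Loading, mg/m2.
#' @export
site_loading <- function(concentration, swe) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  check_positive(swe, "swe")
  concentration * swe
}

## Semivariogram curve gamma(h); gamma(0) = 0 regardless of nugget.
vgm_gamma <- function(h, model, nugget, sill, range) {
  psill <- sill - nugget
  g <- switch(model,
    exponential = psill * (1 - exp(-h / range)),
    gaussian = psill * (1 - exp(-(h / range)^2)),
    spherical = ifelse(h >= range, psill,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    stop("unknown variogram model: ", model)
  )
  ifelse(h > 0, nugget + g, 0)
}

#' Empirical semivariogram and weighted least-squares model fit
#'
#' The empirical semivariance at lag h is the mean of half squared
#' differences over site pairs in the lag bin; a nugget + partial-sill
#' model curve (exponential, spherical or gaussian; for the exponential,
#' `range` is the e-folding distance) is fitted by least squares weighted
#' by the pair count in each bin.
#'
#' @param sites Data frame with `x_m`, `y_m` and the value column.
#' @param value Name of the value column (default `"loading_mg_m2"`).
#' @param model Variogram family.
#' @param n_lags Number of lag bins (default 15).
#' @param max_lag Largest pair distance used, metres (default half the
#'   maximum inter-site distance).
#' @return Object of class `variogram_fit`: `model`, `nugget`, `sill`,
#'   `range`, `fitted`, `degenerate`, plus the empirical semivariogram
#'   (`empirical`: `lag`, `gamma`, `np`).
#' @export
fit_variogram <- function(sites, value = "loading_mg_m2",
                          model = c("exponential", "spherical", "gaussian"),
                          n_lags = 15, max_lag = NULL) {
  model <- match.arg(model)
  z <- sites[[value]]
  if (is.null(z)) stop("no '", value, "' column")
  if (nrow(sites) < 10) stop("need at least 10 sites to fit a variogram")
  d <- as.matrix(stats::dist(cbind(sites$x_m, sites$y_m)))
  iu <- upper.tri(d)
  h <- d[iu]
  g <- 0.5 * outer(z, z, `-`)[iu]^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h <= max_lag & h > 0
  h <- h[keep]; g <- g[keep]
  br <- seq(0, max_lag, length.out = n_lags + 1)
  bin <- cut(h, br, include.lowest = TRUE)
  emp <- data.frame(
    lag = as.numeric(tapply(h, bin, mean)),
    gamma = as.numeric(tapply(g, bin, mean)),
    np = as.integer(table(bin))
  )
  emp <- emp[emp$np > 0 & is.finite(emp$gamma), ]

  if (stats::var(z) == 0) {
    return(structure(list(model = model, nugget = 0, sill = 0,
                          range = max_lag / 3, fitted = TRUE,
                          degenerate = TRUE, empirical = emp),
                     class = "variogram_fit"))
  }

  ## profile fit: for fixed range the curve is linear in (nugget, psill),
  ## solved by constrained WLS; grid + golden-section over the range
  wls_at <- function(rng) {
    f <- vgm_gamma(emp$lag, model, 0, 1, rng)   # unit-psill structure
    X <- cbind(1, f)
    w <- emp$np
    cf <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * w, emp$gamma)),
                   error = function(e) matrix(c(0, 0), 2))
    if (cf[1] < 0 || cf[2] < 0) {
      ## clip at the boundary and refit the free coefficient
      if (cf[2] < 0) {
        cf <- c(sum(w * emp$gamma) / sum(w), 0)
      } else {
        cf <- c(0, sum(w * f * emp$gamma) / sum(w * f^2))
      }
    }
    rss <- sum(w * (emp$gamma - cf[1] - cf[2] * f)^2)
    list(nugget = cf[1], psill = cf[2], rss = rss)
  }
  ranges <- exp(seq(log(min(emp$lag) / 2), log(2 * max_lag), length.out = 60))
  rss <- vapply(ranges, function(r) wls_at(r)$rss, numeric(1))
  i <- which.min(rss)
  opt <- stats::optimize(function(r) wls_at(r)$rss,
                         c(ranges[max(i - 1, 1)],
                           ranges[min(i + 1, length(ranges))]))
  best <- wls_at(opt$minimum)
  structure(list(model = model, nugget = unname(best$nugget),
                 sill = unname(best$nugget + best$psill),
                 range = unname(opt$minimum),
                 fitted = TRUE, degenerate = FALSE, empirical = emp),
            class = "variogram_fit")
}

#' Construct a variogram model directly
#'
#' @param model Family: exponential, spherical or gaussian.
#' @param nugget Nugget semivariance (>= 0).
#' @param sill Total sill (>= nugget).
#' @param range Range parameter, metres (e-folding distance for the
#'   exponential family).
#' @return Object of class `variogram_fit` (with `fitted = FALSE`).
#' @export
variogram_model <- function(model = c("exponential", "spherical", "gaussian"),
                            nugget = 0, sill = 1, range = 1e4) {
  model <- match.arg(model)
  if (nugget < 0 || sill < nugget) stop_invalid("need 0 <= nugget <= sill")
  check_positive(range, "range")
  structure(list(model = model, nugget = nugget, sill = sill, range = range,
                 fitted = FALSE, degenerate = FALSE, empirical = NULL),
            class = "variogram_fit")
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, sill %.4g, range %.4g m%s\n",
              x$model, x$nugget, x$sill, x$range,
              if (isTRUE(x$degenerate)) " (degenerate: pure nugget)" else ""))
  invisible(x)
}

## Average duplicate coordinates (exact ties) so the kriging matrix is
## nonsingular; warns when any are found.
dedupe_sites <- function(x, y, z) {
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    warning("duplicate site coordinates: averaging values")
    x <- tapply(x, key, mean); y <- tapply(y, key, mean)
    z <- tapply(z, key, mean)
  }
  list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
}

## Ordinary-kriging weights and Lagrange multiplier for prediction
## locations `px, py`; returns list(w = n x m weights, mu, gamma0).
ok_solve <- function(x, y, z, vg, px, py) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- rbind(cbind(vgm_gamma(D, vg$model, vg$nugget, vg$sill, vg$range),
                   1),
             c(rep(1, n), 0))
  d0 <- sqrt(outer(x, px, `-`)^2 + outer(y, py, `-`)^2)
  B <- rbind(vgm_gamma(d0, vg$model, vg$nugget, vg$sill, vg$range),
             1)
  W <- solve(A, B)
  list(w = unname(W[seq_len(n), , drop = FALSE]),
       mu = unname(W[n + 1, ]), B = B)
}

#' Ordinary-kriging weights at prediction points
#'
#' Solves the ordinary-kriging system (weights constrained to sum to 1
#' via a Lagrange multiplier) for one or more prediction locations;
#' useful for inspecting the interpolator directly.
#'
#' @param sites Data frame with `x_m`, `y_m` and the value column.
#' @param variogram A `variogram_fit`.
#' @param px,py Prediction coordinates, metres.
#' @param value Value column name.
#' @return List: `weights` (sites x points), `mu` (Lagrange
#'   multipliers), `pred`, `var`.
#' @export
kriging_weights <- function(sites, variogram, px, py,
                            value = "loading_mg_m2") {
  s <- dedupe_sites(sites$x_m, sites$y_m, sites[[value]])
  sol <- ok_solve(s$x, s$y, s$z, variogram, px, py)
  list(weights = sol$w, mu = sol$mu,
       pred = as.numeric(crossprod(sol$w, s$z)),
       var = pmax(colSums(sol$B * rbind(sol$w, sol$mu)), 0))
}

#' Ordinary kriging of site loadings onto a regular grid
#'
#' Interpolates the site values onto cell centres of a regular grid by
#' ordinary kriging with the given semivariogram.  With a zero nugget
#' the interpolator is exact at the data sites.
#'
#' @param sites Data frame with `x_m`, `y_m` and the value column (at
#'   least 5 sites).
#' @param variogram A `variogram_fit` (from [fit_variogram()] or
#'   [variogram_model()]).
#' @param cell_size Grid cell size, metres (default 1000).
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` metres; defaults to
#'   the site bounding box.
#' @param value Value column name.
#' @param analyte Label carried on the field.
#' @return Object of class `loading_field`: `x`, `y` (cell-centre
#'   coordinate vectors), matrices `pred` and `var` (rows = x, cols =
#'   y), `cell_size`, `analyte`, plus the sites and variogram.
#' @export
ordinary_kriging <- function(sites, variogram, cell_size = 1000,
                             extent = NULL, value = "loading_mg_m2",
                             analyte = attr(sites, "analyte")) {
  if (nrow(sites) < 5) stop("need at least 5 sites")
  s <- dedupe_sites(sites$x_m, sites$y_m, sites[[value]])
  if (is.null(extent)) {
    extent <- c(range(s$x), range(s$y))
  }
  gx <- seq(extent[1] + cell_size / 2, extent[2], by = cell_size)
  gy <- seq(extent[3] + cell_size / 2, extent[4], by = cell_size)
  nodes <- expand.grid(x = gx, y = gy)
  sol <- ok_solve(s$x, s$y, s$z, variogram, nodes$x, nodes$y)
  pred <- matrix(as.numeric(crossprod(sol$w, s$z)), length(gx), length(gy))
  vr <- matrix(pmax(colSums(sol$B * rbind(sol$w, sol$mu)), 0),
               length(gx), length(gy))
  structure(list(x = gx, y = gy, pred = pred, var = vr,
                 cell_size = cell_size, analyte = analyte,
                 sites = sites, variogram = variogram),
            class = "loading_field")
}

#' Construct a loading field from values on a grid
#'
#' For analytic fields and tests: wraps cell-centre coordinates and a
#' value matrix in the same container [ordinary_kriging()] returns.
#'
#' @param x,y Cell-centre coordinate vectors, metres (regular spacing).
#' @param pred Matrix of loadings, mg/m2 (`length(x)` rows,
#'   `length(y)` columns).
#' @param analyte Label.
#' @return A `loading_field`.
#' @export
loading_field <- function(x, y, pred, analyte = "field") {
  stopifnot(nrow(pred) == length(x), ncol(pred) == length(y))
  cell <- if (length(x) > 1) diff(x)[1] else diff(y)[1]
  structure(list(x = x, y = y, pred = pred,
                 var = matrix(0, length(x), length(y)),
                 cell_size = cell, analyte = analyte,
                 sites = NULL, variogram = NULL),
            class = "loading_field")
}

#' @export
print.loading_field <- function(x, ...) {
  cat(sprintf("kriged loading field [%s]: %d x %d cells of %g m, %s%.3g-%.3g mg/m2\n",
              x$analyte, length(x$x), length(x$y), x$cell_size,
              "range ", min(x$pred), max(x$pred)))
  invisible(x)
}

#' @export
plot.loading_field <- function(x, ...) {
  graphics::image(x$x / 1000, x$y / 1000, x$pred, xlab = "x (km)",
                  ylab = "y (km)", main = x$analyte, ...)
  if (!is.null(x$sites)) {
    graphics::points(x$sites$x_m / 1000, x$sites$y_m / 1000, pch = 3, cex = 0.5)
  }
  invisible(x)
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Re-predicts each site from all the others with the fixed variogram
#' and summarizes the errors.
#'
#' @param sites Data frame with `x_m`, `y_m` and the value column (>=
#'   10 sites).
#' @param variogram A `variogram_fit`.
#' @param value Value column name.
#' @return Object of class `kriging_cv`: data frame `site` (`observed`,
#'   `predicted`, `error`) plus `me` (mean of kriged minus measured) and
#'   `rmse`.
#' @export
cross_validate <- function(sites, variogram, value = "loading_mg_m2") {
  if (nrow(sites) < 10) stop("need at least 10 sites")
  s <- dedupe_sites(sites$x_m, sites$y_m, sites[[value]])
  n <- length(s$x)
  pred <- vapply(seq_len(n), function(i) {
    sol <- ok_solve(s$x[-i], s$y[-i], s$z[-i], variogram,
                    s$x[i], s$y[i])
    as.numeric(crossprod(sol$w, s$z[-i]))
  }, numeric(1))
  err <- pred - s$z
  structure(list(results = data.frame(x_m = s$x, y_m = s$y,
                                      observed = s$z, predicted = pred,
                                      error = err),
                 me = mean(err), rmse = sqrt(mean(err^2))),
            class = "kriging_cv")
}

#' @export
print.kriging_cv <- function(x, ...) {
  cat(sprintf("leave-one-out CV over %d sites: ME %.4g, RMSE %.4g\n",
              nrow(x$results), x$me, x$rmse))
  invisible(x)
}

#' Integrate deposition within a radius
#'
#' Sums loading over all grid cells whose centre falls inside the disc
#' (no partial-cell weighting) and converts to tonnes:
#' mg/m2 x m2 x 1e-9.  Negative predictions are clipped to zero (a
#' loading is a physical mass); cells outside the field contribute
#' nothing, with a warning when the disc is not fully covered.
#'
#' @param field A `loading_field`.
#' @param center `c(x, y)` of the disc centre, metres.
#' @param radius Disc radius, metres (> 0).
#' @return Tonnes deposited within the disc (attribute `n_clipped`
#'   counts clipped cells).
#' @export
integrate_radius <- function(field, center, radius) {
  check_positive(radius, "radius")
  half <- field$cell_size / 2
  if (center[1] - radius < min(field$x) - half ||
      center[1] + radius > max(field$x) + half ||
      center[2] - radius < min(field$y) - half ||
      center[2] + radius > max(field$y) + half) {
    warning("disc extends beyond the field; uncovered area contributes 0")
  }
  dx2 <- (field$x - center[1])^2
  dy2 <- (field$y - center[2])^2
  inside <- outer(dx2, dy2, `+`) <= radius^2
  vals <- field$pred[inside]
  n_clip <- sum(vals < 0)
  vals <- pmax(vals, 0)
  cell_area <- field$cell_size^2
  structure(sum(vals) * cell_area * 1e-9, n_clipped = n_clip)
}

#' Normalize a seasonal load between accumulation periods
#'
#' Scales a snowpack-integrated load to a different number of days of
#' snow accumulation, assuming constant daily deposition:
#' `load * days_target / days_source`.
#'
#' @param load Tonnes (or any mass unit).
#' @param days_source Days of accumulation behind the measured load.
#' @param days_target Days to normalize to.
#' @return Normalized load.
#' @export
day_normalize <- function(load, days_source, days_target) {
  check_positive(days_source, "days_source")
  check_positive(days_target, "days_target")
  load * days_target / days_source
}

#' Simulate a Gaussian random field at site locations
#'
#' Draws one realization of a stationary, isotropic Gaussian process
#' whose semivariogram is the given model: covariance
#' `(sill - nugget) * rho(h)` plus independent nugget noise.  Used to
#' verify variogram parameter recovery.
#'
#' @param x,y Site coordinates, metres.
#' @param variogram A `variogram_fit` (model, nugget, sill, range).
#' @param mean Process mean.
#' @param seed Integer seed.
#' @return Numeric vector of simulated values.
#' @export
simulate_gaussian_field <- function(x, y, variogram, mean = 0, seed = 1L) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  psill <- variogram$sill - variogram$nugget
  C <- psill * (1 - vgm_gamma(D, variogram$model, 0, 1, variogram$range))
  diag(C) <- psill
  L <- chol(C + diag(1e-10 * psill, n))
  with_seed(seed, {
    z <- mean + drop(crossprod(L, stats::rnorm(n))) +
      stats::rnorm(n, 0, sqrt(variogram$nugget))
  })
  z
}
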