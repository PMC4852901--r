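#' Validate a radionuclide profile
#'
#' Checks and classes a per-interval radionuclide table for one core.
#' Depth intervals are half-open `[top, bottom)` cm below the
#' sediment-water interface, strictly increasing and non-overlapping.
#'
#' @param x Data frame with columns `top_cm`, `bottom_cm`,
#'   `dry_mass_g_cm2`, `pb210_Bq_g`, `pb210_sd`, `ra226_Bq_g`,
#'   `ra226_sd`, and optionally `cs137_Bq_g`, `cs137_sd`.
#' @return `x`, classed `radionuclide_profile`.
#' @export
as_radionuclide_profile <- function(x) {
  need <- c("top_cm", "bottom_cm", "dry_mass_g_cm2",
            "pb210_Bq_g", "pb210_sd", "ra226_Bq_g", "ra226_sd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(diff(x$top_cm) <= 0) || any(x$bottom_cm <= x$top_cm)) {
    stop("depths must be strictly increasing half-open intervals")
  }
  if (any(x$bottom_cm[-nrow(x)] > x$top_cm[-1] + 1e-9)) {
    stop("intervals overlap")
  }
  check_positive(x$dry_mass_g_cm2, "dry_mass_g_cm2")
  if (any(x$pb210_sd < 0) || any(x$ra226_sd < 0)) stop("SDs must be >= 0")
  class(x) <- unique(c("radionuclide_profile", class(x)))
  x
}

#' Unsupported (excess) 210Pb activity
#'
#' Unsupported activity is total 210Pb minus supported 210Pb (taken from
#' 226Ra, its equilibrium parent), clipped at zero; the SD is the
#' quadrature sum of the two counting SDs.
#'
#' @param profile A [as_radionuclide_profile()] table (or the `intervals`
#'   table of a [simulate_core()] result).
#' @return Data frame: `unsupported`, `sd`, `clipped` (TRUE where total
#'   fell below supported).
#' @export
compute_unsupported <- function(profile) {
  need <- c("pb210_Bq_g", "ra226_Bq_g")
  for (nm in need) {
    bad <- which(is.na(profile[[nm]]) | is.null(profile[[nm]]))
    if (length(bad)) {
      stop("missing ", nm, " activity in interval(s) ",
           paste(bad, collapse = ", "))
    }
  }
  raw <- profile$pb210_Bq_g - profile$ra226_Bq_g
  data.frame(unsupported = pmax(raw, 0),
             sd = sqrt(profile$pb210_sd^2 + profile$ra226_sd^2),
             clipped = raw < 0)
}

#' Locate the 210Pb background depth
#'
#' Background is the shallowest depth from which the unsupported activity
#' is indistinguishable from zero -- at or below `k` combined counting
#' SDs (or the absolute floor, whichever is larger) -- for that interval
#' and every deeper measured interval.
#'
#' @param profile A radionuclide profile (>= 4 intervals).
#' @param k Multiple of the combined SD treated as indistinguishable from
#'   zero (default 2).
#' @param floor Absolute activity floor, Bq/g, applied in addition to the
#'   SD criterion (relevant for noiseless synthetics whose SDs are 0).
#' @return List: `depth_cm` (top of the first background interval, or the
#'   core bottom when background is never reached), `index` (first
#'   background interval; `n + 1` when never reached), `reached`.
#' @export
find_background_depth <- function(profile, k = 2, floor = 0.01) {
  n <- nrow(profile)
  if (n < 4) stop("need at least 4 intervals to locate background")
  u <- compute_unsupported(profile)
  thr <- pmax(k * u$sd, floor)
  below <- u$unsupported <= thr
  ## shallowest index from which everything deeper is at background
  idx <- n + 1L
  for (i in rev(seq_len(n))) {
    if (below[i]) idx <- i else break
  }
  if (idx == 1L) {
    stop("unsupported 210Pb at background from the surface: no inventory")
  }
  if (idx > n) {
    warning("core never reaches 210Pb background; using deepest interval")
    return(list(depth_cm = profile$bottom_cm[n], index = n + 1L,
                reached = FALSE))
  }
  list(depth_cm = profile$top_cm[idx], index = idx, reached = TRUE)
}

#' Constant-rate-of-supply (CRS) age-depth model
#'
#' Dates every interval above the 210Pb background by the CRS model: with
#' cumulative unsupported inventory beneath depth x, \eqn{A(x)}, and
#' total inventory \eqn{A(0)}, the age of x is
#' \eqn{t(x) = \lambda^{-1}\ln[A(0)/A(x)]} with \eqn{\lambda = \ln 2 /
#' 22.3} per yr.  Boundary inventories are sums of activity times
#' interval dry mass (activities constant within an interval); interval
#' dates use the inventory linearly interpolated to the interval's mass
#' midpoint.  The mass accumulation rate at an interval is
#' \eqn{r = \lambda A / C}.  2-SD age uncertainties come from Monte-Carlo
#' resampling of the measured activities.
#'
#' Inventories sum over every measured interval (intervals below
#' background still hold a little unsupported activity), and the
#' residual inventory beneath the core bottom is estimated by
#' extrapolating the exponential decline of the deepest intervals and
#' added to all cumulative inventories; without this correction CRS ages
#' near background are biased old whenever the core does not extend well
#' past background depth.  Because the tail estimate dominates the
#' uncertainty of deep ages, it is re-estimated in every Monte-Carlo
#' draw.
#'
#' @param profile A radionuclide profile.
#' @param coring_year Calendar year of collection (surface age 0).
#' @param background Result of [find_background_depth()]; computed if
#'   `NULL`.
#' @param n_mc Monte-Carlo draws for the age uncertainty (default 1000).
#' @param seed Seed for the Monte-Carlo resampling.
#' @param k,floor Passed to [find_background_depth()] when `background`
#'   is `NULL`.
#' @return An object of class `age_depth_model`: a data frame with one
#'   row per dated interval (`top_cm`, `bottom_cm`, `mid_depth_cm`,
#'   `age_yr`, `year`, `sd2_yr`, `mar_g_cm2_yr`, `extrapolated`,
#'   `method`) and attributes `coring_year`, `background`, `A0`,
#'   `lambda`, `profile`.
#' @seealso [extrapolate_below_background()],
#'   [fit_age_depth_polynomial()], [locate_cs137_peak()]
#' @export
crs_age_model <- function(profile, coring_year, background = NULL,
                          n_mc = 1000, seed = 1L, k = 2, floor = 0.01) {
  if (is.null(background)) {
    background <- find_background_depth(profile, k = k, floor = floor)
  }
  nd <- background$index - 1L          # dated intervals 1..nd
  u <- compute_unsupported(profile)
  dm <- profile$dry_mass_g_cm2
  ## inventories sum over every measured interval (the residual
  ## unsupported activity below background still contributes); ages are
  ## assigned only above background
  ages <- crs_ages(u$unsupported, dm)
  if (any(!is.finite(ages$t_mid[seq_len(nd)])) ||
      any(ages$A_mid[seq_len(nd)] <= 0)) {
    stop("non-positive inventory above background; cannot date core")
  }

  ## Monte-Carlo 2-SD envelope: perturb measured activities by their SDs
  sd2 <- rep(NA_real_, nd)
  if (n_mc > 0) {
    np <- nrow(profile)
    with_seed(seed, {
      pb <- matrix(stats::rnorm(n_mc * np, rep(profile$pb210_Bq_g, each = n_mc),
                                rep(profile$pb210_sd, each = n_mc)), n_mc, np)
      ra <- matrix(stats::rnorm(n_mc * np, rep(profile$ra226_Bq_g, each = n_mc),
                                rep(profile$ra226_sd, each = n_mc)), n_mc, np)
      um <- pmax(pb - ra, 0)
      ## the bottom-tail estimate is itself a major error source at depth:
      ## re-estimate it for every draw
      tails <- vapply(seq_len(n_mc), function(d) crs_tail(um[d, ], dm),
                      numeric(1))
      tmat <- crs_ages_matrix(um, dm, tail = tails)
      sd2 <- 2 * apply(tmat[, seq_len(nd), drop = FALSE], 2, stats::sd,
                       na.rm = TRUE)
    })
  }

  out <- data.frame(
    top_cm = profile$top_cm[seq_len(nd)],
    bottom_cm = profile$bottom_cm[seq_len(nd)],
    mid_depth_cm = (profile$top_cm[seq_len(nd)] + profile$bottom_cm[seq_len(nd)]) / 2,
    dry_mass_g_cm2 = dm[seq_len(nd)],
    age_yr = ages$t_mid[seq_len(nd)],
    year = coring_year - ages$t_mid[seq_len(nd)],
    sd2_yr = sd2,
    mar_g_cm2_yr = PB210_LAMBDA * ages$A_mid[seq_len(nd)] /
      u$unsupported[seq_len(nd)],
    extrapolated = FALSE,
    method = "CRS",
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("age_depth_model", "data.frame"),
            coring_year = coring_year, background = background,
            A0 = ages$A0, lambda = PB210_LAMBDA, profile = profile)
}

## Residual unsupported inventory beneath the core bottom, estimated by
## regressing log activity on cumulative mass over the deepest measured
## intervals (exponential-decline extrapolation).  Returns 0 when the
## decline cannot be estimated.
crs_tail <- function(unsupported, dm) {
  n <- length(dm)
  k <- min(n, max(5L, ceiling(n / 5)))
  i <- seq.int(n - k + 1L, n)
  i <- i[unsupported[i] > 0]
  if (length(i) < 3) return(0)
  m_mid <- cumsum(dm) - dm / 2
  fit <- stats::lm.fit(cbind(1, m_mid[i]), log(unsupported[i]))
  beta <- -fit$coefficients[2]
  if (!is.finite(beta) || beta <= 0) return(0)
  unname(exp(fit$coefficients[1] - beta * sum(dm)) / beta)
}

## CRS ages at interval mass midpoints from unsupported activities and
## interval dry masses.  `tail` is the estimated inventory beneath the
## core bottom, added to every cumulative inventory.
crs_ages <- function(unsupported, dm, tail = crs_tail(unsupported, dm)) {
  inc <- unsupported * dm
  A0 <- sum(inc) + tail
  A_below <- A0 - cumsum(inc)            # inventory beneath each lower boundary
  A_above <- c(A0, A_below[-length(inc)])
  A_mid <- (A_above + A_below) / 2       # linear in cumulative mass
  list(A0 = A0, A_mid = A_mid,
       t_mid = log(A0 / A_mid) / PB210_LAMBDA,
       A_bound = A_below, tail = tail)
}

## Row-wise CRS midpoint ages for a draws x intervals activity matrix.
## `tail` is a scalar or per-draw vector of bottom-tail inventories.
crs_ages_matrix <- function(um, dm, tail = 0) {
  nd <- length(dm)
  inc <- sweep(um, 2, dm, `*`)
  csum <- inc %*% upper.tri(diag(nd), diag = TRUE) * 1  # running sums
  A0 <- csum[, nd] + tail
  A_below <- A0 - csum
  A_above <- cbind(A0, A_below[, -nd, drop = FALSE])
  A_mid <- (A_above + A_below) / 2
  A_mid[A_mid <= 0] <- NA_real_
  log(A0 / A_mid) / PB210_LAMBDA
}

#' Extrapolate ages below the 210Pb background
#'
#' Extends the chronology linearly in cumulative dry mass beneath the
#' deepest CRS-dated interval, using the mean CRS mass accumulation rate
#' over the deepest third of dated intervals.
#'
#' @param model An [crs_age_model()] result.
#' @param profile The full radionuclide profile (supplies the intervals
#'   below background); defaults to the profile stored in `model`.
#' @return The model with extrapolated intervals appended
#'   (`extrapolated = TRUE`, `method = "extrapolated"`).
#' @export
extrapolate_below_background <- function(model, profile = attr(model, "profile")) {
  nd <- sum(!model$extrapolated)
  n <- nrow(profile)
  if (nd >= n) return(model)
  deep <- seq.int(min(nd, ceiling(2 * nd / 3) + 1), nd)
  r_bar <- mean(model$mar_g_cm2_yr[deep])
  dm <- profile$dry_mass_g_cm2
  ## mass from the deepest dated midpoint to each undated midpoint
  extra <- (nd + 1L):n
  m_mid <- cumsum(dm) - dm / 2
  age_extra <- model$age_yr[nd] + (m_mid[extra] - m_mid[nd]) / r_bar
  add <- data.frame(
    top_cm = profile$top_cm[extra], bottom_cm = profile$bottom_cm[extra],
    mid_depth_cm = (profile$top_cm[extra] + profile$bottom_cm[extra]) / 2,
    dry_mass_g_cm2 = dm[extra],
    age_yr = age_extra,
    year = attr(model, "coring_year") - age_extra,
    sd2_yr = NA_real_, mar_g_cm2_yr = r_bar,
    extrapolated = TRUE, method = "extrapolated",
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(model), add)
  attributes(out)[c("coring_year", "background", "A0", "lambda", "profile")] <-
    attributes(model)[c("coring_year", "background", "A0", "lambda", "profile")]
  class(out) <- class(model)
  out
}

#' Constrained polynomial smoothing of an age-depth model
#'
#' Fits polynomials of order 2..`max_order` in midpoint depth to the CRS
#' (and extrapolated) dates, with the depth-0 intercept constrained to
#' the coring year.  The selected order is the lowest one that is
#' monotone (dates non-increasing with depth) over the data range and
#' whose adjusted R-squared is within `tol_r2` of the next order.  If no
#' candidate is monotone the model falls back to piecewise-linear
#' interpolation through the dated points, with a warning.
#'
#' @param model An `age_depth_model`.
#' @param max_order Highest polynomial order tried (default 4).
#' @param tol_r2 Adjusted R-squared tolerance for "no better fit at the
#'   next order" (default 0.005).
#' @return The model with a `year_smoothed` column and attributes
#'   `poly_coef` (coefficients of `year - coring_year` on depth powers)
#'   and `poly_order` (or `"piecewise-linear"` on fallback).
#' @export
fit_age_depth_polynomial <- function(model, max_order = 4, tol_r2 = 0.005) {
  if (nrow(model) < 5) stop("need at least 5 dated points")
  cy <- attr(model, "coring_year")
  d <- model$mid_depth_cm
  y <- model$year - cy
  grid <- seq(0, max(d), length.out = 512)
  fits <- lapply(2:max_order, function(ord) {
    X <- outer(d, seq_len(ord), `^`)
    fit <- stats::lm.fit(X, y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    pred_grid <- outer(grid, seq_len(ord), `^`) %*% co
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    nprm <- ord
    r2adj <- 1 - (rss / (length(y) - nprm)) / (tss / (length(y) - 1))
    list(order = ord, coef = co, monotone = all(diff(pred_grid) <= 1e-9),
         r2adj = r2adj)
  })
  sel <- NULL
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!f$monotone) next
    nxt <- if (i < length(fits)) fits[[i + 1]]$r2adj else -Inf
    if (f$r2adj >= nxt - tol_r2 || i == length(fits)) { sel <- f; break }
  }
  if (is.null(sel)) {
    ## last resort: highest-order monotone fit, else piecewise linear
    mono <- Filter(function(f) f$monotone, fits)
    if (length(mono)) {
      sel <- mono[[length(mono)]]
    } else {
      warning("no monotone polynomial; falling back to piecewise-linear interpolation")
      interp <- stats::approx(c(0, d), c(cy, model$year), xout = d, rule = 2)
      model$year_smoothed <- interp$y
      attr(model, "poly_coef") <- NULL
      attr(model, "poly_order") <- "piecewise-linear"
      return(model)
    }
  }
  model$year_smoothed <- cy +
    as.vector(outer(d, seq_len(sel$order), `^`) %*% sel$coef)
  attr(model, "poly_coef") <- sel$coef
  attr(model, "poly_order") <- sel$order
  model
}

#' Locate the 137Cs fallout peak and validate the chronology
#'
#' Finds the depth of maximum 137Cs activity (ties broken toward the
#' shallower interval) and compares the CRS date there with the fallout
#' year.  Validation passes when the date differs from `peak_year` by no
#' more than the interval's 2-SD Monte-Carlo age uncertainty plus half
#' the interval's own age span (the dating resolution of a peak located
#' only to within one discrete interval).
#'
#' @param profile A radionuclide profile with a `cs137_Bq_g` column.
#' @param model An `age_depth_model` covering the peak depth.
#' @param peak_year Expected fallout maximum (default 1963).
#' @return List: `depth_cm`, `index`, `year` (CRS date at the peak),
#'   `sd2_yr`, `tolerance_yr`, `valid`, `no_peak`.
#' @export
locate_cs137_peak <- function(profile, model, peak_year = 1963) {
  cs <- profile$cs137_Bq_g
  if (is.null(cs)) stop("profile has no cs137_Bq_g column")
  n <- length(cs)
  i <- which.max(cs)                     # first occurrence = shallower
  flat <- diff(range(cs)) <= .Machine$double.eps * max(abs(cs), 1)
  if (flat || i == 1L || i == n) {
    return(list(depth_cm = NA_real_, index = NA_integer_, year = NA_real_,
                sd2_yr = NA_real_, tolerance_yr = NA_real_,
                valid = NA, no_peak = TRUE))
  }
  if (i > nrow(model)) stop("137Cs peak below the dated part of the model")
  sd2 <- model$sd2_yr[i]
  half_span <- profile$dry_mass_g_cm2[i] / model$mar_g_cm2_yr[i] / 2
  tol <- (if (is.na(sd2)) 0 else sd2) + half_span
  yr <- model$year[i]
  list(depth_cm = model$mid_depth_cm[i], index = i, year = yr,
       sd2_yr = sd2, tolerance_yr = tol,
       valid = abs(yr - peak_year) <= tol, no_peak = FALSE)
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat("210Pb CRS age-depth model\n")
  cat("  coring year:", attr(x, "coring_year"),
      "  total inventory A(0):", signif(attr(x, "A0"), 4), "Bq/cm2\n")
  bg <- attr(x, "background")
  cat("  background depth:", bg$depth_cm, "cm",
      if (!bg$reached) "(never reached)" else "", "\n")
  cat("  ", sum(!x$extrapolated), "CRS-dated +", sum(x$extrapolated),
      "extrapolated intervals,", round(min(x$year), 1), "-",
      round(max(x$year), 1), "CE\n")
  if (!is.null(attr(x, "poly_order"))) {
    cat("  smoothed: polynomial order", attr(x, "poly_order"), "\n")
  }
  invisible(x)
}

#' @export
summary.age_depth_model <- function(object, ...) {
  print(object)
  print(utils::head(as.data.frame(object), 5))
  invisible(object)
}

#' Predict calendar year at arbitrary depths
#'
#' Uses the constrained polynomial when fitted, else linear interpolation
#' of the dated midpoints (anchored at the coring year at depth 0).
#'
#' @param object An `age_depth_model`.
#' @param depth_cm Depths below the sediment-water interface.
#' @param ... Unused.
#' @return Calendar years.
#' @export
predict.age_depth_model <- function(object, depth_cm, ...) {
  cy <- attr(object, "coring_year")
  co <- attr(object, "poly_coef")
  if (!is.null(co)) {
    return(cy + as.vector(outer(depth_cm, seq_along(co), `^`) %*% co))
  }
  stats::approx(c(0, object$mid_depth_cm), c(cy, object$year),
                xout = depth_cm, rule = 2)$y
}

#' @export
plot.age_depth_model <- function(x, ...) {
  graphics::plot(x$year, x$mid_depth_cm, ylim = rev(range(x$mid_depth_cm)),
                 xlab = "Year CE", ylab = "Depth (cm)",
                 pch = ifelse(x$extrapolated, 1, 16), ...)
  if (!is.null(x$year_smoothed)) {
    graphics::lines(x$year_smoothed, x$mid_depth_cm, col = "grey40")
  }
  if (!all(is.na(x$sd2_yr))) {
    graphics::segments(x$year - x$sd2_yr, x$mid_depth_cm,
                       x$year + x$sd2_yr, x$mid_depth_cm)
  }
  invisible(x)
}
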