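#' Enrichment factor of a dated concentration profile
#'
#' Ratio of the mean concentration in a modern window to the mean in a
#' pre-industrial baseline window.  The primary variant uses calendar
#' windows (post-2000 vs 1955-1970, both closed); the interval-count
#' variants swap one window for a fixed number of intervals -- the 2 or 3
#' most recent intervals (`last2`, `last3`) or the 2 or 3 intervals
#' immediately preceding the end of the baseline window (`pre1970_2`,
#' `pre1970_3`) -- as a sensitivity check on the window choice.
#'
#' @param profile Data frame with `year` and a value column (`chla_mg_g`
#'   by default).
#' @param modern,baseline Closed year windows `c(from, to)`; the modern
#'   window is unbounded above by default.
#' @param variant One of `"primary"`, `"last2"`, `"last3"`,
#'   `"pre1970_2"`, `"pre1970_3"`.
#' @param value Name of the value column.
#' @param lake_id Optional identifier carried into the result.
#' @return Object of class `enrichment_result`: list with `lake_id`,
#'   `ef`, `modern_window`, `baseline_window`, `n_modern`, `n_baseline`,
#'   `variant`.
#' @export
enrichment_factor <- function(profile,
                              modern = c(2000, Inf),
                              baseline = c(1955, 1970),
                              variant = c("primary", "last2", "last3",
                                          "pre1970_2", "pre1970_3"),
                              value = "chla_mg_g",
                              lake_id = attr(profile, "lake_id")) {
  variant <- match.arg(variant)
  yr <- profile$year
  v <- profile[[value]]
  if (is.null(v)) stop("no '", value, "' column in profile")
  ok <- is.finite(yr) & is.finite(v)
  yr <- yr[ok]; v <- v[ok]

  pick_recent <- function(k) order(yr, decreasing = TRUE)[seq_len(k)]
  pick_pre <- function(k, cutoff) {
    cand <- which(yr <= cutoff)
    cand[order(yr[cand], decreasing = TRUE)][seq_len(k)]
  }
  i_mod <- which(yr >= modern[1] & yr <= modern[2])
  i_base <- which(yr >= baseline[1] & yr <= baseline[2])
  k <- switch(variant, last2 = 2L, last3 = 3L, pre1970_2 = 2L,
              pre1970_3 = 3L, 0L)
  if (variant %in% c("last2", "last3")) {
    if (length(yr) < k) stop("window_empty: fewer than ", k, " intervals")
    i_mod <- pick_recent(k)
  } else if (variant %in% c("pre1970_2", "pre1970_3")) {
    if (sum(yr <= baseline[2]) < k) {
      stop("window_empty: fewer than ", k, " intervals preceding ", baseline[2])
    }
    i_base <- pick_pre(k, baseline[2])
  }
  if (!length(i_mod)) {
    stop("window_empty: no intervals in modern window [",
         modern[1], ", ", modern[2], "]")
  }
  if (!length(i_base)) {
    stop("window_empty: no intervals in baseline window [",
         baseline[1], ", ", baseline[2], "]")
  }
  structure(list(lake_id = lake_id,
                 ef = mean(v[i_mod]) / mean(v[i_base]),
                 modern_window = range(yr[i_mod]),
                 baseline_window = range(yr[i_base]),
                 n_modern = length(i_mod), n_baseline = length(i_base),
                 variant = variant),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("EF (%s%s) = %.3g  [modern n=%d %s-%s / baseline n=%d %s-%s]\n",
              if (!is.null(x$lake_id)) paste0(x$lake_id, ", ") else "",
              x$variant, x$ef, x$n_modern,
              round(x$modern_window[1]), round(x$modern_window[2]),
              x$n_baseline,
              round(x$baseline_window[1]), round(x$baseline_window[2])))
  invisible(x)
}

#' Total dibenzothiophenes
#'
#' Sum of the parent compound and its C1-C4 alkylated homologues.
#'
#' @param parent,c1,c2,c3,c4 Concentrations, ng/g dry weight (vectors
#'   recycled to a common length).
#' @param missing_as_zero Treat `NA` analytes as zero (default FALSE:
#'   `NA` propagates).
#' @return Total DBT concentration, ng/g.
#' @export
total_dbt <- function(parent, c1, c2, c3, c4, missing_as_zero = FALSE) {
  m <- cbind(parent, c1, c2, c3, c4)
  if (any(m < 0, na.rm = TRUE)) stop("DBT concentrations must be >= 0")
  rowSums(m, na.rm = missing_as_zero)
}

#' DBT enrichment factor
#'
#' Same mean-ratio computation as [enrichment_factor()] applied to a
#' dated total-DBT series.  Returns an inapplicable result (rather than
#' erroring) when the baseline window holds no DBT data, e.g. where the
#' DBT record does not extend back to pre-industrial times.
#'
#' @inheritParams enrichment_factor
#' @param value Name of the total-DBT column (default `"dbt_total_ng_g"`).
#' @return An `enrichment_result`, or a list with `applicable = FALSE`
#'   and a `reason` when a window is empty.
#' @export
dbt_enrichment_factor <- function(profile,
                                  modern = c(2000, Inf),
                                  baseline = c(1955, 1970),
                                  value = "dbt_total_ng_g",
                                  lake_id = attr(profile, "lake_id")) {
  tryCatch(
    enrichment_factor(profile, modern = modern, baseline = baseline,
                      variant = "primary", value = value, lake_id = lake_id),
    error = function(e) {
      if (!grepl("window_empty", conditionMessage(e))) stop(e)
      structure(list(lake_id = lake_id, ef = NA_real_, applicable = FALSE,
                     reason = conditionMessage(e)),
                class = c("enrichment_inapplicable", "enrichment_result"))
    }
  )
}

#' Classify sites by DBT enrichment
#'
#' Threshold rule: DBT enrichment factor above 2 is "highly"
#' DBT-enriched, at or below 2 "minimally" (a factor of exactly 2 is
#' classified minimally; documented tie-break), and sites without a
#' computable DBT enrichment factor are "undetermined".
#'
#' @param x Data frame with columns `lake_id` and `dbt_ef` (`NA` =
#'   inapplicable), or a numeric vector of DBT enrichment factors.
#' @param threshold Division point (default 2).
#' @return The input with a `group` factor
#'   (`minimally`/`highly`/`undetermined`) appended (or a factor for
#'   vector input).
#' @export
classify_sites <- function(x, threshold = 2) {
  ef <- if (is.data.frame(x)) x$dbt_ef else x
  group <- factor(ifelse(is.na(ef), "undetermined",
                         ifelse(ef > threshold, "highly", "minimally")),
                  levels = c("minimally", "highly", "undetermined"))
  if (is.data.frame(x)) {
    x$group <- group
    x
  } else group
}

#' Standardized Z scores of a concentration series
#'
#' Per-series standardization: (value - mean) / SD, using the series'
#' own full-record mean and sample SD (n - 1 denominator).
#'
#' @param x Numeric vector (>= 2 values, non-constant).
#' @return Z scores (mean 0, sample SD 1).
#' @export
zscores <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 values")
  s <- stats::sd(x)
  if (s == 0) stop("zero standard deviation: Z scores undefined")
  (x - mean(x)) / s
}

#' Average a dated series into 5-year calendar bins
#'
#' Bins are `[5k, 5k + 4]` calendar years anchored at multiples of 5;
#' each observation is assigned to the bin of its (midpoint-estimated)
#' year and the bin value is the unweighted mean of all observations
#' falling in it -- pooled across lakes when a group's series are
#' concatenated.  Intervals spanning more than the bin width keep their
#' midpoint assignment.
#'
#' @param year Calendar years (interval midpoint dates).
#' @param value Values to average.
#' @param width Bin width in years (default 5).
#' @return Data frame of class `binned_series`: `bin_start`, `mean`, `n`.
#' @export
bin_5yr <- function(year, value, width = 5) {
  ok <- is.finite(year) & is.finite(value)
  year <- year[ok]; value <- value[ok]
  if (!length(year)) {
    return(structure(data.frame(bin_start = numeric(0), mean = numeric(0),
                                n = integer(0)),
                     class = c("binned_series", "data.frame")))
  }
  bin <- floor(year / width) * width
  agg <- tapply(value, bin, mean)
  n <- tapply(value, bin, length)
  structure(data.frame(bin_start = as.numeric(names(agg)),
                       mean = as.numeric(agg), n = as.integer(n),
                       row.names = NULL),
            class = c("binned_series", "data.frame"))
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.  When both groups have zero
#' variance and equal means the test is degenerate and p = 1 by
#' convention.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List: `t`, `df`, `p`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pearson correlation with significance
#'
#' Product-moment correlation with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.  For climate analyses, pair the
#' series by 5-year bin (see [bin_5yr()]) before calling.
#'
#' @param x,y Paired numeric vectors (n >= 3, non-constant).
#' @return List: `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
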