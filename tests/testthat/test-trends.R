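test_that("enrichment factor is the ratio of window means", {
  p <- ef_profile()                        # baseline mean 1, modern mean 2
  e <- enrichment_factor(p)
  expect_equal(e$ef, 2)
  expect_equal(e$n_modern, 6)
  expect_equal(e$n_baseline, 4)
  ## constant profile gives EF 1
  pc <- ef_profile(baseline_value = 3, modern_value = 3)
  expect_equal(enrichment_factor(pc)$ef, 1)
  ## scale invariance
  p2 <- p; p2$chla_mg_g <- p2$chla_mg_g * 7.3
  expect_equal(enrichment_factor(p2)$ef, e$ef)
})

test_that("enrichment windows are closed and empty windows error by name", {
  p <- data.frame(year = c(1970, 2000), chla_mg_g = c(1, 2))
  e <- enrichment_factor(p)                # both boundary years included
  expect_equal(e$ef, 2)
  p_empty <- data.frame(year = c(1980, 2005), chla_mg_g = c(1, 2))
  expect_error(enrichment_factor(p_empty), "baseline window")
  p_old <- data.frame(year = c(1960, 1990), chla_mg_g = c(1, 2))
  expect_error(enrichment_factor(p_old), "modern window")
})

test_that("interval-count variants select the right intervals", {
  p <- data.frame(year = c(2011, 2009, 2007, 2005, 1968, 1964, 1960, 1956),
                  chla_mg_g = c(4, 3, 2, 1, 1, 1, 2, 4))
  e2 <- enrichment_factor(p, variant = "last2")
  expect_equal(e2$n_modern, 2)
  expect_equal(e2$ef, mean(c(4, 3)) / 2)       # baseline 1955-1970 mean = 2
  e3 <- enrichment_factor(p, variant = "pre1970_3")
  expect_equal(e3$n_baseline, 3)
  expect_equal(e3$ef, 2.5 / mean(c(1, 1, 2)))  # 3 intervals nearest 1970
  expect_error(enrichment_factor(p[1:3, ], variant = "pre1970_2"), "preceding")
})

test_that("total DBTs sum the parent and C1-C4 homologues", {
  expect_equal(total_dbt(10, 20, 30, 20, 20), 100)
  expect_equal(total_dbt(0, 0, 0, 0, 0), 0)
  expect_equal(total_dbt(10, 20, NA, 20, 20, missing_as_zero = TRUE), 70)
  expect_true(is.na(total_dbt(10, 20, NA, 20, 20)))
  expect_error(total_dbt(-1, 0, 0, 0, 0), ">= 0")
})

test_that("DBT enrichment mirrors the chl-a computation and records inapplicability", {
  p <- data.frame(year = seq(2011, 1951, by = -4),
                  dbt_total_ng_g = ifelse(seq(2011, 1951, by = -4) >= 1970,
                                          140, 20))
  e <- dbt_enrichment_factor(p)
  expect_equal(e$ef, 7)
  pc <- p; pc$dbt_total_ng_g <- 55
  expect_equal(dbt_enrichment_factor(pc)$ef, 1)
  ## record without pre-industrial data is inapplicable, not an error
  short <- p[p$year >= 1990, ]
  r <- dbt_enrichment_factor(short, lake_id = "X")
  expect_false(isTRUE(r$applicable))
  expect_match(r$reason, "baseline")
})

test_that("threshold-2 classification reproduces the published grouping", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 23)
  expect_equal(as.character(t1$group[t1$site == "RAMP 271"]), "minimally")
  expect_equal(as.character(t1$group[t1$site == "NE13"]), "highly")
  expect_equal(as.character(t1$group[t1$site == "RAMP 227"]), "undetermined")
  counts <- table(t1$group)
  expect_equal(unname(counts["minimally"]), 6L)
  expect_equal(unname(counts["highly"]), 16L)
  expect_equal(unname(counts["undetermined"]), 1L)
  ## exact threshold ties go to the minimally enriched group
  expect_equal(as.character(classify_sites(2)), "minimally")
  expect_equal(as.character(classify_sites(2.000001)), "highly")
})

test_that("Z scores standardize to mean 0 and sample SD 1, affine-invariantly", {
  expect_equal(zscores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  for (k in 1:5) {
    x <- rnorm(30, 5, 2)
    z <- zscores(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    expect_equal(zscores(2.7 * x + 11), z, tolerance = 1e-10)
  }
  expect_error(zscores(rep(1, 5)), "zero standard deviation")
  expect_error(zscores(3), "at least 2")
})

test_that("5-year bins anchor at multiples of five and average contents", {
  b <- bin_5yr(c(1971, 1973), c(1, 3))
  expect_equal(b$bin_start, 1970)
  expect_equal(b$mean, 2)
  expect_equal(b$n, 2L)
  expect_equal(bin_5yr(1984, 7)$mean, 7)
  expect_equal(nrow(bin_5yr(numeric(0), numeric(0))), 0)
})

test_that("binned group means match a brute-force loop over lakes and bins", {
  set.seed(12)
  dat <- do.call(rbind, lapply(1:4, function(l) {
    data.frame(lake = l, year = sample(1950:2010, 25),
               z = rnorm(25))
  }))
  b <- bin_5yr(dat$year, dat$z)
  for (i in seq_len(nrow(b))) {
    sel <- floor(dat$year / 5) * 5 == b$bin_start[i]
    expect_equal(b$mean[i], mean(dat$z[sel]))
    expect_equal(b$n[i], sum(sel))
  }
})

test_that("Welch t-test matches the closed-form hand computation", {
  r <- welch_ttest(c(1, 2, 3), c(1, 2, 3, 4, 5))
  expect_equal(r$t, (2 - 3) / sqrt(1 / 3 + 2.5 / 5), tolerance = 1e-10)
  expect_equal(r$t, -1.0954451, tolerance = 1e-6)
  expect_equal(r$df, (1 / 3 + 0.5)^2 / ((1 / 3)^2 / 2 + 0.5^2 / 4),
               tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(r$t, r$df), tolerance = 1e-10)
  ## identical groups: t = 0, p = 1
  same <- welch_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Welch p agrees with a 1e5-draw permutation test on a balanced fixture", {
  set.seed(31)
  a <- rnorm(12, 0.3); b <- rnorm(12, 0)
  w <- welch_ttest(a, b)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  reps <- 1e5
  perm <- replicate(reps, {
    i <- sample.int(24, 12)
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  p_perm <- (sum(perm >= obs) + 1) / (reps + 1)
  expect_lt(abs(w$p - p_perm), 0.03)
})

test_that("Pearson correlation matches the covariance formula and edge cases", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  set.seed(8)
  u <- rnorm(8); v <- 0.4 * u + rnorm(8)
  r <- pearson_with_p(u, v)
  r_direct <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(r$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt((8 - 2) / (1 - r_direct^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), 6), tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "constant")
})
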