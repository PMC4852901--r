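## Delimited-text I/O.  All tables are tab-separated with a header row;
## missing values are empty fields.  The writers emit exactly what the
## readers consume, so simulated fixtures and real data are
## interchangeable.

read_table_ <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

write_table_ <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a core interval table
#'
#' One row per sediment interval: `lake_id`, `top_cm`, `bottom_cm`,
#' `dry_mass_g_cm2`, radionuclide activities with SDs (`pb210_Bq_g`,
#' `pb210_sd`, `ra226_Bq_g`, `ra226_sd`, `cs137_Bq_g`, `cs137_sd`), and
#' any additional columns (chlorophyll-a, DBT analytes) pass through.
#'
#' @param path File path.
#' @return For the reader, a validated [as_radionuclide_profile()] data
#'   frame.
#' @export
read_core_table <- function(path) {
  as_radionuclide_profile(read_table_(path))
}

#' @rdname read_core_table
#' @param x Interval data frame (e.g. the `intervals` element of a
#'   [simulate_core()] result).
#' @export
write_core_table <- function(x, path) write_table_(x, path)

#' Read / write a chronology table
#'
#' One row per dated interval: `lake_id`, `top_cm`, `bottom_cm`,
#' `mid_depth_cm`, `year` (CRS or extrapolated), `sd2_yr`,
#' `year_smoothed` if present, `method`.
#'
#' @param model An `age_depth_model`.
#' @param path File path.
#' @param lake_id Identifier written with the table.
#' @export
write_chronology_table <- function(model, path, lake_id = "core") {
  df <- as.data.frame(model)
  df <- cbind(lake_id = lake_id, df)
  write_table_(df, path)
}

#' @rdname write_chronology_table
#' @export
read_chronology_table <- function(path) read_table_(path)

#' Read / write a snow-site table
#'
#' One row per site: `site_id`, projected coordinates `x_m`, `y_m`,
#' `swe_mm`, and one concentration column per analyte (mg/L) and/or a
#' `loading_mg_m2` column.
#'
#' @param path File path.
#' @export
read_snow_table <- function(path) {
  x <- read_table_(path)
  class(x) <- c("snow_sites", "data.frame")
  x
}

#' @rdname read_snow_table
#' @param x Snow-site data frame.
#' @export
write_snow_table <- function(x, path) write_table_(x, path)

#' Read / write a climate series table
#'
#' One row per year: `year`, `temp_annual`, seasonal temperature
#' columns, `precip_mm`.
#'
#' @param path File path.
#' @export
read_climate_table <- function(path) {
  x <- read_table_(path)
  class(x) <- c("climate_series", "data.frame")
  x
}

#' @rdname read_climate_table
#' @param x Climate data frame.
#' @export
write_climate_table <- function(x, path) write_table_(x, path)

#' Read / write a long-format spectra table
#'
#' Columns `interval`, `wavelength_nm`, `reflectance` (optionally
#' `lake_id`), one block per sediment interval.
#'
#' @param path File path.
#' @export
read_spectra_table <- function(path) read_table_(path)

#' @rdname read_spectra_table
#' @param x Long spectra data frame.
#' @export
write_spectra_table <- function(x, path) write_table_(x, path)

#' Export a loading field as gridded CSV
#'
#' One row per grid cell: `x_m`, `y_m`, `loading_mg_m2`,
#' `kriging_variance`.
#'
#' @param field A `loading_field`.
#' @param path File path.
#' @export
write_field_csv <- function(field, path) {
  g <- expand.grid(x_m = field$x, y_m = field$y)
  g$loading_mg_m2 <- as.vector(field$pred)
  g$kriging_variance <- as.vector(field$var)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' Export a loading field as GeoJSON grid-cell features
#'
#' Each cell becomes a square Polygon feature with `loading` and
#' `variance` properties (coordinates in the field's projected metres).
#'
#' @param field A `loading_field`.
#' @param path File path.
#' @export
write_field_geojson <- function(field, path) {
  half <- field$cell_size / 2
  feats <- character(0)
  for (j in seq_along(field$y)) {
    for (i in seq_along(field$x)) {
      cx <- field$x[i]; cy <- field$y[j]
      ring <- sprintf("[%g,%g]",
                      c(cx - half, cx + half, cx + half, cx - half, cx - half),
                      c(cy - half, cy - half, cy + half, cy + half, cy - half))
      feats <- c(feats, sprintf(
        '{"type":"Feature","properties":{"loading":%g,"variance":%g},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
        field$pred[i, j], field$var[i, j], paste(ring, collapse = ",")))
    }
  }
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feats, collapse = ",")), path)
  invisible(path)
}

#' The 23-site enrichment-factor table
#'
#' The published per-site summary shipped with the package: site name,
#' chlorophyll-a enrichment factor, DBT enrichment factor (missing where
#' the DBT record does not reach pre-industrial times), mean post-2000
#' total DBT concentration (ng/g dry weight), and whether breakpoint
#' analysis was considered applicable at the site.
#'
#' @return Data frame with 23 rows and a `group` column from
#'   [classify_sites()].
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_sites.csv", package = "paleoprod",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$lake_id <- x$site
  classify_sites(x)
}
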