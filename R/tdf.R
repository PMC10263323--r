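#' Calculate a trophic discrimination factor from consumer and source means
#'
#' The trophic discrimination factor (TDF, Delta) is the systematic isotopic
#' enrichment between a consumer's tissue and its diet. With only group
#' means available it is estimated, per tracer, as the mean and sample SD of
#' the per-source differences (consumer mean - source mean), one difference
#' per candidate source, equally weighted regardless of source sample size.
#' Negative carbon TDFs are legitimate (sources enriched above the
#' consumer).
#'
#' @param consumer_mean Named numeric vector or list with elements `d13C`
#'   and `d15N`: the consumer's mean tissue values (permil).
#' @param sources A source-summary tibble (see [read_sources()]); the
#'   candidate diet sources. The source set is an explicit input and is
#'   never inferred.
#' @param name Label for the resulting TDF (default `"calculated"`).
#' @return A one-row `tdf` tibble: `name`, `mean_dC`, `sd_dC`, `mean_dN`,
#'   `sd_dN`, `provenance = "calculated"`. With a single source the SDs
#'   are 0.
#' @examples
#' src <- tibble::tibble(name = c("a", "b"), zone = "pelagic",
#'                       mean_d13C = c(-21.05, -24), sd_d13C = 0.1,
#'                       mean_d15N = c(3.46, 4.7), sd_d15N = 0.1, n = 3)
#' calc_tdf(c(d13C = -15.3, d15N = 6.63), src)
#' @export
calc_tdf <- function(consumer_mean, sources, name = "calculated") {
  if (is.null(sources) || nrow(sources) == 0) {
    iso_abort("calc_tdf(): at least one source is required",
              class = "isoweb_empty_input_error")
  }
  dC <- consumer_mean[["d13C"]] - sources$mean_d13C
  dN <- consumer_mean[["d15N"]] - sources$mean_d15N
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  tibble(
    name = name,
    mean_dC = mean(dC), sd_dC = sd0(dC),
    mean_dN = mean(dN), sd_dN = sd0(dN),
    provenance = "calculated"
  )
}

#' Zone-wise trophic discrimination factors
#'
#' Splits the candidate sources by habitat zone and computes [calc_tdf()]
#' within each zone present. Zones with no sources are simply absent from
#' the result.
#'
#' @inheritParams calc_tdf
#' @return A `tdf` tibble with one row per zone present, plus a `zone`
#'   column.
#' @export
calc_tdf_by_zone <- function(consumer_mean, sources) {
  if (is.null(sources) || nrow(sources) == 0) {
    iso_abort("calc_tdf_by_zone(): at least one source is required",
              class = "isoweb_empty_input_error")
  }
  sources |>
    dplyr::filter(!is.na(.data$zone)) |>
    dplyr::group_by(zone = .data$zone) |>
    dplyr::group_modify(function(df, key) {
      calc_tdf(consumer_mean, df, name = key$zone)
    }) |>
    dplyr::ungroup()
}

#' Regress per-source TDF on source isotope values
#'
#' Ordinary least-squares fit of the per-source discrimination (dependent)
#' on the source isotope value (independent), used to ask whether the
#' apparent TDF depends on the isotopic signature of the diet source. Note
#' that when the consumer mean is fixed the difference is an affine function
#' of the source value with slope -1, so a slope near -1 with high r-squared
#' indicates the differences carry no information beyond the source values
#' themselves.
#'
#' @param source_values Numeric vector of source isotope values (permil),
#'   one per source.
#' @param tdf_values Numeric vector of per-source discriminations
#'   (consumer - source), same length.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
tdf_source_regression <- function(source_values, tdf_values) {
  if (length(source_values) != length(tdf_values)) {
    iso_abort("source_values and tdf_values must have the same length",
              class = "isoweb_validation_error")
  }
  if (length(source_values) < 3) {
    iso_abort("tdf_source_regression(): at least 3 points required",
              class = "isoweb_insufficient_data_error")
  }
  if (stats::var(source_values) == 0) {
    iso_abort("tdf_source_regression(): zero variance in source values",
              class = "isoweb_degenerate_fit_error")
  }
  fit <- stats::lm(tdf_values ~ source_values)
  # an exact linear relation triggers a harmless perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = p,
    n = length(source_values)
  )
}

#' Published and calculated TDF presets
#'
#' The five TDF parameterizations used in the rainbow-trout diet model grid:
#' TDF1 is the locally calculated value; TDF2-TDF5 are published salmonid /
#' generalist values. TDF4 is published without uncertainties, so its SDs
#' are 0.
#'
#' @return A `tdf` tibble with rows TDF1..TDF5.
#' @export
tdf_presets <- function() {
  path <- system.file("extdata", "tdf_presets.csv", package = "isoweb")
  df <- readr::read_csv(path, col_types = "cddddc", progress = FALSE)
  df
}
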