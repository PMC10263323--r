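#' Define a trophic baseline organism
#'
#' A baseline is an organism of assumed trophic position lambda (2 for a
#' primary consumer, 1 for a primary producer) whose delta15N anchors the
#' trophic-position calculation, and whose delta13C locates it on the
#' littoral-pelagic axis for two-source mixing.
#'
#' @param name Organism label.
#' @param d13C,d15N Baseline isotope values (permil).
#' @param lambda Assumed trophic position (>= 1).
#' @return A one-row `baseline` tibble.
#' @export
baseline <- function(name, d13C, d15N, lambda = 2) {
  if (lambda < 1) {
    iso_abort("baseline lambda must be >= 1", class = "isoweb_validation_error")
  }
  tibble(name = name, d13C = d13C, d15N = d15N, lambda = lambda)
}

#' Two-source (two-baseline) trophic position
#'
#' Computes the trophic position of a consumer integrating two habitat
#' baselines (e.g. a littoral and a pelagic primary consumer). The reliance
#' on baseline 1 is estimated from carbon alone,
#' alpha = (d13C_consumer - d13C_base2) / (d13C_base1 - d13C_base2),
#' clipped to [0, 1], and the trophic position is
#' TP = lambda + (d15N_consumer - [alpha d15N_base1 + (1-alpha) d15N_base2]) / Delta_n,
#' where Delta_n is the per-step nitrogen discrimination (permil).
#'
#' @param consumer Named vector/list with `d13C`, `d15N` (mean tissue
#'   values), optionally `name`.
#' @param base1,base2 One-row `baseline` tibbles with equal `lambda` and
#'   distinct `d13C`.
#' @param delta_n Nitrogen TDF per trophic step (permil, > 0). Common
#'   choices: the 3.4 literature default or a locally calculated value.
#' @return A one-row `trophic_result` tibble: `consumer`, `alpha_littoral`
#'   (reliance on base1), `trophic_position`, `delta_n`, `baseline1`,
#'   `baseline2`.
#' @export
trophic_position_two_source <- function(consumer, base1, base2, delta_n) {
  if (delta_n <= 0) {
    iso_abort("delta_n must be > 0", class = "isoweb_parameter_error")
  }
  if (base1$d13C == base2$d13C) {
    iso_abort("baselines must differ in d13C for two-source mixing",
              class = "isoweb_division_error")
  }
  if (base1$lambda != base2$lambda) {
    iso_abort("baselines must share the same lambda",
              class = "isoweb_validation_error")
  }
  alpha <- (consumer[["d13C"]] - base2$d13C) / (base1$d13C - base2$d13C)
  alpha <- min(1, max(0, alpha))
  base_n <- alpha * base1$d15N + (1 - alpha) * base2$d15N
  tp <- base1$lambda + (consumer[["d15N"]] - base_n) / delta_n
  tibble(
    consumer = consumer_label(consumer),
    alpha_littoral = alpha,
    trophic_position = tp,
    delta_n = delta_n,
    baseline1 = base1$name,
    baseline2 = base2$name
  )
}

#' Single-baseline trophic position
#'
#' TP = lambda + (d15N_consumer - d15N_base) / Delta_n.
#'
#' @inheritParams trophic_position_two_source
#' @param base One-row `baseline` tibble.
#' @return A one-row `trophic_result` tibble (with `alpha_littoral = NA`).
#' @export
trophic_position_single <- function(consumer, base, delta_n) {
  if (delta_n <= 0) {
    iso_abort("delta_n must be > 0", class = "isoweb_parameter_error")
  }
  tp <- base$lambda + (consumer[["d15N"]] - base$d15N) / delta_n
  tibble(
    consumer = consumer_label(consumer),
    alpha_littoral = NA_real_,
    trophic_position = tp,
    delta_n = delta_n,
    baseline1 = base$name,
    baseline2 = NA_character_
  )
}

#' Trophic level of a primary consumer from its sources
#'
#' TL = 1 + (d15N_consumer - mean d15N of its sources) / Delta_n; the
#' standard way to anchor a primary-consumer baseline when only producer
#' values are measured.
#'
#' @param consumer_d15N Consumer mean delta15N (permil).
#' @param source_d15N Numeric vector of source delta15N values.
#' @param delta_n Nitrogen TDF per trophic step (> 0).
#' @return Numeric trophic level.
#' @export
primary_consumer_baseline <- function(consumer_d15N, source_d15N, delta_n) {
  if (length(source_d15N) == 0) {
    iso_abort("primary_consumer_baseline(): at least one source required",
              class = "isoweb_empty_input_error")
  }
  if (delta_n <= 0) {
    iso_abort("delta_n must be > 0", class = "isoweb_parameter_error")
  }
  1 + (consumer_d15N - mean(source_d15N)) / delta_n
}

#' Food-chain length
#'
#' The maximum trophic position over the supplied top consumers.
#'
#' @param trophic_results A `trophic_result` tibble (>= 1 row), as stacked
#'   output of the trophic-position functions.
#' @return Numeric maximum trophic position.
#' @export
food_chain_length <- function(trophic_results) {
  if (is.null(trophic_results) || nrow(trophic_results) == 0) {
    iso_abort("food_chain_length(): no trophic results supplied",
              class = "isoweb_empty_input_error")
  }
  max(trophic_results$trophic_position)
}

consumer_label <- function(consumer) {
  lbl <- tryCatch(consumer[["name"]], error = function(e) NULL)
  if (is.null(lbl) || is.na(lbl)) lbl <- "consumer"
  as.character(lbl)
}
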