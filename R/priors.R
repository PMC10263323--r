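#' Uniform Dirichlet prior over diet proportions
#'
#' The generalist prior: every source is a priori equally likely to be
#' eaten. Each concentration parameter is alpha_i = 1, so the prior mean is
#' 1/n per source and the total concentration sum(alpha) equals the number
#' of sources n. The alternative normalization alpha_i = 1/n (total
#' concentration 1) is selectable but not the default.
#'
#' @param source_names Character vector of source names (>= 2).
#' @param total One of `"n"` (default; alpha_i = 1) or `"one"`
#'   (alpha_i = 1/n).
#' @return A `dirichlet_prior` tibble: `source_name`, `alpha`, with
#'   attribute `kind = "uniform"`.
#' @export
uniform_prior <- function(source_names, total = c("n", "one")) {
  total <- match.arg(total)
  n <- length(source_names)
  if (n < 2) {
    iso_abort("a mixing prior needs at least 2 sources",
              class = "isoweb_degenerate_mixture_error")
  }
  if (anyDuplicated(source_names)) {
    iso_abort("source names must be unique", class = "isoweb_validation_error")
  }
  alpha <- if (total == "n") rep(1, n) else rep(1 / n, n)
  new_prior(source_names, alpha, kind = "uniform")
}

#' Biomass-informed Dirichlet prior over diet proportions
#'
#' Encodes the expectation that a source is eaten in proportion to its
#' standing biomass. Annual average biomasses b_i (mg C m^-2) are
#' standardized so that the total concentration equals the number of
#' sources n, the same total as the uniform prior -- a deliberately
#' less-aggressive informative prior that shifts the mean without
#' sharpening it: alpha_i = b_i * n / sum(b).
#'
#' A source with no biomass estimate can be given the arithmetic mean of
#' the known biomasses (`neutral_fill = TRUE`), a neutral concentration
#' that avoids biasing its contribution either way.
#'
#' @param source_names Character vector of source names (>= 2).
#' @param biomass A tibble with columns `source_name`, `biomass` (mg C
#'   m^-2), as from [read_biomass()].
#' @param neutral_fill If `TRUE`, sources absent from `biomass` receive the
#'   mean of the known biomasses before standardization; if `FALSE`
#'   (default) a missing source is an error.
#' @return A `dirichlet_prior` tibble: `source_name`, `alpha`, attribute
#'   `kind = "biomass"`. `sum(alpha)` equals `length(source_names)` exactly.
#' @examples
#' bm <- tibble::tibble(source_name = c("a", "b", "c"), biomass = c(2, 1, 1))
#' biomass_prior(c("a", "b", "c"), bm)  # alpha = 1.5, 0.75, 0.75
#' @export
biomass_prior <- function(source_names, biomass, neutral_fill = FALSE) {
  n <- length(source_names)
  if (n < 2) {
    iso_abort("a mixing prior needs at least 2 sources",
              class = "isoweb_degenerate_mixture_error")
  }
  b <- biomass$biomass[match(source_names, biomass$source_name)]
  if (any(!is.na(b) & b <= 0)) {
    iso_abort("biomass values must be > 0", class = "isoweb_validation_error")
  }
  if (anyNA(b)) {
    if (!neutral_fill) {
      iso_abort(sprintf("missing biomass for source(s): %s",
                        paste(source_names[is.na(b)], collapse = ", ")),
                class = "isoweb_missing_data_error")
    }
    if (all(is.na(b))) {
      iso_abort("neutral_fill requires at least one known biomass",
                class = "isoweb_missing_data_error")
    }
    b[is.na(b)] <- mean(b, na.rm = TRUE)
  }
  alpha <- b * n / sum(b)
  new_prior(source_names, alpha, kind = "biomass")
}

new_prior <- function(source_names, alpha, kind) {
  out <- tibble(source_name = as.character(source_names), alpha = alpha)
  attr(out, "kind") <- kind
  class(out) <- c("dirichlet_prior", class(out))
  out
}

#' Prior mean diet proportions
#'
#' @param prior A `dirichlet_prior` tibble.
#' @return Named numeric vector E[p_i] = alpha_i / sum(alpha).
#' @export
prior_mean <- function(prior) {
  stats::setNames(prior$alpha / sum(prior$alpha), prior$source_name)
}

#' Serialize a prior to JSON
#'
#' @param prior A `dirichlet_prior` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prior <- function(prior, path) {
  jsonlite::write_json(
    list(kind = attr(prior, "kind"),
         source_names = prior$source_name,
         alpha = prior$alpha),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
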