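#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted diet posterior
#'
#' @param x A `diet_posterior`.
#' @param pars Which parameters to return: `"p"` (global diet proportions,
#'   default), `"primary"` (proportions, error scales, random-effect
#'   scale) or `"all"`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high` (central 95% interval),
#'   `rhat`.
#' @export
tidy.diet_posterior <- function(x, pars = c("p", "primary", "all"), ...) {
  pars <- match.arg(pars)
  pat <- switch(pars,
                p = "^p\\[",
                primary = "^p\\[|^xi\\[|^sigma_re$",
                all = "")
  s <- x$summary[grepl(pat, x$summary$parameter), ]
  out <- tibble(
    term = s$parameter,
    estimate = s$mean,
    std.error = s$sd,
    conf.low = s$q2.5,
    conf.high = s$q97.5
  )
  out$rhat <- x$diagnostics$rhat[match(out$term, x$diagnostics$parameter)]
  out
}

#' One-line summary of a fitted diet posterior
#'
#' @param x A `diet_posterior`.
#' @param ... Unused.
#' @return A one-row tibble: chain settings, counts, `max_rhat`,
#'   `converged` (all R-hat < 1.1), `seed`.
#' @export
glance.diet_posterior <- function(x, ...) {
  rh <- x$diagnostics$rhat
  tibble(
    n_sources = nrow(x$spec$sources),
    n_consumers = length(x$consumer_ids),
    chains = x$settings$chains,
    iterations = x$settings$iterations,
    burn = x$settings$burn,
    thin = x$settings$thin,
    max_rhat = if (all(is.na(rh))) NA_real_ else max(rh, na.rm = TRUE),
    converged = all(is.na(rh)) || all(rh < 1.1, na.rm = TRUE),
    seed = x$settings$seed
  )
}

#' Plot posterior diet proportions
#'
#' Density ridges of the posterior draws of each global diet proportion.
#'
#' @param object A `diet_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diet_posterior <- function(object, ...) {
  nm <- paste0("p[", object$spec$sources$name, "]")
  df <- purrr::map_dfr(seq_along(nm), function(i) {
    tibble(source = object$spec$sources$name[i],
           p = as.vector(object$draws[, , nm[i]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, fill = .data$source)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "diet proportion", y = "posterior density",
                  fill = "source") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot consumers against the TDF-corrected mixing polygon
#'
#' Shows the TDF-corrected source means (polygon vertices) with +/- 1 SD
#' error bars and the consumers in delta13C-delta15N space.
#'
#' @param sources Source-summary tibble.
#' @param tdf One-row `tdf` tibble (or zone-keyed, see [polygon_test()]).
#' @param consumers Consumer tibble.
#' @return A ggplot object.
#' @export
plot_mixing_space <- function(sources, tdf, consumers) {
  tr <- match_tdf_rows(sources, tdf)
  src <- tibble(
    name = sources$name,
    d13C = sources$mean_d13C + tr$mean_dC,
    d15N = sources$mean_d15N + tr$mean_dN,
    sC = sqrt(sources$sd_d13C^2 + tr$sd_dC^2),
    sN = sqrt(sources$sd_d15N^2 + tr$sd_dN^2)
  )
  hull <- src[grDevices::chull(src$d13C, src$d15N), ]
  ggplot2::ggplot(src, ggplot2::aes(x = .data$d13C, y = .data$d15N)) +
    ggplot2::geom_polygon(data = hull, fill = NA, colour = "grey50",
                          linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$d15N - .data$sN,
                                        ymax = .data$d15N + .data$sN),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$d13C - .data$sC,
                                         xmax = .data$d13C + .data$sC),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$name), size = 3) +
    ggplot2::geom_point(data = consumers, colour = "black", shape = 4,
                        size = 2) +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰)"),
                  y = expression(delta^15 * N ~ "(‰)"),
                  colour = "source (TDF-corrected)") +
    ggplot2::theme_minimal()
}

#' Plot per-consumer polygon inclusion probabilities
#'
#' @param object A `polygon_result`.
#' @param ... Unused.
#' @return A ggplot object with the 0.05 pass threshold marked.
#' @export
autoplot.polygon_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id,
                                       y = .data$probability,
                                       fill = .data$pass_95)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = NULL, y = "inclusion probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' One-row summary of food-web metrics
#'
#' @param x A `web_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of the scalar metrics and category fractions.
#' @export
glance.web_metrics <- function(x, ...) {
  tibble(
    S = x$S, N = x$N, L = x$L, D1 = x$D1, D2 = x$D2, Lp = x$Lp, C = x$C,
    trophic_levels = x$trophic_levels,
    basal_fraction = x$fractions$basal,
    herbivore_fraction = x$fractions$herbivore,
    omnivore_fraction = x$fractions$omnivore,
    predator_fraction = x$fractions$predator,
    littoral_links = x$sublinks$littoral %||% NA_integer_,
    pelagic_links = x$sublinks$pelagic %||% NA_integer_,
    coupling_links = x$sublinks$coupling %||% NA_integer_
  )
}
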