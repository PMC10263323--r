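#' Fit the full TDF-by-prior model grid
#'
#' Fits the diet mixing model for every combination of a TDF row and a
#' prior on identical consumer data, then assembles the model-comparison
#' table (one row per model, best first), per-model convergence flags and
#' the mixing-polygon check. Models that fail the polygon assumption or
#' convergence are flagged, never dropped, so the comparison table always
#' has one row per requested model.
#'
#' @param consumers Consumer tibble (`sample_id`, `d13C`, `d15N`).
#' @param sources Source-summary tibble.
#' @param tdf_grid A `tdf` tibble, one row per TDF to try (e.g.
#'   [tdf_presets()], optionally with a calculated row appended).
#' @param priors Named list of `dirichlet_prior` objects (e.g.
#'   `list(uniform = ..., biomass = ...)`).
#' @param chains,iterations,burn,thin MCMC settings per model.
#' @param polygon_iterates Monte-Carlo iterates for the polygon check.
#' @param seed Integer seed; model m gets a sub-seed derived from it.
#' @param method `"loo"` or `"waic"` for the comparison.
#' @return A `model_grid` list: `comparison` (tibble with the criterion,
#'   SE, difference, SE of difference and weight columns plus `converged`,
#'   `polygon_pass` and `config_hash`), `fits` (named list of
#'   `diet_posterior`), `polygon` (named list of `polygon_result`).
#' @export
run_model_grid <- function(consumers, sources, tdf_grid, priors,
                           chains = 3, iterations = 30000, burn = 15000,
                           thin = 10, polygon_iterates = 1500, seed,
                           method = c("loo", "waic")) {
  method <- match.arg(method)
  if (missing(seed)) {
    iso_abort("run_model_grid(): seed is required",
              class = "isoweb_validation_error")
  }
  if (is.null(names(priors)) || any(names(priors) == "")) {
    iso_abort("priors must be a named list", class = "isoweb_validation_error")
  }
  grid <- tidyr::expand_grid(tdf_name = tdf_grid$name,
                             prior_name = names(priors))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid) * 2)
  fits <- list()
  polys <- list()
  for (m in seq_len(nrow(grid))) {
    tdf_row <- tdf_grid[tdf_grid$name == grid$tdf_name[m], ]
    spec <- mixing_model_spec(sources, tdf_row, priors[[grid$prior_name[m]]])
    nm <- paste(grid$tdf_name[m], grid$prior_name[m], sep = " + ")
    fits[[nm]] <- fit_mixing_model(spec, consumers, chains = chains,
                                   iterations = iterations, burn = burn,
                                   thin = thin, seed = sub_seeds[2 * m - 1])
    polys[[nm]] <- polygon_test(sources, tdf_row, consumers,
                                iterates = polygon_iterates,
                                seed = sub_seeds[2 * m])
  }
  comparison <- compare_models(fits, method = method)
  comparison$converged <- vapply(comparison$model, function(nm) {
    rh <- fits[[nm]]$diagnostics$rhat
    all(is.na(rh)) || all(rh < 1.1, na.rm = TRUE)
  }, logical(1))
  comparison$polygon_pass <- vapply(comparison$model, function(nm) {
    all(polys[[nm]]$pass_95)
  }, logical(1))
  cfg <- list(tdfs = tdf_grid, priors = lapply(priors, function(p) p$alpha),
              chains = chains, iterations = iterations, burn = burn,
              thin = thin, polygon_iterates = polygon_iterates, seed = seed,
              method = method)
  comparison$config_hash <- rlang::hash(cfg)
  structure(list(comparison = comparison, fits = fits, polygon = polys,
                 config = cfg),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("<model_grid> %d models\n", nrow(x$comparison)))
  print(dplyr::select(x$comparison, -"config_hash"))
  invisible(x)
}

#' Assemble a human-readable run report
#'
#' Formats the results of the analysis stages into a single plain-text
#' report: TDF estimates, prior vectors, the model-comparison table, diet
#' posterior summaries (sources sorted by posterior mean, descending),
#' polygon results, trophic positions and food-web metrics. Stages not
#' supplied are omitted with a notice line.
#'
#' @param tdfs Optional `tdf` tibble.
#' @param priors Optional named list of `dirichlet_prior`.
#' @param grid Optional `model_grid`.
#' @param trophic Optional `trophic_result` tibble.
#' @param metrics Optional `web_metrics`.
#' @param file Optional path; when given the report is also written there.
#' @return The report as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
report_run <- function(tdfs = NULL, priors = NULL, grid = NULL,
                       trophic = NULL, metrics = NULL, file = NULL) {
  if (is.null(tdfs) && is.null(priors) && is.null(grid) &&
      is.null(trophic) && is.null(metrics)) {
    iso_abort("report_run(): at least one completed stage is required",
              class = "isoweb_empty_input_error")
  }
  lines <- c("# isoweb run report", "")
  section <- function(title, body) c(paste0("## ", title), body, "")
  fmt_tbl <- function(df) utils::capture.output(print(as.data.frame(df),
                                                      row.names = FALSE))
  lines <- c(lines, if (!is.null(tdfs)) {
    section("Trophic discrimination factors", fmt_tbl(tdfs))
  } else "[TDF stage not run]")
  lines <- c(lines, if (!is.null(priors)) {
    section("Dirichlet priors",
            unlist(lapply(names(priors), function(nm) {
              sprintf("%s: alpha = (%s)", nm,
                      paste(signif(priors[[nm]]$alpha, 4), collapse = ", "))
            })))
  } else "[prior stage not run]")
  if (!is.null(grid)) {
    lines <- c(lines, section("Model comparison",
                              fmt_tbl(dplyr::select(grid$comparison,
                                                    -"config_hash"))))
    best <- grid$comparison$model[1]
    ds <- tidy(grid$fits[[best]]) |>
      dplyr::arrange(dplyr::desc(.data$estimate))
    lines <- c(lines, section(
      sprintf("Diet posterior (best model: %s), sources by posterior mean", best),
      fmt_tbl(ds)))
    pg <- purrr::imap_dfr(grid$polygon, function(p, nm) {
      tibble(model = nm, min_probability = min(p$probability),
             all_pass = all(p$pass_95))
    })
    lines <- c(lines, section("Mixing-polygon validation", fmt_tbl(pg)))
  } else {
    lines <- c(lines, "[mixing-model stage not run]")
  }
  lines <- c(lines, if (!is.null(trophic)) {
    section("Trophic positions", fmt_tbl(trophic))
  } else "[trophic stage not run]")
  lines <- c(lines, if (!is.null(metrics)) {
    section("Food-web topology", utils::capture.output(print(metrics)))
  } else "[topology stage not run]")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Published metrics for tropical versus temperate high-mountain lakes
#'
#' A static comparison table of food-web metrics for the two tropical
#' study lakes and three temperate high-mountain lakes, shipped as a
#' fixture for contextual comparison only (no computation is performed on
#' it).
#'
#' @return A tibble.
#' @export
temperate_comparison <- function() {
  path <- system.file("extdata", "temperate_lakes_comparison.csv",
                      package = "isoweb")
  readr::read_csv(path, col_types = "ciidddddcc", progress = FALSE)
}
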