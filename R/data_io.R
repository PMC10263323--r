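#' Read per-sample consumer isotope measurements
#'
#' Reads a delimited table of individual stable-isotope measurements
#' (delta13C in permil vs VPDB, delta15N in permil vs AIR) with habitat and
#' taxon labels, validating the schema and every row. Decimal commas in the
#' isotope columns are normalized to decimal points on read.
#'
#' @param path Path to a delimited text file with header
#'   `sample_id,lake,zone,taxon,group,d13C,d15N[,cn_ratio,tissue]`.
#' @return A tibble with one validated row per sample, in file order.
#' @details Validation: all required columns present; `zone` one of
#'   `"pelagic"`, `"littoral"`, `"profundal"`; `d13C`/`d15N` finite numbers
#'   (a warning is issued for values outside the ranges typical of lake
#'   biota, -40..0 and -15..20 permil); `sample_id` unique.
#' @export
read_consumers <- function(path) {
  df <- read_delim_chr(path)
  validate_consumers(df)
}

#' Validate a consumer measurement table
#'
#' @param df A data frame of consumer measurements (see [read_consumers()]).
#' @return The validated tibble (isotope columns numeric).
#' @export
validate_consumers <- function(df) {
  what <- "consumer table"
  stop_if_missing_cols(df, c("sample_id", "lake", "zone", "taxon", "group",
                             "d13C", "d15N"), what)
  df <- as_tibble(df)
  df$d13C <- parse_decimal(df$d13C, "d13C", what)
  df$d15N <- parse_decimal(df$d15N, "d15N", what)
  if ("cn_ratio" %in% names(df)) {
    df$cn_ratio <- parse_decimal(df$cn_ratio, "cn_ratio", what)
  }
  if (nrow(df) == 0) return(df)
  check_zone(df$zone, what)
  if (anyDuplicated(df$sample_id)) {
    iso_abort(sprintf("%s: duplicated sample_id '%s'", what,
                      df$sample_id[duplicated(df$sample_id)][1]),
              class = "isoweb_validation_error")
  }
  if (any(!is.finite(df$d13C)) || any(!is.finite(df$d15N))) {
    iso_abort(sprintf("%s: non-finite isotope value", what),
              class = "isoweb_validation_error")
  }
  if (any(df$d13C < -40 | df$d13C > 0) || any(df$d15N < -15 | df$d15N > 20)) {
    warn(paste(what, "has isotope values outside the typical lake-biota",
               "range (d13C -40..0, d15N -15..20 permil)"))
  }
  df
}

#' Read per-source isotope summaries
#'
#' @param path Path to a delimited file with header
#'   `name,zone,mean_d13C,sd_d13C,mean_d15N,sd_d15N,n`.
#' @return A validated tibble of source summaries.
#' @export
read_sources <- function(path) {
  df <- read_delim_chr(path)
  validate_sources(df)
}

#' Validate a source summary table
#'
#' @param df A data frame of per-source means/SDs (see [read_sources()]).
#' @return The validated tibble.
#' @export
validate_sources <- function(df) {
  what <- "source table"
  stop_if_missing_cols(df, c("name", "zone", "mean_d13C", "sd_d13C",
                             "mean_d15N", "sd_d15N", "n"), what)
  df <- as_tibble(df)
  for (col in c("mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N", "n")) {
    df[[col]] <- parse_decimal(df[[col]], col, what)
  }
  if (nrow(df) == 0) return(df)
  check_zone(df$zone, what, allow_na = TRUE)
  if (anyDuplicated(df$name)) {
    iso_abort(sprintf("%s: duplicated source name '%s'", what,
                      df$name[duplicated(df$name)][1]),
              class = "isoweb_validation_error")
  }
  if (any(df$sd_d13C < 0, na.rm = TRUE) || any(df$sd_d15N < 0, na.rm = TRUE)) {
    iso_abort(sprintf("%s: negative SD", what),
              class = "isoweb_validation_error")
  }
  if (any(df$n < 1)) {
    iso_abort(sprintf("%s: n must be >= 1", what),
              class = "isoweb_validation_error")
  }
  df
}

#' Read a source biomass table
#'
#' Annual average biomass per diet source, in mg C per square metre, used to
#' build the biomass-informed Dirichlet prior.
#'
#' @param path Path to a delimited file with header
#'   `source_name,biomass_mgC_m2`.
#' @return A tibble with columns `source_name`, `biomass`.
#' @export
read_biomass <- function(path) {
  df <- read_delim_chr(path)
  stop_if_missing_cols(df, c("source_name", "biomass_mgC_m2"), "biomass table")
  out <- tibble(
    source_name = df$source_name,
    biomass = parse_decimal(df$biomass_mgC_m2, "biomass_mgC_m2",
                            "biomass table")
  )
  if (any(out$biomass <= 0, na.rm = TRUE)) {
    iso_abort("biomass table: biomass must be > 0",
              class = "isoweb_validation_error")
  }
  out
}

#' Read a binary food-web link matrix with node attributes
#'
#' The link matrix follows the predator-as-column convention: entry
#' (prey row i, predator column j) is 1 iff predator j eats prey i. The
#' first row and first column hold node names. Entries must be exactly 0 or
#' 1 (no coercion). Node attributes are joined by name from a second file.
#'
#' @param matrix_path Path to the n x n 0/1 matrix file (first row/column are
#'   node names).
#' @param attrs_path Path to a delimited file with header
#'   `node,zone,guild,species_richness[,category]`.
#' @return A `foodweb` object: list with `node_names`, `adjacency` (integer
#'   matrix, prey rows x predator columns) and `node_attrs` (tibble).
#' @export
read_foodweb <- function(matrix_path, attrs_path) {
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  node_names <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  attrs <- as_tibble(utils::read.csv(attrs_path, stringsAsFactors = FALSE))
  foodweb(adjacency = m, node_names = node_names,
          col_names = colnames(raw)[-1], node_attrs = attrs)
}

#' Construct and validate a food web
#'
#' @param adjacency n x n matrix of 0/1 links, prey rows x predator columns.
#' @param node_names Character vector of node names (row order).
#' @param col_names Optional column names to check against `node_names`.
#' @param node_attrs Optional tibble of per-node attributes with columns
#'   `node`, `zone`, `guild`, `species_richness` and optionally `category`
#'   (one of basal/herbivore/omnivore/predator).
#' @return A validated `foodweb` object.
#' @export
foodweb <- function(adjacency, node_names = rownames(adjacency),
                    col_names = NULL, node_attrs = NULL) {
  m <- as.matrix(adjacency)
  if (nrow(m) != ncol(m)) {
    iso_abort(sprintf("food-web matrix must be square, got %d x %d",
                      nrow(m), ncol(m)),
              class = "isoweb_shape_error")
  }
  if (is.null(node_names)) node_names <- paste0("node", seq_len(nrow(m)))
  node_names <- as.character(node_names)
  if (length(node_names) != nrow(m) || anyDuplicated(node_names)) {
    iso_abort("node names must be unique and match the matrix dimension",
              class = "isoweb_validation_error")
  }
  if (!is.null(col_names) && !identical(as.character(col_names), node_names)) {
    iso_abort("matrix column names do not match row names",
              class = "isoweb_validation_error")
  }
  vals <- suppressWarnings(as.numeric(m))
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    bad <- vals[!(vals %in% c(0, 1))][1]
    iso_abort(sprintf("food-web matrix entries must be exactly 0 or 1 (found %s)",
                      format(bad)),
              class = "isoweb_validation_error")
  }
  m <- matrix(as.integer(vals), nrow(m), ncol(m),
              dimnames = list(node_names, node_names))
  if (!is.null(node_attrs)) {
    node_attrs <- as_tibble(node_attrs)
    stop_if_missing_cols(node_attrs, c("node"), "node attribute table")
    orphans <- union(setdiff(node_names, node_attrs$node),
                     setdiff(node_attrs$node, node_names))
    if (length(orphans) > 0) {
      iso_abort(sprintf("node attributes do not match matrix nodes: %s",
                        paste(orphans, collapse = ", ")),
                class = "isoweb_join_error")
    }
    node_attrs <- node_attrs[match(node_names, node_attrs$node), ]
    if ("species_richness" %in% names(node_attrs) &&
        any(node_attrs$species_richness < 1, na.rm = TRUE)) {
      iso_abort("species_richness must be >= 1",
                class = "isoweb_validation_error")
    }
  }
  structure(list(node_names = node_names, adjacency = m,
                 node_attrs = node_attrs),
            class = "foodweb")
}

#' @export
print.foodweb <- function(x, ...) {
  cat(sprintf("<foodweb> %d nodes, %d links\n",
              length(x$node_names), sum(x$adjacency)))
  invisible(x)
}

#' Write a food web to matrix + attribute files
#'
#' Inverse of [read_foodweb()]; a write/read round trip reproduces the
#' adjacency matrix exactly.
#'
#' @param web A `foodweb` object.
#' @param matrix_path,attrs_path Output file paths.
#' @return `web`, invisibly.
#' @export
write_foodweb <- function(web, matrix_path, attrs_path) {
  df <- data.frame(node = web$node_names, web$adjacency,
                   check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE)
  attrs <- web$node_attrs %||%
    tibble(node = web$node_names)
  readr::write_csv(attrs, attrs_path)
  invisible(web)
}

#' Summarize individual measurements into per-group source summaries
#'
#' Collapses per-sample isotope measurements to per-group mean and sample
#' standard deviation (n - 1 denominator) per tracer, the "mean +/- SD" form
#' in which sources enter the mixing model. Groups of one sample get SD 0.
#'
#' @param measurements A consumer/measurement tibble (see [read_consumers()]).
#' @param group_by Name of the column defining the grouping (default
#'   `"group"`).
#' @return A source-summary tibble (`name`, `zone`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`, `n`). `zone` is the group's zone when unique
#'   within the group, otherwise `NA`.
#' @export
summarize_sources <- function(measurements, group_by = "group") {
  if (nrow(measurements) == 0) {
    iso_abort("summarize_sources(): no measurements supplied",
              class = "isoweb_empty_input_error")
  }
  stop_if_missing_cols(measurements, c(group_by, "d13C", "d15N"),
                       "measurement table")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  measurements |>
    dplyr::group_by(name = .data[[group_by]]) |>
    dplyr::summarise(
      zone = if ("zone" %in% names(measurements) &&
                 dplyr::n_distinct(.data$zone) == 1) .data$zone[1]
             else NA_character_,
      mean_d13C = mean(.data$d13C), sd_d13C = sd0(.data$d13C),
      mean_d15N = mean(.data$d15N), sd_d15N = sd0(.data$d15N),
      n = dplyr::n(),
      .groups = "drop"
    )
}

# readr-based reader that keeps isotope columns robust to decimal commas:
# everything is read as character and parsed downstream.
read_delim_chr <- function(path) {
  if (!file.exists(path)) {
    iso_abort(sprintf("file not found: %s", path), class = "isoweb_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
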