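#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Allowed lake habitat zones. "profundal" covers benthic-offshore habitats.
ZONES <- c("pelagic", "littoral", "profundal")

iso_abort <- function(message, class, ...) {
  abort(message, class = c(class, "isoweb_error"), ...)
}

stop_if_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    iso_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "isoweb_schema_error"
    )
  }
  invisible(df)
}

# Parse a numeric column that may use a decimal comma; returns numeric vector,
# aborting with the offending row index on failure.
parse_decimal <- function(x, col, what) {
  if (is.numeric(x)) return(as.numeric(x))
  x_chr <- trimws(as.character(x))
  x_norm <- gsub(",", ".", x_chr, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x_norm))
  bad <- which(is.na(out) & !is.na(x_chr) & nzchar(x_chr))
  if (length(bad) > 0) {
    iso_abort(
      sprintf("%s: column '%s' has non-numeric value '%s' at row %d",
              what, col, x_chr[bad[1]], bad[1]),
      class = "isoweb_parse_error"
    )
  }
  out
}

check_zone <- function(zone, what, allow_na = FALSE) {
  ok <- zone %in% ZONES | (allow_na & is.na(zone))
  if (!all(ok)) {
    iso_abort(
      sprintf("%s: unknown zone label '%s' (allowed: %s)",
              what, zone[!ok][1], paste(ZONES, collapse = ", ")),
      class = "isoweb_validation_error"
    )
  }
  invisible(zone)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
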