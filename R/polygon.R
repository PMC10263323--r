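#' Monte-Carlo mixing-polygon validation
#'
#' A mixing model can only explain a consumer that lies inside the convex
#' hull (mixing polygon) of its TDF-corrected sources in tracer space. This
#' test propagates source and TDF uncertainty: at each iterate every source
#' vertex is drawn as Normal(mu_S + mu_TDF, sqrt(sigma_S^2 + sigma_TDF^2))
#' independently per tracer, the convex hull of the drawn vertices is
#' formed, and each consumer is tested for membership (boundary counts as
#' inside). The per-consumer inclusion probability is the fraction of
#' iterates containing it; a consumer passes when its probability is at
#' least 0.05, i.e. it falls inside the 95% mixing region.
#'
#' @param sources Source-summary tibble (>= 3 sources).
#' @param tdf A one-row `tdf` tibble, or a multi-row one with a `zone`
#'   column (as from [calc_tdf_by_zone()]) to apply a zone-specific TDF to
#'   each source.
#' @param consumers Consumer tibble with `sample_id`, `d13C`, `d15N`.
#' @param iterates Number of Monte-Carlo hulls (default 1500).
#' @param seed Integer seed; required.
#' @return A `polygon_result` tibble: `sample_id`, `probability`,
#'   `pass_95`, with attributes `iterates` and `seed`.
#' @export
polygon_test <- function(sources, tdf, consumers, iterates = 1500, seed) {
  if (missing(seed)) {
    iso_abort("polygon_test(): seed is required",
              class = "isoweb_validation_error")
  }
  if (nrow(sources) < 3) {
    iso_abort("polygon_test(): a mixing polygon requires at least 3 sources",
              class = "isoweb_geometry_error")
  }
  if (iterates < 1) {
    iso_abort("polygon_test(): iterates must be >= 1",
              class = "isoweb_validation_error")
  }
  tdf_rows <- match_tdf_rows(sources, tdf)
  muC <- sources$mean_d13C + tdf_rows$mean_dC
  muN <- sources$mean_d15N + tdf_rows$mean_dN
  sC <- sqrt(sources$sd_d13C^2 + tdf_rows$sd_dC^2)
  sN <- sqrt(sources$sd_d15N^2 + tdf_rows$sd_dN^2)
  d <- nrow(sources)
  pts <- cbind(consumers$d13C, consumers$d15N)
  inside <- numeric(nrow(pts))
  set.seed(seed)
  for (it in seq_len(iterates)) {
    vx <- stats::rnorm(d, muC, sC)
    vy <- stats::rnorm(d, muN, sN)
    verts <- cbind(vx, vy)
    inside <- inside + vapply(seq_len(nrow(pts)), function(i) {
      point_in_hull(pts[i, ], verts)
    }, logical(1))
  }
  out <- tibble(
    sample_id = consumers$sample_id %||% paste0("consumer", seq_len(nrow(pts))),
    probability = inside / iterates
  )
  out$pass_95 <- out$probability >= 0.05
  attr(out, "iterates") <- iterates
  attr(out, "seed") <- seed
  class(out) <- c("polygon_result", class(out))
  out
}

#' Point-in-convex-hull test
#'
#' Tests whether a 2-d point lies inside or on the convex hull of a vertex
#' set; points on the boundary count as inside. Collinear (degenerate)
#' vertex sets reduce to a point-on-segment test.
#'
#' @param point Numeric length-2 vector.
#' @param vertices Matrix with >= 3 rows and 2 columns.
#' @param tol Geometric tolerance for boundary membership.
#' @return Logical scalar.
#' @export
point_in_hull <- function(point, vertices, tol = 1e-9) {
  if (is.null(nrow(vertices)) || nrow(vertices) < 3) {
    iso_abort("point_in_hull(): at least 3 vertices required",
              class = "isoweb_geometry_error")
  }
  h <- grDevices::chull(vertices[, 1], vertices[, 2])
  hv <- vertices[h, , drop = FALSE]
  m <- nrow(hv)
  if (m < 3) {
    # degenerate (collinear) hull: point-on-segment test
    a <- hv[1, ]; b <- hv[m, ]
    ab <- b - a; ap <- point - a
    cross <- ab[1] * ap[2] - ab[2] * ap[1]
    if (abs(cross) > tol * max(1, sum(abs(ab)))) return(FALSE)
    t <- if (sum(ab^2) == 0) 0 else sum(ap * ab) / sum(ab^2)
    return(t >= -tol && t <= 1 + tol)
  }
  # orient clockwise (negative signed area), then the point is inside iff
  # it is on the non-positive cross-product side of every directed edge
  nxt <- c(seq_len(m)[-1], 1)
  area2 <- sum(hv[, 1] * hv[nxt, 2] - hv[nxt, 1] * hv[, 2])
  if (area2 > 0) hv <- hv[rev(seq_len(m)), , drop = FALSE]
  for (i in seq_len(m)) {
    a <- hv[i, ]
    b <- hv[if (i == m) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (point[2] - a[2]) -
             (b[2] - a[2]) * (point[1] - a[1])
    if (cross > tol * max(1, abs(b[1] - a[1]) + abs(b[2] - a[2]))) {
      return(FALSE)
    }
  }
  TRUE
}

# Resolve a TDF table against a source set: single-row TDFs apply to every
# source; multi-row TDFs with a zone column are looked up per source zone.
match_tdf_rows <- function(sources, tdf) {
  if (nrow(tdf) == 1) {
    return(tdf[rep(1, nrow(sources)), ])
  }
  if (!"zone" %in% names(tdf)) {
    iso_abort("a multi-row TDF table needs a zone column",
              class = "isoweb_validation_error")
  }
  idx <- match(sources$zone, tdf$zone)
  if (anyNA(idx)) {
    iso_abort(sprintf("no TDF for zone(s): %s",
                      paste(unique(sources$zone[is.na(idx)]), collapse = ", ")),
              class = "isoweb_validation_error")
  }
  tdf[idx, ]
}
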