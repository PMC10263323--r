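# Shared in-code fixtures for the test suite.

# A zero TDF: consumers sit directly on the source mixture.
tdf_zero <- function() {
  tibble::tibble(name = "zero", mean_dC = 0, sd_dC = 0,
                 mean_dN = 0, sd_dN = 0, provenance = "calculated")
}

# Three well-separated sources spanning the tracer plane.
sources_abc <- function(sd = 0.3) {
  tibble::tibble(
    name = c("A", "B", "C"), zone = c("littoral", "pelagic", "pelagic"),
    mean_d13C = c(-10, -20, -25), sd_d13C = sd,
    mean_d15N = c(2, 6, 12), sd_d15N = sd, n = 3
  )
}

# Two symmetric sources around a consumer at the midpoint.
sources_sym <- function() {
  tibble::tibble(
    name = c("A", "B"), zone = "pelagic",
    mean_d13C = c(-10, -20), sd_d13C = 0.5,
    mean_d15N = c(5, 5), sd_d15N = 0.5, n = 3
  )
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent half-plane membership oracle for a convex polygon given in
# counterclockwise order (used to cross-check point_in_hull)
halfplane_inside <- function(pt, verts_ccw, tol = 1e-9) {
  m <- nrow(verts_ccw)
  for (i in seq_len(m)) {
    a <- verts_ccw[i, ]
    b <- verts_ccw[if (i == m) 1 else i + 1, ]
    cr <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    if (cr < -tol) return(FALSE)
  }
  TRUE
}
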