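#' Isometric log-ratio (ILR) transform for diet compositions
#'
#' The mixing model and the synthetic-data generator parameterize diet
#' proportions on unconstrained ILR coordinates. `ilr_basis()` returns a
#' d x (d-1) orthonormal basis of the hyperplane orthogonal to the unit
#' vector (built from Helmert contrasts); `ilr()` maps a composition of d
#' parts to d-1 real coordinates and `ilr_inv()` maps back to the simplex.
#'
#' @param d Number of composition parts (>= 2).
#' @param p Numeric composition vector (positive, any scale; normalized
#'   internally).
#' @param z Numeric ILR coordinate vector of length d-1.
#' @param V Basis matrix from `ilr_basis()`; recomputed when omitted.
#' @return `ilr_basis()`: a d x (d-1) matrix. `ilr()`: a numeric vector of
#'   length d-1. `ilr_inv()`: a composition summing to 1.
#' @examples
#' p <- c(0.7, 0.2, 0.1)
#' z <- ilr(p)
#' ilr_inv(z)  # recovers p
#' @export
ilr_basis <- function(d) {
  stopifnot(d >= 2)
  H <- stats::contr.helmert(d)
  apply(H, 2, function(v) v / sqrt(sum(v^2)))
}

#' @rdname ilr_basis
#' @export
ilr <- function(p, V = ilr_basis(length(p))) {
  if (any(p <= 0)) {
    iso_abort("ilr() requires strictly positive parts",
              class = "isoweb_validation_error")
  }
  p <- p / sum(p)
  as.vector(crossprod(V, log(p)))
}

#' @rdname ilr_basis
#' @export
ilr_inv <- function(z, V = ilr_basis(length(z) + 1L)) {
  e <- exp(as.vector(V %*% z))
  e / sum(e)
}

# log |Jacobian| of z -> p (first d-1 simplex coordinates); needed to express
# a Dirichlet density on ILR coordinates. Verified against numerical
# differentiation: log|J| = sum(log p) + 0.5 * log(d).
ilr_log_jacobian <- function(p) {
  sum(log(p)) + 0.5 * log(length(p))
}
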