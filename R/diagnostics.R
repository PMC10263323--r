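#' Gelman-Rubin convergence diagnostic (split R-hat)
#'
#' Potential scale reduction factor comparing between- and within-chain
#' variance, computed on split chains (each chain halved, doubling the
#' chain count) so that within-chain drift also inflates the statistic.
#' Values below 1.1 are the conventional convergence bar.
#'
#' @param draws Either a chains x iterations x parameters array, a
#'   chains x iterations matrix (single parameter), or a list of equal-length
#'   numeric vectors (one per chain).
#' @return A tibble `parameter`, `rhat`, with attribute `converged`
#'   (all rhat < 1.1). Constant parameters get rhat 1.
#' @export
gelman_rubin <- function(draws) {
  arr <- as_draws_array(draws)
  if (dim(arr)[1] < 2) {
    iso_abort("gelman_rubin(): at least 2 chains are required",
              class = "isoweb_insufficient_chains_error")
  }
  if (dim(arr)[2] < 10) {
    iso_abort("gelman_rubin(): at least 10 draws per chain are required",
              class = "isoweb_validation_error")
  }
  pars <- dimnames(arr)[[3]]
  rhat <- vapply(seq_along(pars), function(i) {
    split_rhat(arr[, , i, drop = TRUE])
  }, numeric(1))
  out <- tibble(parameter = pars, rhat = rhat)
  attr(out, "converged") <- all(out$rhat < 1.1)
  out
}

split_rhat <- function(mat) {
  # mat: chains x iterations; split each chain in half
  n <- ncol(mat)
  half <- n %/% 2
  sub <- rbind(mat[, seq_len(half), drop = FALSE],
               mat[, (n - half + 1):n, drop = FALSE])
  m <- nrow(sub)
  n <- ncol(sub)
  means <- rowMeans(sub)
  vars <- apply(sub, 1, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of a chain against the mean of a
#' late window, scaled by spectral-density-at-zero variance estimates of
#' each window (autoregressive estimator), yielding an asymptotically
#' standard-normal z under stationarity. The conventional windows are the
#' first 10% and the last 50% of the chain; |z| < 1.96 passes.
#'
#' @param draws A numeric vector (single chain), or any input accepted by
#'   [gelman_rubin()] (z is then computed per parameter and chain).
#' @param first_frac,last_frac Window fractions (defaults 0.10 and 0.50);
#'   must sum to at most 1.
#' @return For a vector: a single z value. Otherwise a tibble `parameter`,
#'   `chain`, `z`, `pass` (|z| < 1.96).
#' @export
geweke <- function(draws, first_frac = 0.10, last_frac = 0.50) {
  if (first_frac + last_frac > 1 || first_frac <= 0 || last_frac <= 0) {
    iso_abort("geweke(): window fractions must be positive and sum to <= 1",
              class = "isoweb_parameter_error")
  }
  if (is.numeric(draws) && is.null(dim(draws))) {
    return(geweke_z(draws, first_frac, last_frac))
  }
  arr <- as_draws_array(draws)
  pars <- dimnames(arr)[[3]]
  out <- tidyr::expand_grid(parameter = pars,
                            chain = seq_len(dim(arr)[1]))
  out$z <- purrr::map2_dbl(out$parameter, out$chain, function(p, ch) {
    geweke_z(arr[ch, , p], first_frac, last_frac)
  })
  out$pass <- abs(out$z) < 1.96
  out
}

geweke_z <- function(x, first_frac, last_frac) {
  n <- length(x)
  n1 <- max(1L, floor(first_frac * n))
  n2 <- max(1L, floor(last_frac * n))
  x1 <- x[seq_len(n1)]
  x2 <- x[(n - n2 + 1):n]
  if (length(x1) < 1 || length(x2) < 1) {
    iso_abort("geweke(): chain too short for the requested windows",
              class = "isoweb_parameter_error")
  }
  v1 <- spectrum0_ar(x1)
  v2 <- spectrum0_ar(x2)
  num <- mean(x1) - mean(x2)
  den <- sqrt(v1 / n1 + v2 / n2)
  if (den == 0) return(if (num == 0) 0 else Inf * sign(num))
  num / den
}

# Spectral density at frequency zero via an AIC-selected AR fit; the
# standard long-run variance estimator for MCMC means.
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  ord <- min(length(x) - 1L, floor(10 * log10(length(x))))
  fit <- try(stats::ar(x, aic = TRUE, order.max = ord), silent = TRUE)
  if (inherits(fit, "try-error")) return(stats::var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

# Coerce the accepted draw containers to a chains x iterations x parameters
# array.
as_draws_array <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    if (is.null(dimnames(draws)[[3]])) {
      dimnames(draws)[[3]] <- paste0("par", seq_len(dim(draws)[3]))
    }
    return(draws)
  }
  if (is.matrix(draws)) {
    return(array(draws, c(nrow(draws), ncol(draws), 1),
                 dimnames = list(NULL, NULL, "par1")))
  }
  if (is.list(draws)) {
    lens <- lengths(draws)
    if (length(unique(lens)) != 1) {
      iso_abort("chains must have equal length",
                class = "isoweb_validation_error")
    }
    return(array(do.call(rbind, lapply(draws, as.numeric)),
                 c(length(draws), lens[1], 1),
                 dimnames = list(NULL, NULL, "par1")))
  }
  iso_abort("unsupported draws container", class = "isoweb_validation_error")
}
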