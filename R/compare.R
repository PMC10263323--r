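#' Compare fitted mixing models by PSIS-LOO or WAIC
#'
#' Ranks fitted models on estimated out-of-sample predictive accuracy using
#' either Pareto-smoothed importance-sampling leave-one-out cross-validation
#' (PSIS-LOO) or the widely applicable information criterion (WAIC), both on
#' the deviance scale (lower is better). All models must have been fitted
#' to the identical consumer set. The reported weight is the Akaike-type
#' pseudo-weight w_m proportional to exp(-d_m / 2), where d_m is the
#' model's criterion difference to the best model; weights sum to 1.
#'
#' @param models Named list of `diet_posterior` fits.
#' @param method `"loo"` (default) or `"waic"`.
#' @return A tibble sorted ascending by criterion with columns `model`,
#'   `LOOic`, `se_LOOic`, `dLOOic`, `se_dLOOic`, `weight` (or the `WAIC`
#'   equivalents). The best model's `se_dLOOic` is `NA`. For LOO a
#'   `max_pareto_k` column reports the largest Pareto shape diagnostic.
#' @export
compare_models <- function(models, method = c("loo", "waic")) {
  method <- match.arg(method)
  if (length(models) < 1) {
    iso_abort("compare_models(): at least one model required",
              class = "isoweb_empty_input_error")
  }
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  id_sets <- lapply(models, function(m) m$consumer_ids)
  if (length(unique(lapply(id_sets, sort))) != 1) {
    iso_abort("compare_models(): models were fitted to different consumer sets",
              class = "isoweb_comparison_error")
  }
  ord_ids <- id_sets[[1]]
  pw <- lapply(models, function(m) {
    ll <- pointwise_ll_matrix(m)          # draws x J
    ll <- ll[, ord_ids, drop = FALSE]
    if (method == "loo") elpd_loo_pointwise(ll) else elpd_waic_pointwise(ll)
  })
  J <- length(ord_ids)
  ic <- vapply(pw, function(x) -2 * sum(x$elpd), numeric(1))
  se <- vapply(pw, function(x) 2 * sqrt(J * stats::var(x$elpd)), numeric(1))
  best <- which.min(ic)
  d <- ic - ic[best]
  se_d <- vapply(seq_along(pw), function(m) {
    if (m == best) return(NA_real_)
    diff <- pw[[m]]$elpd - pw[[best]]$elpd
    2 * sqrt(J * stats::var(diff))
  }, numeric(1))
  w <- exp(-0.5 * d)
  w <- w / sum(w)
  out <- tibble(model = names(models), ic = unname(ic), se_ic = unname(se),
                d_ic = unname(d), se_d_ic = unname(se_d),
                weight = unname(w))
  if (method == "loo") {
    out$max_pareto_k <- unname(vapply(pw, function(x) max(x$pareto_k),
                                      numeric(1)))
    names(out)[2:5] <- c("LOOic", "se_LOOic", "dLOOic", "se_dLOOic")
  } else {
    names(out)[2:5] <- c("WAIC", "se_WAIC", "dWAIC", "se_dWAIC")
  }
  out[order(out[[2]]), ]
}

pointwise_ll_matrix <- function(fit) {
  arr <- fit$pointwise_loglik
  matrix(arr, dim(arr)[1] * dim(arr)[2], dim(arr)[3],
         dimnames = list(NULL, dimnames(arr)[[3]]))
}

elpd_waic_pointwise <- function(ll) {
  lppd <- apply(ll, 2, log_mean_exp)
  p_waic <- apply(ll, 2, stats::var)
  list(elpd = lppd - p_waic, pareto_k = rep(NA_real_, ncol(ll)))
}

elpd_loo_pointwise <- function(ll) {
  res <- apply(ll, 2, function(l) {
    ps <- psis_smooth(-l)          # log importance ratios for LOO
    lw <- ps$log_weights
    lw <- lw - log_sum_exp(lw)
    c(elpd = log_sum_exp(lw + l), k = ps$pareto_k)
  })
  list(elpd = res["elpd", ], pareto_k = res["k", ])
}

# Pareto-smoothed importance sampling on a vector of log ratios: fit a
# generalized Pareto distribution to the upper tail and replace the tail
# log-weights by expected order statistics of the fit, truncated at the
# raw maximum.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5 || stats::var(log_ratios) == 0) {
    return(list(log_weights = lw, pareto_k = -Inf))
  }
  ord <- order(lw)
  tail_ids <- ord[(S - tail_len + 1):S]
  cutoff <- lw[ord[S - tail_len]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exc <= 0)) return(list(log_weights = lw, pareto_k = -Inf))
  fit <- gpd_fit(exc)
  q <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(exp(cutoff) + gpd_quantile(q, fit$k, fit$sigma))
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(sort(smoothed), 0)
  list(log_weights = lw, pareto_k = fit$k)
}

# Zhang & Stephens (2009) empirical-Bayes GPD fit (shape k, scale sigma).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  b <- 1 / x[n] +
    (1 - sqrt(m / (seq_len(m) - 0.5))) / (prior_bs * x[ceiling(n / 4 + 0.5)])
  l <- vapply(b, function(bi) {
    k <- -mean(log1p(-bi * x))
    n * (log(bi / k) + k - 1)
  }, numeric(1))
  w <- exp(l - log_sum_exp(l))
  b_hat <- sum(b * w)
  k_zs <- -mean(log1p(-b_hat * x))
  # convert the Zhang-Stephens shape to the usual (Coles) GPD shape xi = -k,
  # the scale on which the Pareto-k diagnostic is read
  list(k = -k_zs, sigma = k_zs / b_hat)
}

gpd_quantile <- function(q, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-q))
  sigma * expm1(-k * log1p(-q)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))
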