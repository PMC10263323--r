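#' Specify a Bayesian two-tracer diet mixing model
#'
#' Bundles the ingredients of the mixing model: TDF-corrected sources, a
#' Dirichlet prior on the global diet proportions, the error structure and
#' the consumer random effect. The likelihood for consumer j and tracer k is
#'
#'   y_jk ~ Normal(mu_jk, s_jk),
#'   mu_jk   = sum_i p_ji (mu_S,ik + mu_TDF,k),
#'   s_jk^2  = xi_k * sum_i p_ji^2 (sigma_S,ik^2 + sigma_TDF,k^2),
#'
#' with global proportions p ~ Dirichlet(alpha) and consumer-level p_j
#' obtained by adding Normal(0, sigma_re) deviations to the isometric
#' log-ratio coordinates of p. The multiplicative error scale xi_k absorbs
#' sampling bias and predation-process variability beyond the propagated
#' source/TDF variance; `error_model = "process_only"` fixes xi_k = 1.
#' There are no covariates or grouping factors beyond the consumer random
#' effect (population structure is deliberately not modelled).
#'
#' @param sources Source-summary tibble (see [read_sources()]).
#' @param tdf One-row `tdf` tibble (see [calc_tdf()] / [tdf_presets()]).
#' @param prior A `dirichlet_prior` over the same sources.
#' @param error_model `"multiplicative"` (default) or `"process_only"`.
#' @param random_effect `"consumer"` (default) or `"none"`.
#' @return A `mixing_model_spec` object.
#' @export
mixing_model_spec <- function(sources, tdf, prior,
                              error_model = c("multiplicative", "process_only"),
                              random_effect = c("consumer", "none")) {
  error_model <- match.arg(error_model)
  random_effect <- match.arg(random_effect)
  if (nrow(sources) < 1) {
    iso_abort("mixing model needs at least one source",
              class = "isoweb_empty_input_error")
  }
  if (nrow(tdf) != 1) {
    iso_abort("mixing model takes a single TDF row",
              class = "isoweb_validation_error")
  }
  if (!setequal(prior$source_name, sources$name)) {
    iso_abort("prior and sources must reference the same source set",
              class = "isoweb_validation_error")
  }
  prior <- prior[match(sources$name, prior$source_name), ]
  structure(list(sources = sources, tdf = tdf, prior = prior,
                 error_model = error_model, random_effect = random_effect,
                 tracers = c("d13C", "d15N")),
            class = "mixing_model_spec")
}

#' Fit the diet mixing model by adaptive random-walk MCMC
#'
#' Samples the posterior of the mixing model with independent adaptive
#' random-walk Metropolis chains on unconstrained coordinates: the ILR
#' transform of the global proportions, per-consumer ILR deviations, log
#' error scales and the log random-effect scale. Proposal scales adapt
#' toward an acceptance rate of 0.3 during burn-in (Robbins-Monro) and are
#' frozen afterwards. Priors: p ~ Dirichlet(alpha); xi_k ~ Uniform(0, 20);
#' sigma_re ~ Half-Normal(1).
#'
#' With a single source the posterior is the degenerate point p = 1 and is
#' returned without sampling.
#'
#' @param spec A `mixing_model_spec`.
#' @param consumers Consumer measurement tibble with `sample_id`, `d13C`,
#'   `d15N`.
#' @param chains Number of independent chains (default 3).
#' @param iterations Total iterations per chain (default 30000).
#' @param burn Burn-in iterations discarded (default 15000).
#' @param thin Keep every `thin`-th post-burn draw (default 10).
#' @param seed Integer seed; required, no silent default.
#' @return A `diet_posterior` object: `draws` (array chain x draw x
#'   parameter), `pointwise_loglik` (chain x draw x consumer), `summary`
#'   and `diagnostics` tibbles, acceptance rates, spec and settings.
#' @export
fit_mixing_model <- function(spec, consumers, chains = 3, iterations = 30000,
                             burn = 15000, thin = 10, seed) {
  if (missing(seed)) {
    iso_abort("fit_mixing_model(): seed is required",
              class = "isoweb_validation_error")
  }
  if (iterations <= burn) {
    iso_abort("iterations must exceed burn",
              class = "isoweb_validation_error")
  }
  for (tr in spec$tracers) {
    if (!tr %in% names(consumers) || anyNA(consumers[[tr]])) {
      iso_abort(sprintf("consumer tracer '%s' missing or incomplete", tr),
                class = "isoweb_validation_error")
    }
  }
  src <- spec$sources
  d <- nrow(src)
  J <- nrow(consumers)
  K <- length(spec$tracers)
  Y <- as.matrix(consumers[, spec$tracers])
  ids <- consumers$sample_id %||% paste0("consumer", seq_len(J))

  muS <- as.matrix(src[, c("mean_d13C", "mean_d15N")])
  sdS <- as.matrix(src[, c("sd_d13C", "sd_d15N")])
  muT <- c(spec$tdf$mean_dC, spec$tdf$mean_dN)
  sdT <- c(spec$tdf$sd_dC, spec$tdf$sd_dN)
  M <- sweep(muS, 2, muT, "+")          # d x K source + TDF means
  S2 <- sweep(sdS^2, 2, sdT^2, "+")     # d x K propagated variances

  if (d == 1) {
    return(degenerate_posterior(spec, Y, ids, M, S2, chains, seed))
  }

  V <- ilr_basis(d)
  alpha <- spec$prior$alpha
  re <- spec$random_effect == "consumer"
  mult <- spec$error_model == "multiplicative"

  Vt <- t(V)
  LOG2PI_HALF <- 0.5 * log(2 * pi)
  # N(y; mu, s2) log-density on variance scale, vectorized
  ldnorm2 <- function(y, mu, s2) -LOG2PI_HALF - 0.5 * log(s2) -
    0.5 * (y - mu)^2 / s2
  log_dirichlet_ilr <- function(p) sum((alpha - 1) * log(p)) +
    ilr_log_jacobian(p)
  # eps prior over all J*(d-1) deviations, as a function of the sum of
  # squares, plus the Half-Normal(1) hyperprior with log-scale Jacobian
  ne <- J * (d - 1)
  lp_eps_fun <- function(ss, sre) -ne * LOG2PI_HALF - ne * log(sre) -
    ss / (2 * sre^2)
  lp_sre_fun <- function(lsre) stats::dnorm(exp(lsre), 0, 1, log = TRUE) +
    log(2) + lsre
  ap <- function(delta) if (is.nan(delta)) 0 else min(1, exp(delta))
  row_quants <- function(zj) {
    e <- exp(as.vector(zj %*% Vt))
    pj <- e / sum(e)
    mu_j <- as.vector(pj %*% M)
    s2b_j <- as.vector(pj^2 %*% S2)
    list(pj = pj, mu = mu_j, s2b = s2b_j)
  }

  n_blocks <- 1L + (if (re) J else 0L) + (if (mult) K else 0L) +
    (if (re) 1L else 0L)
  n_keep <- (iterations - burn) %/% thin
  par_names <- c(paste0("p[", src$name, "]"),
                 if (mult) paste0("xi[", spec$tracers, "]"),
                 if (re) "sigma_re",
                 if (re) as.vector(outer(src$name, ids,
                                         function(s, id) paste0("p_cons[", id, ",", s, "]"))))
  n_store <- length(par_names)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  draws <- array(NA_real_, c(chains, n_keep, n_store),
                 dimnames = list(NULL, NULL, par_names))
  ll_arr <- array(NA_real_, c(chains, n_keep, J),
                  dimnames = list(NULL, NULL, ids))
  acc <- matrix(0, chains, n_blocks)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    z <- ilr(alpha / sum(alpha), V) + stats::rnorm(d - 1, 0, 0.3)
    eps <- if (re) matrix(stats::rnorm(ne, 0, 0.05), J, d - 1) else
      matrix(0, J, d - 1)
    lxi <- if (mult) stats::rnorm(K, 0, 0.1) else rep(0, K)
    lsre <- if (re) log(0.5) + stats::rnorm(1, 0, 0.1) else 0
    xi <- exp(lxi)
    sre <- exp(lsre)
    # caches
    p <- ilr_inv(z, V)
    lp_dir <- log_dirichlet_ilr(p)
    Zj <- sweep(eps, 2, z, "+")
    E <- exp(Zj %*% Vt)
    Pj <- E / rowSums(E)
    mu <- Pj %*% M
    s2b <- Pj^2 %*% S2
    ll <- ldnorm2(Y, mu, sweep(s2b, 2, xi, "*"))
    ss <- sum(eps^2)

    lscale <- rep(log(0.2), n_blocks)
    n_acc <- numeric(n_blocks)
    keep_i <- 0L
    adapt <- function(b, a, it) {
      if (it <= burn) lscale[b] <<- lscale[b] + (a - 0.3) / it^0.6
    }
    for (it in seq_len(iterations)) {
      b <- 1L
      # --- global ILR coordinates ---
      z_p <- z + exp(lscale[b]) * stats::rnorm(d - 1)
      p_p <- ilr_inv(z_p, V)
      lp_dir_p <- log_dirichlet_ilr(p_p)
      Zj_p <- sweep(eps, 2, z_p, "+")
      E_p <- exp(Zj_p %*% Vt)
      Pj_p <- E_p / rowSums(E_p)
      mu_p <- Pj_p %*% M
      s2b_p <- Pj_p^2 %*% S2
      ll_p <- ldnorm2(Y, mu_p, sweep(s2b_p, 2, xi, "*"))
      a <- ap(lp_dir_p + sum(ll_p) - lp_dir - sum(ll))
      if (stats::runif(1) < a) {
        z <- z_p; p <- p_p; lp_dir <- lp_dir_p
        Pj <- Pj_p; mu <- mu_p; s2b <- s2b_p; ll <- ll_p
        n_acc[b] <- n_acc[b] + 1
      }
      adapt(b, a, it)
      # --- per-consumer ILR deviations ---
      if (re) {
        inv_2s2 <- 1 / (2 * sre^2)
        for (j in seq_len(J)) {
          b <- b + 1L
          ej <- eps[j, ] + exp(lscale[b]) * stats::rnorm(d - 1)
          q <- row_quants(z + ej)
          ll_j <- ldnorm2(Y[j, ], q$mu, xi * q$s2b)
          d_ss <- sum(ej^2) - sum(eps[j, ]^2)
          a <- ap(sum(ll_j) - sum(ll[j, ]) - d_ss * inv_2s2)
          if (stats::runif(1) < a) {
            eps[j, ] <- ej; Pj[j, ] <- q$pj; mu[j, ] <- q$mu
            s2b[j, ] <- q$s2b; ll[j, ] <- ll_j
            ss <- ss + d_ss
            n_acc[b] <- n_acc[b] + 1
          }
          adapt(b, a, it)
        }
      }
      # --- multiplicative error scales (log) ---
      if (mult) {
        for (k in seq_len(K)) {
          b <- b + 1L
          lxk <- lxi[k] + exp(lscale[b]) * stats::rnorm(1)
          xk <- exp(lxk)
          if (xk < 20) {
            ll_k <- ldnorm2(Y[, k], mu[, k], xk * s2b[, k])
            a <- ap(sum(ll_k) - sum(ll[, k]) + lxk - lxi[k])
          } else {
            a <- 0
          }
          if (stats::runif(1) < a) {
            lxi[k] <- lxk; xi[k] <- xk; ll[, k] <- ll_k
            n_acc[b] <- n_acc[b] + 1
          }
          adapt(b, a, it)
        }
      }
      # --- random-effect scale (log) ---
      if (re) {
        b <- b + 1L
        lsre_p <- lsre + exp(lscale[b]) * stats::rnorm(1)
        sre_p <- exp(lsre_p)
        a <- ap(lp_eps_fun(ss, sre_p) + lp_sre_fun(lsre_p) -
                  lp_eps_fun(ss, sre) - lp_sre_fun(lsre))
        if (stats::runif(1) < a) {
          lsre <- lsre_p; sre <- sre_p
          n_acc[b] <- n_acc[b] + 1
        }
        adapt(b, a, it)
      }
      if (it > burn && (it - burn) %% thin == 0) {
        keep_i <- keep_i + 1L
        draws[ch, keep_i, ] <- c(p,
                                 if (mult) xi,
                                 if (re) sre,
                                 if (re) as.vector(t(Pj)))
        ll_arr[ch, keep_i, ] <- rowSums(ll)
      }
    }
    acc[ch, ] <- n_acc / iterations
  }

  new_diet_posterior(spec, draws, ll_arr, ids, chains, iterations, burn, thin,
                     seed, acc)
}

degenerate_posterior <- function(spec, Y, ids, M, S2, chains, seed) {
  J <- nrow(Y)
  draws <- array(1, c(chains, 1, 1),
                 dimnames = list(NULL, NULL, paste0("p[", spec$sources$name, "]")))
  ll <- stats::dnorm(Y, matrix(M, J, ncol(Y), byrow = TRUE),
                     matrix(sqrt(S2), J, ncol(Y), byrow = TRUE), log = TRUE)
  ll_arr <- array(rep(rowSums(ll), each = chains), c(chains, 1, J),
                  dimnames = list(NULL, NULL, ids))
  new_diet_posterior(spec, draws, ll_arr, ids, chains, 1, 0, 1, seed,
                     matrix(1, chains, 1), degenerate = TRUE)
}

new_diet_posterior <- function(spec, draws, ll_arr, ids, chains, iterations,
                               burn, thin, seed, acc, degenerate = FALSE) {
  smry <- summarize_draws(draws)
  prim <- grep("^p\\[|^xi\\[|^sigma_re$", dimnames(draws)[[3]], value = TRUE)
  diag <- if (!degenerate && chains >= 2 && dim(draws)[2] >= 10) {
    gr <- gelman_rubin(draws[, , prim, drop = FALSE])
    gw <- geweke(draws[, , prim, drop = FALSE]) |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(geweke_z = .data$z[which.max(abs(.data$z))],
                       .groups = "drop")
    dplyr::left_join(gr, gw, by = "parameter")
  } else {
    tibble(parameter = prim, rhat = NA_real_, geweke_z = NA_real_)
  }
  structure(list(
    draws = draws, pointwise_loglik = ll_arr, summary = smry,
    diagnostics = diag, consumer_ids = ids, spec = spec,
    settings = list(chains = chains, iterations = iterations, burn = burn,
                    thin = thin, seed = seed),
    accept_rates = acc, degenerate = degenerate
  ), class = "diet_posterior")
}

summarize_draws <- function(draws) {
  pars <- dimnames(draws)[[3]]
  purrr::map_dfr(seq_along(pars), function(i) {
    x <- as.vector(draws[, , i])
    q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
    tibble(parameter = pars[i], mean = mean(x), sd = stats::sd(x),
           q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4], q97.5 = q[5])
  })
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("<diet_posterior> %d sources, %d consumers, %d chains x %d kept draws\n",
              nrow(x$spec$sources), length(x$consumer_ids),
              dim(x$draws)[1], dim(x$draws)[2]))
  p_rows <- grepl("^p\\[", x$summary$parameter)
  print(x$summary[p_rows, c("parameter", "mean", "sd", "q2.5", "q97.5")])
  invisible(x)
}

#' Posterior mean diet proportions
#'
#' @param fit A `diet_posterior`.
#' @return Named numeric vector of posterior mean global proportions,
#'   summing to 1.
#' @export
diet_proportions <- function(fit) {
  nm <- paste0("p[", fit$spec$sources$name, "]")
  stats::setNames(
    vapply(nm, function(p) mean(fit$draws[, , p]), numeric(1)),
    fit$spec$sources$name
  )
}

#' Write posterior draws to a long delimited file
#'
#' One row per (chain, draw, parameter): `chain,iteration,parameter,value`.
#'
#' @param fit A `diet_posterior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  dn <- dimnames(fit$draws)[[3]]
  long <- tidyr::expand_grid(chain = seq_len(dim(fit$draws)[1]),
                             iteration = seq_len(dim(fit$draws)[2]),
                             parameter = dn)
  long$value <- as.vector(aperm(fit$draws, c(3, 2, 1)))
  readr::write_csv(long, path)
  invisible(path)
}
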