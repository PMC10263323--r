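#' Container for simulation ground truth
#'
#' Bundles the parameters from which a synthetic mixing dataset is
#' generated, so recovery tests can compare posterior estimates against
#' known values.
#'
#' @param true_p Numeric simplex vector of true global diet proportions
#'   (normalized internally).
#' @param tdf One-row `tdf` tibble.
#' @param xi Length-2 multiplicative error scales (d13C, d15N), > 0.
#' @param sigma_re Consumer random-effect scale on ILR coordinates, >= 0.
#' @param n_consumers Number of consumers to simulate.
#' @param seed Integer seed.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(true_p, tdf, xi = c(1, 1), sigma_re = 0.1,
                             n_consumers = 30, seed) {
  if (missing(seed)) {
    iso_abort("simulation_truth(): seed is required",
              class = "isoweb_validation_error")
  }
  if (any(true_p <= 0)) {
    iso_abort("true_p must be strictly positive",
              class = "isoweb_validation_error")
  }
  if (any(xi <= 0)) {
    iso_abort("xi must be > 0", class = "isoweb_validation_error")
  }
  structure(list(true_p = true_p / sum(true_p), tdf = tdf, xi = xi,
                 sigma_re = sigma_re, n_consumers = n_consumers, seed = seed),
            class = "simulation_truth")
}

#' Generate a synthetic consumer dataset from the mixing model
#'
#' Draws consumers from exactly the generative process the mixing model
#' assumes: per consumer, ILR-space deviations Normal(0, sigma_re) perturb
#' the true global proportions; tracer values are then drawn from
#' Normal(sum_i p_ji (mu_S + mu_TDF), sqrt(xi_k sum_i p_ji^2 (sigma_S^2 +
#' sigma_TDF^2))). Deterministic for a fixed seed.
#'
#' @param truth A `simulation_truth`.
#' @param sources Source-summary tibble; row count must match
#'   `length(truth$true_p)`.
#' @return A consumer tibble (`sample_id`, `lake`, `zone`, `taxon`,
#'   `group`, `d13C`, `d15N`) with attribute `provenance` recording the
#'   truth parameters and seed.
#' @export
gen_mixing_dataset <- function(truth, sources) {
  d <- nrow(sources)
  if (length(truth$true_p) != d) {
    iso_abort("true_p length must equal the number of sources",
              class = "isoweb_shape_error")
  }
  muT <- c(truth$tdf$mean_dC, truth$tdf$mean_dN)
  sdT <- c(truth$tdf$sd_dC, truth$tdf$sd_dN)
  M <- sweep(as.matrix(sources[, c("mean_d13C", "mean_d15N")]), 2, muT, "+")
  S2 <- sweep(as.matrix(sources[, c("sd_d13C", "sd_d15N")])^2, 2, sdT^2, "+")
  J <- truth$n_consumers
  V <- ilr_basis(max(d, 2))
  set.seed(truth$seed)
  z0 <- if (d >= 2) ilr(truth$true_p, V) else numeric(0)
  Y <- matrix(NA_real_, J, 2)
  for (j in seq_len(J)) {
    pj <- if (d >= 2) {
      ilr_inv(z0 + stats::rnorm(d - 1, 0, truth$sigma_re), V)
    } else {
      1
    }
    mu <- as.vector(pj %*% M)
    s <- sqrt(truth$xi * as.vector(pj^2 %*% S2))
    Y[j, ] <- stats::rnorm(2, mu, s)
  }
  out <- tibble(
    sample_id = sprintf("sim%03d", seq_len(J)),
    lake = "synthetic", zone = "pelagic", taxon = "synthetic consumer",
    group = "consumer", d13C = Y[, 1], d15N = Y[, 2]
  )
  attr(out, "provenance") <- truth
  out
}

#' Generate a random food web with known node categories
#'
#' Builds a 0/1 link matrix whose nodes obey the category rules by
#' construction: herbivores eat only basal nodes, omnivores eat at least
#' one basal and one herbivore node (two distinct prey levels), predators
#' eat only herbivores. After the mandatory links, random admissible links
#' are added to approach the target directed connectance C = L/N^2;
#' realized C lands within 20% of the target whenever the admissible link
#' range allows, otherwise a feasibility error is raised.
#'
#' @param n_basal,n_herb,n_omn,n_pred Node counts per category.
#' @param connectance_target Target directed connectance.
#' @param zones Zone labels sampled uniformly per node (default
#'   littoral/pelagic).
#' @param seed Integer seed.
#' @return A `foodweb` with node attributes `zone`, `guild`
#'   (= generating category), `species_richness = 1`.
#' @export
gen_foodweb <- function(n_basal, n_herb, n_omn = 0, n_pred = 0,
                        connectance_target = 0.06,
                        zones = c("littoral", "pelagic"), seed) {
  if (missing(seed)) {
    iso_abort("gen_foodweb(): seed is required",
              class = "isoweb_validation_error")
  }
  n_cons <- n_herb + n_omn + n_pred
  if (n_cons > 0 && n_basal < 1) {
    iso_abort("consumers require at least one basal node",
              class = "isoweb_validation_error")
  }
  if ((n_omn > 0 || n_pred > 0) && n_herb < 1) {
    iso_abort("omnivores and predators require at least one herbivore",
              class = "isoweb_feasibility_error")
  }
  N <- n_basal + n_cons
  cats <- rep(c("basal", "herbivore", "omnivore", "predator"),
              c(n_basal, n_herb, n_omn, n_pred))
  names_ <- paste0(substr(cats, 1, 1), stats::ave(seq_len(N), cats,
                                                  FUN = seq_along))
  i_b <- which(cats == "basal")
  i_h <- which(cats == "herbivore")
  i_o <- which(cats == "omnivore")
  i_p <- which(cats == "predator")
  # admissible prey sets per consumer
  allowed <- vector("list", N)
  for (j in i_h) allowed[[j]] <- i_b
  for (j in i_o) allowed[[j]] <- c(i_b, i_h)
  for (j in i_p) allowed[[j]] <- i_h
  L_min <- n_herb + 2 * n_omn + n_pred
  L_max <- sum(lengths(allowed))
  L_target <- round(connectance_target * N^2)
  L_use <- min(max(L_target, L_min), L_max)
  if (L_target > 0 && abs(L_use - L_target) / L_target > 0.2) {
    iso_abort(sprintf("target connectance %.3f infeasible: admissible links allow C in [%.3f, %.3f]",
                      connectance_target, L_min / N^2, L_max / N^2),
              class = "isoweb_feasibility_error")
  }
  set.seed(seed)
  adj <- matrix(0L, N, N)
  pick <- function(x, k) if (length(x) == 1) rep(x, k) else sample(x, k)
  for (j in i_h) adj[pick(i_b, 1), j] <- 1L
  for (j in i_o) {
    adj[pick(i_b, 1), j] <- 1L
    adj[pick(i_h, 1), j] <- 1L
  }
  for (j in i_p) adj[pick(i_h, 1), j] <- 1L
  # grow toward the target with random admissible links
  free <- do.call(rbind, lapply(seq_len(N), function(j) {
    pr <- setdiff(allowed[[j]], which(adj[, j] == 1L))
    if (length(pr) == 0) NULL else cbind(pr, j)
  }))
  need <- L_use - sum(adj)
  if (need > 0 && !is.null(free)) {
    take <- free[sample.int(nrow(free), min(need, nrow(free))), , drop = FALSE]
    adj[take] <- 1L
  }
  attrs <- tibble(
    node = names_,
    zone = sample(zones, N, replace = TRUE),
    guild = cats,
    species_richness = 1L
  )
  foodweb(adjacency = adj, node_names = names_, node_attrs = attrs)
}

#' Reference isotope table for the two study lakes
#'
#' The packaged per-group stable-isotope summaries (mean +/- SD, permil)
#' for the 14 El Sol groups and 6 La Luna groups, with habitat-zone labels.
#' Sample counts per group were not published; the fixture carries a
#' nominal n = 3 for schema completeness.
#'
#' @return A tibble `lake`, `name`, `zone`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`, `n`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_isotopes.csv", package = "isoweb")
  readr::read_csv(path, col_types = "cccddddi", progress = FALSE)
}

#' The six candidate diet sources of the introduced rainbow trout
#'
#' Filters the reference table to the El Sol mixing-model source set: three
#' oligochaetes, the gastropod, and the two zooplankton species.
#'
#' @return A source-summary tibble of six rows.
#' @export
trout_diet_sources <- function() {
  tab <- table1_fixture()
  keep <- c("Lumbriculus variegatus", "Tubifex tubifex",
            "Limnodrilus hoffmeisteri", "Physa sp.",
            "Daphnia ambigua", "Leptodiaptomus cuauhtemoci")
  out <- tab[tab$lake == "El Sol" & tab$name %in% keep, ]
  out[match(keep, out$name), setdiff(names(out), "lake")]
}

#' Simulate individual consumers from a summary row
#'
#' Draws per-individual tracer values from Normal(mean, SD) per tracer,
#' e.g. to reconstruct plausible individual fish from a published
#' mean +/- SD.
#'
#' @param summary_row One-row tibble with `name`, `zone`, `mean_d13C`,
#'   `sd_d13C`, `mean_d15N`, `sd_d15N`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return A consumer tibble.
#' @export
simulate_consumers <- function(summary_row, n, seed) {
  set.seed(seed)
  tibble(
    sample_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", summary_row$name), seq_len(n)),
    lake = if ("lake" %in% names(summary_row)) summary_row$lake else NA_character_,
    zone = summary_row$zone,
    taxon = summary_row$name,
    group = summary_row$name,
    d13C = stats::rnorm(n, summary_row$mean_d13C, summary_row$sd_d13C),
    d15N = stats::rnorm(n, summary_row$mean_d15N, summary_row$sd_d15N)
  )
}

#' Synthetic source biomass table
#'
#' Draws per-source annual biomasses log-uniformly over two orders of
#' magnitude (default 10..1000 mg C m^-2), mimicking the right-skew of
#' real benthic/zooplankton biomass spectra. Purely synthetic: the field
#' biomasses behind the biomass prior were not published.
#'
#' @param source_names Character vector.
#' @param seed Integer seed.
#' @param range Biomass range (mg C m^-2).
#' @return A tibble `source_name`, `biomass`.
#' @export
gen_biomass <- function(source_names, seed, range = c(10, 1000)) {
  set.seed(seed)
  tibble(
    source_name = source_names,
    biomass = exp(stats::runif(length(source_names),
                               log(range[1]), log(range[2])))
  )
}
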