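#' Classify food-web nodes into trophic categories
#'
#' Assigns each node an integer trophic level (basal = 1, consumer = 1 +
#' max level of its prey) and a category:
#' * basal: no prey;
#' * herbivore: preys only on basal nodes;
#' * omnivore: preys on nodes at two or more distinct integer levels
#'   (including mixing basal and animal prey);
#' * predator: preys on animal (non-basal) nodes only, all at one level.
#'
#' Cannibalistic self-links make a node non-basal. Cycles among non-basal
#' nodes prevent the longest-path level assignment; those nodes fall back
#' to shortest-path-to-basal + 1, with a warning. An explicit `category`
#' column in the node attributes overrides the inferred category.
#'
#' @param web A `foodweb` object.
#' @return A tibble `node`, `level`, `category`.
#' @export
classify_nodes <- function(web) {
  adj <- web$adjacency
  n <- nrow(adj)
  prey_of <- lapply(seq_len(n), function(j) which(adj[, j] == 1))
  basal <- lengths(prey_of) == 0
  level <- ifelse(basal, 1L, NA_integer_)
  # longest-path levels by iterative relaxation; stalls indicate a cycle
  repeat {
    changed <- FALSE
    for (j in which(is.na(level))) {
      pl <- level[prey_of[[j]]]
      if (!anyNA(pl)) {
        level[j] <- 1L + max(pl)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(level)) {
    warn("cycle detected among non-basal nodes; falling back to shortest-path-to-basal + 1 for the nodes involved")
    sp <- shortest_path_levels(prey_of, basal)
    level[is.na(level)] <- sp[is.na(level)]
  }
  category <- vapply(seq_len(n), function(j) {
    prey <- prey_of[[j]]
    if (length(prey) == 0) return("basal")
    lv <- unique(level[prey])
    if (length(lv) >= 2) return("omnivore")
    if (all(basal[prey])) return("herbivore")
    "predator"
  }, character(1))
  out <- tibble(node = web$node_names, level = as.integer(level),
                category = category)
  if (!is.null(web$node_attrs) && "category" %in% names(web$node_attrs)) {
    given <- web$node_attrs$category
    override <- !is.na(given) & nzchar(given)
    out$category[override] <- given[override]
  }
  out
}

shortest_path_levels <- function(prey_of, basal) {
  n <- length(prey_of)
  lvl <- ifelse(basal, 1L, NA_integer_)
  frontier <- which(basal)
  dist <- 1L
  while (length(frontier) > 0 && anyNA(lvl)) {
    dist <- dist + 1L
    nxt <- which(is.na(lvl) &
                   vapply(prey_of, function(p) any(p %in% frontier), logical(1)))
    lvl[nxt] <- dist
    frontier <- nxt
  }
  lvl
}

#' Number of occupied integer trophic levels
#'
#' @param web A `foodweb` object.
#' @return Integer count of distinct levels (basal = 1, consumer = 1 + max
#'   prey level).
#' @export
trophic_level_count <- function(web) {
  length(unique(classify_nodes(web)$level))
}

#' Food-web topology metrics
#'
#' Computes the standard binary food-web descriptors from the 0/1 link
#' matrix (predator columns, prey rows): link count L, node count N,
#' species richness S (per-node richness summed, since one node may
#' aggregate several species), linkage densities D1 = L/S and D2 = L/N,
#' potential links Lp = N^2, directed connectance C = L/N^2, the fractions
#' of basal/herbivore/omnivore/predator nodes, guild node counts, the
#' number of occupied trophic levels, and the littoral/pelagic/coupling
#' decomposition of links by endpoint zones (both endpoints littoral ->
#' littoral link; both pelagic -> pelagic; mixed -> coupling).
#'
#' @param web A `foodweb` object. Node attributes supply
#'   `species_richness` (required for S and D1), `zone` (for sub-network
#'   links; omitted with a warning when missing) and `guild` (for node
#'   counts).
#' @return A `web_metrics` list with elements `S`, `N`, `L`, `D1`, `D2`,
#'   `Lp`, `C`, `fractions`, `counts`, `trophic_levels`, `sublinks`,
#'   `nodes` (the classification tibble).
#' @export
compute_metrics <- function(web) {
  adj <- web$adjacency
  N <- nrow(adj)
  L <- sum(adj)
  attrs <- web$node_attrs
  S <- if (!is.null(attrs) && "species_richness" %in% names(attrs) &&
           !anyNA(attrs$species_richness)) {
    sum(attrs$species_richness)
  } else {
    iso_abort("species richness unavailable: node attributes must provide species_richness",
              class = "isoweb_missing_data_error")
  }
  cls <- classify_nodes(web)
  frac <- prop.table(table(factor(cls$category,
                                  levels = c("basal", "herbivore",
                                             "omnivore", "predator"))))
  counts <- if (!is.null(attrs) && "guild" %in% names(attrs)) {
    as.list(table(attrs$guild))
  } else {
    list()
  }
  sublinks <- NULL
  if (!is.null(attrs) && "zone" %in% names(attrs) && !anyNA(attrs$zone)) {
    zone <- attrs$zone
    idx <- which(adj == 1, arr.ind = TRUE)
    ztype <- ifelse(zone[idx[, 1]] == "littoral" & zone[idx[, 2]] == "littoral",
                    "littoral",
             ifelse(zone[idx[, 1]] == "pelagic" & zone[idx[, 2]] == "pelagic",
                    "pelagic", "coupling"))
    sublinks <- list(
      littoral = sum(ztype == "littoral"),
      pelagic = sum(ztype == "pelagic"),
      coupling = sum(ztype == "coupling")
    )
  } else {
    warn("node zones missing; sub-network link decomposition omitted")
  }
  structure(list(
    S = S, N = N, L = L,
    D1 = L / S, D2 = L / N, Lp = N^2, C = L / N^2,
    fractions = as.list(frac),
    counts = counts,
    trophic_levels = length(unique(cls$level)),
    sublinks = sublinks,
    nodes = cls
  ), class = "web_metrics")
}

#' Derived topology metrics from printed counts
#'
#' Computes the cells of a food-web summary table that are pure arithmetic
#' on the headline counts: D1 = L/S, D2 = L/N, Lp = N^2, C = L/N^2. Useful
#' for checking a published table's internal consistency without the link
#' matrix.
#'
#' @param S Species richness.
#' @param N Node count.
#' @param L Link count.
#' @return A one-row tibble `S`, `N`, `L`, `D1`, `D2`, `Lp`, `C`.
#' @export
web_metrics_from_counts <- function(S, N, L) {
  tibble(S = S, N = N, L = L, D1 = L / S, D2 = L / N, Lp = N^2, C = L / N^2)
}

#' @export
print.web_metrics <- function(x, ...) {
  cat(sprintf("<web_metrics> N=%d L=%d S=%d  D1=%.3f D2=%.3f C=%.4f Lp=%d  levels=%d\n",
              x$N, x$L, x$S, x$D1, x$D2, x$C, x$Lp, x$trophic_levels))
  if (!is.null(x$sublinks)) {
    cat(sprintf("  sublinks: littoral %d, pelagic %d, coupling %d\n",
                x$sublinks$littoral, x$sublinks$pelagic, x$sublinks$coupling))
  }
  invisible(x)
}

#' Serialize web metrics to JSON
#'
#' @param metrics A `web_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  m <- unclass(metrics)
  m$nodes <- NULL
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
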