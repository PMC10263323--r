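chain_web <- function() {
  adj <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  adj["a", "b"] <- 1L  # b eats a
  adj["b", "c"] <- 1L  # c eats b
  foodweb(adj, node_attrs = tibble::tibble(
    node = c("a", "b", "c"), zone = "littoral", guild = c("algae", "bmi", "fish"),
    species_richness = 1L))
}

test_that("a three-node chain yields the hand-counted metrics", {
  m <- compute_metrics(chain_web())
  expect_equal(m$S, 3)
  expect_equal(m$N, 3)
  expect_equal(m$L, 2)
  expect_equal(m$C, 2 / 9)
  expect_equal(m$D2, 2 / 3)
  expect_equal(m$Lp, 9)
  expect_equal(m$fractions$basal, 1 / 3)
  expect_equal(m$trophic_levels, 3)
})

test_that("an empty web has no links and zero connectance", {
  adj <- matrix(0L, 2, 2)
  web <- foodweb(adj, node_names = c("x", "y"),
                 node_attrs = tibble::tibble(node = c("x", "y"),
                                             zone = "pelagic", guild = "algae",
                                             species_richness = 2L))
  m <- compute_metrics(web)
  expect_equal(m$L, 0)
  expect_equal(m$C, 0)
  expect_equal(m$fractions$basal, 1)
  expect_equal(m$trophic_levels, 1)
})

test_that("node classification follows the prey-level rules", {
  # alga <- herb1, alga <- herb2, herb1 <- pred, alga+herb1 <- omn
  nodes <- c("alga", "herb1", "herb2", "pred", "omn")
  adj <- matrix(0L, 5, 5, dimnames = list(nodes, nodes))
  adj["alga", "herb1"] <- 1L
  adj["alga", "herb2"] <- 1L
  adj["herb1", "pred"] <- 1L
  adj["alga", "omn"] <- 1L
  adj["herb1", "omn"] <- 1L
  cls <- classify_nodes(foodweb(adj))
  expect_equal(cls$category,
               c("basal", "herbivore", "herbivore", "predator", "omnivore"))
  expect_equal(cls$level, c(1L, 2L, 2L, 3L, 3L))
  expect_equal(trophic_level_count(foodweb(adj)), 3)

  # a cannibalistic self-link makes a node non-basal
  solo <- matrix(1L, 1, 1, dimnames = list("x", "x"))
  expect_warning(cls_solo <- classify_nodes(foodweb(solo)))
  expect_false(cls_solo$category == "basal")

  # explicit category attributes override inference
  attrs <- tibble::tibble(node = nodes, zone = "littoral", guild = "g",
                          species_richness = 1L,
                          category = c(NA, NA, NA, "omnivore", NA))
  cls2 <- classify_nodes(foodweb(adj, node_attrs = attrs))
  expect_equal(cls2$category[4], "omnivore")
})

test_that("cycles fall back to shortest-path levels with a warning", {
  nodes <- c("alga", "u", "v")
  adj <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  adj["alga", "u"] <- 1L
  adj["u", "v"] <- 1L
  adj["v", "u"] <- 1L  # u <-> v cycle
  expect_warning(cls <- classify_nodes(foodweb(adj)), regexp = "cycle")
  expect_equal(cls$level[1], 1L)
  expect_equal(cls$level[2], 2L)  # shortest path to basal + 1
})

test_that("L and C match exhaustive counting over all 3-node webs", {
  attrs <- tibble::tibble(node = c("a", "b", "c"), zone = "littoral",
                          guild = "g", species_richness = 1L)
  for (code in 0:511) {
    bits <- as.integer(intToBits(code)[1:9])
    adj <- matrix(bits, 3, 3, dimnames = list(c("a", "b", "c"),
                                              c("a", "b", "c")))
    web <- foodweb(adj, node_attrs = attrs)
    m <- suppressWarnings(compute_metrics(web))
    expect_equal(m$L, sum(bits))
    expect_equal(m$C, sum(bits) / 9)
    expect_equal(m$Lp, 9)
  }
})

test_that("metrics are invariant under node permutation", {
  set.seed(61)
  web <- gen_foodweb(4, 4, 2, 1, connectance_target = 0.1, seed = 62)
  m1 <- compute_metrics(web)
  perm <- sample(length(web$node_names))
  web2 <- foodweb(web$adjacency[perm, perm],
                  node_names = web$node_names[perm],
                  node_attrs = web$node_attrs[perm, ])
  m2 <- compute_metrics(web2)
  expect_equal(m1$L, m2$L)
  expect_equal(m1$C, m2$C)
  expect_equal(m1$fractions, m2$fractions)
  expect_equal(m1$trophic_levels, m2$trophic_levels)
  expect_equal(m1$sublinks, m2$sublinks)
})

test_that("sub-network links decompose by endpoint zones and sum to L", {
  nodes <- c("la", "lb", "pa", "pb")
  adj <- matrix(0L, 4, 4, dimnames = list(nodes, nodes))
  adj["la", "lb"] <- 1L  # littoral-littoral
  adj["pa", "pb"] <- 1L  # pelagic-pelagic
  adj["la", "pb"] <- 1L  # coupling
  adj["pa", "lb"] <- 1L  # coupling
  web <- foodweb(adj, node_attrs = tibble::tibble(
    node = nodes, zone = c("littoral", "littoral", "pelagic", "pelagic"),
    guild = "g", species_richness = 1L))
  m <- compute_metrics(web)
  expect_equal(m$sublinks, list(littoral = 1L, pelagic = 1L, coupling = 2L))
  expect_equal(with(m$sublinks, littoral + pelagic + coupling), m$L)

  # consistency identities
  expect_equal(m$C * m$N^2, m$L)
  expect_equal(m$D2 * m$N, m$L)
})

test_that("missing attributes degrade gracefully", {
  adj <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  web_no_rich <- foodweb(adj, node_attrs = tibble::tibble(
    node = c("a", "b"), zone = "littoral", guild = "g"))
  expect_error(compute_metrics(web_no_rich),
               class = "isoweb_missing_data_error")
  web_no_zone <- foodweb(adj, node_attrs = tibble::tibble(
    node = c("a", "b"), guild = "g", species_richness = 1L))
  expect_warning(m <- compute_metrics(web_no_zone), regexp = "zone")
  expect_null(m$sublinks)
})

test_that("derived table cells follow from the headline counts", {
  m <- web_metrics_from_counts(S = 261, N = 42, L = 99)
  expect_equal(m$D1, 99 / 261)
  expect_equal(m$D2, 99 / 42)
  expect_equal(m$Lp, 1764)
  expect_equal(m$C, 99 / 1764)
})
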