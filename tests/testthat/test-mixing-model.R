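test_that("a single source forces a degenerate posterior without sampling", {
  src <- sources_abc()[1, ]
  pr <- isoweb:::new_prior(src$name, 1, "uniform")
  spec <- mixing_model_spec(src, tdf_zero(), pr)
  cons <- tibble::tibble(sample_id = "c1", d13C = -10, d15N = 2)
  fit <- fit_mixing_model(spec, cons, chains = 2, seed = 1)
  expect_true(fit$degenerate)
  expect_equal(unname(diet_proportions(fit)), 1)
})

test_that("a midpoint consumer between two symmetric sources splits 50/50", {
  spec <- mixing_model_spec(sources_sym(), tdf_zero(),
                            uniform_prior(c("A", "B")))
  cons <- tibble::tibble(sample_id = "c1", d13C = -15, d15N = 5)
  fit <- fit_mixing_model(spec, cons, chains = 2, iterations = 3000,
                          burn = 1500, thin = 5, seed = 42)
  p <- diet_proportions(fit)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 0.06)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("every retained draw satisfies the simplex constraint", {
  src <- sources_abc()
  spec <- mixing_model_spec(src, tdf_zero(), uniform_prior(src$name))
  cons <- tibble::tibble(sample_id = c("c1", "c2"),
                         d13C = c(-15, -18), d15N = c(5, 7))
  fit <- fit_mixing_model(spec, cons, chains = 2, iterations = 600,
                          burn = 300, thin = 2, seed = 7)
  pn <- paste0("p[", src$name, "]")
  psum <- apply(fit$draws[, , pn, drop = FALSE], c(1, 2), sum)
  expect_true(all(abs(psum - 1) < 1e-9))
  for (id in c("c1", "c2")) {
    cn <- paste0("p_cons[", id, ",", src$name, "]")
    csum <- apply(fit$draws[, , cn, drop = FALSE], c(1, 2), sum)
    expect_true(all(abs(csum - 1) < 1e-9))
  }
  expect_true(all(fit$draws[, , grep("^xi", dimnames(fit$draws)[[3]])] > 0))
})

test_that("fits are reproducible for a seed and differ across seeds", {
  src <- sources_sym()
  spec <- mixing_model_spec(src, tdf_zero(), uniform_prior(src$name))
  cons <- tibble::tibble(sample_id = "c1", d13C = -14, d15N = 5)
  f1 <- fit_mixing_model(spec, cons, chains = 2, iterations = 400,
                         burn = 200, thin = 2, seed = 9)
  f2 <- fit_mixing_model(spec, cons, chains = 2, iterations = 400,
                         burn = 200, thin = 2, seed = 9)
  f3 <- fit_mixing_model(spec, cons, chains = 2, iterations = 400,
                         burn = 200, thin = 2, seed = 10)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior is invariant to source relabeling within MC error", {
  src <- sources_abc()
  cons <- tibble::tibble(sample_id = paste0("c", 1:5),
                         d13C = c(-15, -16, -14, -15.5, -15.2),
                         d15N = c(5, 5.5, 4.8, 5.2, 5.1))
  fit1 <- fit_mixing_model(
    mixing_model_spec(src, tdf_zero(), uniform_prior(src$name)),
    cons, chains = 2, iterations = 3000, burn = 1500, thin = 5, seed = 3)
  perm <- src[c(3, 1, 2), ]
  fit2 <- fit_mixing_model(
    mixing_model_spec(perm, tdf_zero(), uniform_prior(perm$name)),
    cons, chains = 2, iterations = 3000, burn = 1500, thin = 5, seed = 4)
  p1 <- diet_proportions(fit1)
  p2 <- diet_proportions(fit2)
  expect_lt(max(abs(p1[c("A", "B", "C")] - p2[c("A", "B", "C")])), 0.08)
})

test_that("a consumer pinned at one source concentrates the posterior there", {
  src <- sources_abc(sd = 0.05)
  spec <- mixing_model_spec(src, tdf_zero(), uniform_prior(src$name),
                            error_model = "process_only",
                            random_effect = "none")
  cons <- tibble::tibble(sample_id = "c1", d13C = -10, d15N = 2)  # = source A
  fit <- fit_mixing_model(spec, cons, chains = 2, iterations = 4000,
                          burn = 2000, thin = 5, seed = 12)
  expect_gt(diet_proportions(fit)[["A"]], 0.9)
})

test_that("the posterior recovers known proportions from synthetic data", {
  src <- sources_abc()
  truth <- simulation_truth(c(0.7, 0.2, 0.1), tdf_zero(), xi = c(1, 1),
                            sigma_re = 0.1, n_consumers = 30, seed = 77)
  dat <- gen_mixing_dataset(truth, src)
  fit <- fit_mixing_model(
    mixing_model_spec(src, tdf_zero(), uniform_prior(src$name)),
    dat, chains = 2, iterations = 4000, burn = 2000, thin = 5, seed = 78)
  td <- tidy(fit)
  expect_equal(td$estimate, c(0.7, 0.2, 0.1), tolerance = 0.1)
  covered <- td$conf.low <= c(0.7, 0.2, 0.1) &
    c(0.7, 0.2, 0.1) <= td$conf.high
  expect_gte(sum(covered), 2)
})

test_that("tidy and glance expose the expected fit summaries", {
  src <- sources_sym()
  spec <- mixing_model_spec(src, tdf_zero(), uniform_prior(src$name))
  cons <- tibble::tibble(sample_id = "c1", d13C = -15, d15N = 5)
  fit <- fit_mixing_model(spec, cons, chains = 2, iterations = 600,
                          burn = 300, thin = 2, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high", "rhat"))
  expect_equal(td$term, c("p[A]", "p[B]"))
  full <- tidy(fit, pars = "primary")
  expect_true("sigma_re" %in% full$term)
  g <- glance(fit)
  expect_equal(g$n_sources, 2L)
  expect_equal(g$chains, 2)
  expect_true(is.logical(g$converged))
})

test_that("missing consumer tracers and bad chain settings are rejected", {
  src <- sources_sym()
  spec <- mixing_model_spec(src, tdf_zero(), uniform_prior(src$name))
  expect_error(
    fit_mixing_model(spec, tibble::tibble(sample_id = "c", d13C = -15),
                     chains = 2, seed = 1),
    class = "isoweb_validation_error"
  )
  cons <- tibble::tibble(sample_id = "c1", d13C = -15, d15N = 5)
  expect_error(
    fit_mixing_model(spec, cons, iterations = 100, burn = 100, seed = 1),
    class = "isoweb_validation_error"
  )
  expect_error(fit_mixing_model(spec, cons), class = "isoweb_validation_error")
  expect_error(
    mixing_model_spec(src, tdf_zero(), uniform_prior(c("X", "Y"))),
    class = "isoweb_validation_error"
  )
})
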