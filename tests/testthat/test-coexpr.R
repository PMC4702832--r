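test_that("sample-size filter rejects small datasets before correlation", {
  set.seed(2)
  mk <- function(n) {
    expression_dataset(matrix(rnorm(20L * n), nrow = 20L,
                              dimnames = list(sprintf("g%02d", 1:20),
                                              NULL)),
                       id = paste0("ds", n))
  }
  expect_null(correlate(mk(11L)))
  expect_s3_class(correlate(mk(12L)), "evidence_layer")

  verdict <- evaluate_dataset(NULL, fx_small_gs(), id = "ds11")
  expect_false(verdict$passed_size)
  expect_false(verdict$retained)
  expect_true(is.na(verdict$best_bin_lls))
})

test_that("correlation layer has the expected algebraic structure", {
  base <- rnorm(12)
  m <- rbind(a = base, b = base, c = -base, d = rnorm(12),
             e = rep(1, 12))
  ds <- expression_dataset(m, id = "toy")
  layer <- correlate(ds, min_samples = 12L)
  w <- setNames(layer$score, pair_key(layer$geneA, layer$geneB))
  expect_equal(unname(w[pair_key("a", "b")]), 1.0)
  expect_equal(unname(w[pair_key("a", "c")]), -1.0)
  expect_true(all(abs(layer$score) <= 1 + 1e-12))
  # constant gene excluded and reported
  expect_false("e" %in% c(layer$geneA, layer$geneB))
  expect_equal(attr(layer, "dropped_constant"), 1L)
})

test_that("planted modules are recovered among the top correlations", {
  world <- make_world(k = 5L, m = 10L, n_background = 50L, rho = 0.8,
                      seed = 4)
  ds <- sim_expression(world, n_samples = 20L, id = "rec", stream = 90L)
  layer <- correlate(ds, min_samples = 12L, top_n = 120L)
  keys <- llsnet:::world_module_pairs(world)
  ord <- order(-layer$score)
  top <- pair_key(layer$geneA[ord], layer$geneB[ord])[seq_along(keys)]
  expect_gte(mean(keys %in% top), 0.9)
})

test_that("dataset retention tracks gold-standard signal, not size alone", {
  world <- fx_world()
  gs <- fx_build()$gold_standard
  ds <- sim_expression(world, n_samples = 20L, id = "sig", stream = 21L)
  layer <- correlate(ds, min_samples = 12L)
  verdict <- evaluate_dataset(layer, gs, retain_threshold = 0.5)
  expect_true(verdict$retained)
  expect_gt(verdict$best_bin_lls, 0.5)

  # destroying the label-score relationship kills retention:
  # shuffle universe gene labels within the gold standard
  set.seed(21)
  retained <- replicate(50, {
    perm <- setNames(sample(gs$universe), gs$universe)
    gs_perm <- gs
    gs_perm$positives <- vapply(
      strsplit(gs$positives, "\t", fixed = TRUE),
      function(p) paste(sort(c(perm[[p[1L]]], perm[[p[2L]]])),
                        collapse = "\t"),
      character(1L))
    evaluate_dataset(layer, gs_perm, retain_threshold = 0.5)$retained
  })
  expect_lte(mean(retained), 0.1)

  # raising the threshold never retains a previously rejected dataset
  thresholds <- c(0.1, 0.5, 1, 2, 5, 10)
  kept <- vapply(thresholds, function(th) {
    evaluate_dataset(layer, gs, retain_threshold = th)$retained
  }, logical(1L))
  expect_true(all(diff(as.integer(kept)) <= 0L))
})

test_that("co-expression integration follows the weighted-sum closed form", {
  n1 <- weighted_network(c("a", "c"), c("b", "d"), c(2.0, 1.5), name = "x")
  n2 <- weighted_network("a", "b", 1.0, name = "y")
  # single network: identity
  single <- integrate_coexpression(list(n1), D = 2)
  expect_equal(network_edge_weights(single), network_edge_weights(n1))
  # shared pair: WS closed form 2.0 + 1.0/2
  both <- integrate_coexpression(list(n1, n2), D = 2)
  w <- network_edge_weights(both)
  expect_equal(unname(w[pair_key("a", "b")]), 2.5)
  # disjoint edge passes through unchanged
  expect_equal(unname(w[pair_key("c", "d")]), 1.5)
  expect_error(integrate_coexpression(list()), "no co-expression")
})
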