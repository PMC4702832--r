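test_that("precision-coverage points count evaluable edges correctly", {
  ref <- reference_pair_set(rbind(c("a", "b"), c("a", "c"), c("b", "d")),
                            c("a", "b", "c", "d"))
  # network made exactly of the reference positives: precision 1 everywhere
  net_pos <- weighted_network(c("a", "a", "b"), c("b", "c", "d"),
                              c(3, 2, 1))
  pts <- precision_coverage_curve(net_pos, ref, genome_size = 4L,
                                  n_points = 3L)
  expect_true(all(pts$precision == 1))
  expect_equal(max(pts$genome_coverage), 1.0)

  # toy: 4 ranked evaluable edges, positives at ranks 1, 2, 4
  net_toy <- weighted_network(c("a", "a", "c", "b"),
                              c("b", "c", "d", "d"),
                              c(4, 3, 2, 1))
  pts_toy <- precision_coverage_curve(net_toy, ref, genome_size = 4L,
                                      n_points = 4L)
  expect_equal(pts_toy$precision[pts_toy$rank_cutoff == 4L], 0.75)
  # full-depth precision closed form
  expect_equal(pts_toy$precision[nrow(pts_toy)], 3 / 4)

  # edges with unannotated endpoints are not evaluable but still count
  # toward coverage
  net_mix <- weighted_network(c("a", "x"), c("b", "y"), c(2, 1))
  pts_mix <- precision_coverage_curve(net_mix, ref, genome_size = 10L,
                                      n_points = 2L)
  expect_equal(pts_mix$precision, c(1, 1))
  expect_equal(pts_mix$genome_coverage, c(0.2, 0.4))
})

test_that("connectivity AUC is exact on hand-checkable topologies", {
  # clique disconnected from the rest: perfect separation
  clique <- combn(c("m1", "m2", "m3", "m4"), 2L)
  net <- weighted_network(c(clique[1L, ], "x", "y"),
                          c(clique[2L, ], "y", "z"),
                          c(rep(2, ncol(clique)), 1, 1))
  expect_equal(set_connectivity_auc(net, c("m1", "m2", "m3", "m4")), 1.0)

  # 5-node toy agrees with exhaustive comparison counting
  toy <- weighted_network(c("a", "a", "b", "c"), c("b", "c", "d", "e"),
                          c(3, 1, 2, 1))
  expect_equal(set_connectivity_auc(toy, c("a", "b")),
               oracle_auc(toy, c("a", "b")))

  expect_error(set_connectivity_auc(toy, c("a", "zz")), "fewer than 2")
})

test_that("rank-sum AUC equals exhaustive pair counting on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n_nodes <- sample(10:200, 1L)
    net <- random_network(n_nodes, n_nodes * 2L, seed = 1000L + i)
    nodes <- network_nodes(net)
    gene_set <- sample(nodes, sample(2:min(8L, length(nodes) - 1L), 1L))
    expect_equal(set_connectivity_auc(net, gene_set),
                 oracle_auc(net, gene_set), tolerance = 1e-12)
  }
})

test_that("network randomization preserves the claimed invariants", {
  net <- random_network(40L, 120L, seed = 18)
  sh <- randomize_network(net, "label_shuffle", seed = 5)
  expect_equal(nrow(sh), nrow(net))
  expect_equal(sort(sh$weight), sort(net$weight))
  # weighted degree multiset is preserved by relabeling
  wdeg <- function(n) {
    sort(unname(tapply(c(n$weight, n$weight), c(n$geneA, n$geneB), sum)))
  }
  expect_equal(wdeg(sh), wdeg(net))
  # determinism
  expect_identical(randomize_network(net, "label_shuffle", seed = 5), sh)

  dp <- randomize_network(net, "degree_preserving", seed = 5)
  expect_equal(nrow(dp), nrow(net))
  expect_equal(sort(dp$weight), sort(net$weight))
  # per-node endpoint counts (unweighted degree sequence) preserved
  deg <- function(n) sort(table(c(n$geneA, n$geneB)))
  expect_equal(as.vector(deg(dp)), as.vector(deg(net)))
  expect_false(identical(network_edge_weights(dp),
                         network_edge_weights(net)))
})

test_that("planted gene sets beat their randomized nulls by Wilcoxon", {
  world <- fx_world()
  net <- fx_build()$network
  sets <- sim_gene_sets(world, 50L)
  rep <- auc_null_comparison(net, sets, n_null = 3L, seed = 2)
  expect_true(rep$reliable)
  expect_lt(rep$p_value, 0.01)
  expect_gt(mean(rep$per_set$auc), mean(rep$per_set$null_mean))

  # a single usable set is flagged unreliable
  one <- auc_null_comparison(net, sets[1L], n_null = 2L, seed = 2)
  expect_false(one$reliable)
})

test_that("a fully randomized network is calibrated against its own nulls", {
  base <- random_network(80L, 240L, seed = 19)
  set.seed(20)
  nodes <- network_nodes(base)
  ps <- replicate(20, {
    sets <- lapply(1:10, function(i) sample(nodes, 5L))
    rnet <- randomize_network(base, seed = sample.int(1e6, 1L))
    auc_null_comparison(rnet, sets, n_null = 3L,
                        seed = sample.int(1e6, 1L))$p_value
  })
  expect_gte(mean(ps > 0.01), 0.9)
})
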