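test_that("co-inheritance MI behaves like mutual information", {
  set.seed(6)
  genomes <- sprintf("g%03d", 1:200)
  domains <- setNames(rep("bacteria", 200), genomes)
  v <- rbinom(200, 1L, 0.5)
  m <- rbind(a = v, b = v, c = rep(1, 200), d = rbinom(200, 1L, 0.5))
  colnames(m) <- genomes
  p <- phylo_profile(m, domains)

  # MI(X, X) = H(X)
  freq <- mean(v)
  h <- -freq * log(freq) - (1 - freq) * log(1 - freq)
  expect_equal(profile_similarity(p, "a", "b", "bacteria"), h)
  expect_gt(profile_similarity(p, "a", "b", "bacteria"), 0)
  # constant profile: zero entropy, zero MI
  expect_equal(profile_similarity(p, "a", "c", "bacteria"), 0)
  # symmetry
  expect_equal(profile_similarity(p, "a", "d", "bacteria"),
               profile_similarity(p, "d", "a", "bacteria"))
  expect_error(profile_similarity(p, "a", "zz", "bacteria"), "absent")
})

test_that("independent random profiles have near-zero MI", {
  set.seed(8)
  mis <- replicate(100, {
    x <- rbinom(200, 1L, 0.5)
    y <- rbinom(200, 1L, 0.5)
    m <- rbind(a = x, b = y)
    colnames(m) <- sprintf("g%03d", 1:200)
    p <- phylo_profile(m, setNames(rep("d1", 200), colnames(m)))
    profile_similarity(p, "a", "b", "d1", n_bins = 2L)
  })
  expect_true(all(mis >= 0))
  expect_lt(mean(mis), 0.05)
})

test_that("genes with a planted shared pattern outrank background by MI", {
  set.seed(9)
  hits <- replicate(50, {
    pattern <- rbinom(100, 1L, 0.5)
    flip <- function(v, p = 0.1) {
      f <- rbinom(length(v), 1L, p) == 1L
      v[f] <- 1L - v[f]
      v
    }
    m <- rbind(p1 = flip(pattern), p2 = flip(pattern),
               b1 = rbinom(100, 1L, 0.5), b2 = rbinom(100, 1L, 0.5))
    colnames(m) <- sprintf("g%03d", 1:100)
    p <- phylo_profile(m, setNames(rep("d1", 100), colnames(m)))
    profile_similarity(p, "p1", "p2", "d1") >
      profile_similarity(p, "b1", "b2", "d1")
  })
  expect_gte(mean(hits), 0.95)
})

test_that("profile layer takes the best within-domain LLS", {
  world <- fx_world()
  gs <- fx_build()$gold_standard
  prof <- sim_profiles(world)

  lay <- profile_layer(prof, gs, n_bins = 2L)
  # restricting to one domain must reproduce that domain's LLS; the
  # two-domain layer score is the max, hence >= the bacterial score
  bac_cols <- names(prof$domains)[prof$domains == "bacteria"]
  prof_bac <- phylo_profile(prof$matrix[, bac_cols],
                            prof$domains[bac_cols])
  lay_bac <- profile_layer(prof_bac, gs, n_bins = 2L)
  shared <- intersect(pair_key(lay$geneA, lay$geneB),
                      pair_key(lay_bac$geneA, lay_bac$geneB))
  s_all <- setNames(lay$score, pair_key(lay$geneA, lay$geneB))[shared]
  s_bac <- setNames(lay_bac$score,
                    pair_key(lay_bac$geneA, lay_bac$geneB))[shared]
  expect_true(all(s_all >= s_bac - 1e-9))

  # genes present in fewer than 2 genomes are excluded
  m2 <- prof$matrix
  m2["B0001", ] <- 0
  m2["B0001", 1L] <- 1
  lay2 <- profile_layer(phylo_profile(m2, prof$domains), gs)
  expect_false("B0001" %in% c(lay2$geneA, lay2$geneB))
})

test_that("neighborhood measures follow the closed-form definitions", {
  # adjacent orthologs in 10 genomes of 1000 genes
  genomes <- sprintf("G%02d", 1:10)
  pos <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome = g, gene = sprintf("%s_p%03d", g, 1:1000),
               chrom = "c1", index = 0:999)
  }))
  t <- gene_position_table(pos)
  orth <- rbind(
    data.frame(gene = "a", genome = genomes,
               ortholog = sprintf("%s_p%03d", genomes, 1)),
    data.frame(gene = "b", genome = genomes,
               ortholog = sprintf("%s_p%03d", genomes, 2)),
    data.frame(gene = "x", genome = genomes[1L],
               ortholog = sprintf("%s_p%03d", genomes[1L], 500)))
  layers <- neighborhood_scores(t, data.frame(a = c("a", "a"),
                                              b = c("b", "x")), orth)
  wd <- setNames(layers$dist_layer$score,
                 pair_key(layers$dist_layer$geneA, layers$dist_layer$geneB))
  wp <- setNames(layers$prob_layer$score,
                 pair_key(layers$prob_layer$geneA, layers$prob_layer$geneB))
  expect_equal(unname(wd[pair_key("a", "b")]), 1.0)
  expect_equal(unname(wp[pair_key("a", "b")]), -10 * log(2 / 999))
  # a-x qualifies in one genome at distance 499 on the circle
  expect_equal(unname(wd[pair_key("a", "x")]), 1 / 499)

  # orthologs always on different chromosomes: pair excluded
  pos2 <- data.frame(genome = "G1", gene = c("o1", "o2", "o3", "o4"),
                     chrom = c("c1", "c2", "c1", "c1"), index = c(0, 0, 1, 2))
  t2 <- gene_position_table(pos2)
  orth2 <- data.frame(gene = c("a", "b"), genome = "G1",
                      ortholog = c("o1", "o2"))
  l2 <- neighborhood_scores(t2, data.frame(a = "a", b = "b"), orth2)
  expect_equal(nrow(l2$dist_layer), 0L)

  # maximal circular distance on an odd chromosome is uninformative
  m <- 7L
  pos3 <- data.frame(genome = "G1", gene = sprintf("o%d", 1:m),
                     chrom = "c1", index = 0:(m - 1L))
  orth3 <- data.frame(gene = c("a", "b"), genome = "G1",
                      ortholog = c("o1", sprintf("o%d", (m - 1L) / 2 + 1L)))
  l3 <- neighborhood_scores(gene_position_table(pos3),
                            data.frame(a = "a", b = "b"), orth3)
  expect_equal(l3$prob_layer$score, 0)

  # chromosomes with fewer than 3 genes are skipped
  pos4 <- data.frame(genome = "G1", gene = c("o1", "o2"), chrom = "c1",
                     index = 0:1)
  l4 <- neighborhood_scores(gene_position_table(pos4),
                            data.frame(a = "a", b = "b"),
                            data.frame(gene = c("a", "b"), genome = "G1",
                                       ortholog = c("o1", "o2")))
  expect_equal(nrow(l4$prob_layer), 0L)
})

test_that("combined context network follows the weighted-sum rule", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  set.seed(10)
  # distance scores informative, probability scores random
  d_score <- ifelse(tab$label == "positive", runif(nrow(tab), 0.8, 1),
                    runif(nrow(tab), 0, 0.4))
  dist_layer <- evidence_layer(tab$geneA, tab$geneB, d_score,
                               name = "GN-dist")
  prob_layer <- evidence_layer(tab$geneA, tab$geneB,
                               runif(nrow(tab), 0, 50), name = "GN-prob")
  net <- context_layer(dist_layer, prob_layer, gs, D = 1,
                       min_lls = -Inf, n_bins = 5L)
  expect_s3_class(net, "weighted_network")
  expect_gt(nrow(net), 0L)

  # manual cross-check of the per-pair combination on one pair
  m_d <- benchmark_layer(dist_layer, gs, n_bins = 5L)
  m_p <- benchmark_layer(prob_layer, gs, n_bins = 5L)
  n_d <- apply_mapping(dist_layer, m_d, min_lls = -Inf)
  n_p <- apply_mapping(prob_layer, m_p, min_lls = -Inf)
  wd <- network_edge_weights(n_d)
  wp <- network_edge_weights(n_p)
  wc <- network_edge_weights(net)
  key <- names(wc)[1L]
  expect_equal(unname(wc[key]),
               weighted_sum(c(wd[key], wp[key]), D = 1))
  expect_error(context_layer(evidence_layer(character(), character(),
                                            numeric()),
                             evidence_layer(character(), character(),
                                            numeric()), gs),
               "empty")
})
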