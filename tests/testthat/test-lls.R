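test_that("log-likelihood score formula matches direct arithmetic", {
  expect_equal(lls_of_counts(10, 10, 100, 100, 0), 0)
  expect_equal(lls_of_counts(40, 10, 100, 400, 0), log(16))
  expect_equal(lls_of_counts(0, 10, 100, 100, 0.5), log(0.5 / 10.5))
  # invariant under rescaling both totals
  expect_equal(lls_of_counts(40, 10, 100, 400, 0),
               lls_of_counts(40, 10, 1000, 4000, 0))
  expect_error(lls_of_counts(0, 10, 100, 100, 0), "pseudocount")
})

test_that("benchmarking separates planted signal with the right sign", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  score <- ifelse(tab$label == "positive", 1.0, 0.0)
  layer <- evidence_layer(tab$geneA, tab$geneB, score)
  m <- benchmark_layer(layer, gs, n_bins = 2L, isotonic = FALSE)
  expect_gt(m$bin_lls[2L], 0)
  expect_lt(m$bin_lls[1L], 0)
  expect_gt(m$bin_lls[2L], m$bin_lls[1L])
})

test_that("scores independent of labels give near-zero LLS in every bin", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  set.seed(7)
  layer <- evidence_layer(tab$geneA, tab$geneB, runif(nrow(tab)))
  m <- benchmark_layer(layer, gs, n_bins = 5L, pseudocount = 0.5,
                       isotonic = FALSE, prior = "layer")
  se <- sqrt(1 / (m$pos + 0.5) + 1 / (m$neg + 0.5))
  expect_true(all(abs(m$bin_lls) <= 3 * se))
})

test_that("a single bin covering all labelled pairs reproduces the prior", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  layer <- evidence_layer(tab$geneA, tab$geneB, runif(nrow(tab)))
  for (prior in c("gold_standard", "layer")) {
    m <- benchmark_layer(layer, gs, n_bins = 1L, pseudocount = 0,
                         isotonic = FALSE, prior = prior)
    expect_equal(m$bin_lls, 0)
  }
})

test_that("bin counts and LLS match naive enumeration exactly", {
  gs <- fx_build()$gold_standard
  set.seed(11)
  tab <- export_gold_standard(gs)
  idx <- sample(nrow(tab), 800L)
  layer <- evidence_layer(tab$geneA[idx], tab$geneB[idx],
                          rnorm(length(idx)))
  for (nb in c(2L, 5L, 10L)) {
    m <- benchmark_layer(layer, gs, n_bins = nb, pseudocount = 0.5,
                         isotonic = FALSE)
    o <- oracle_bin_lls(layer, gs, m$bin_edges, 0.5)
    expect_identical(m$pos, o$pos)
    expect_identical(m$neg, o$neg)
    expect_equal(m$bin_lls, o$lls)
  }
})

test_that("isotonic smoothing yields monotone LLS along the raw score", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  set.seed(3)
  noisy <- ifelse(tab$label == "positive", rnorm(nrow(tab), 1),
                  rnorm(nrow(tab), 0))
  layer <- evidence_layer(tab$geneA, tab$geneB, noisy)
  m <- benchmark_layer(layer, gs, n_bins = 10L, isotonic = TRUE)
  expect_true(all(diff(m$bin_lls) >= -1e-12))
})

test_that("permuting gold-standard labels drives bin LLS toward zero", {
  gs <- fx_small_gs()
  tab <- export_gold_standard(gs)
  set.seed(5)
  score <- ifelse(tab$label == "positive", 1, 0) + rnorm(nrow(tab),
                                                         sd = 0.3)
  layer <- evidence_layer(tab$geneA, tab$geneB, score)
  observed <- mean(abs(benchmark_layer(layer, gs, n_bins = 5L,
                                       isotonic = FALSE)$bin_lls))
  set.seed(13)
  shuffled <- replicate(30, {
    perm <- setNames(sample(gs$universe), gs$universe)
    gs_perm <- gs
    gs_perm$positives <- pair_keys <- vapply(
      strsplit(gs$positives, "\t", fixed = TRUE),
      function(p) paste(sort(c(perm[[p[1L]]], perm[[p[2L]]])),
                        collapse = "\t"),
      character(1L))
    mean(abs(benchmark_layer(layer, gs_perm, n_bins = 5L,
                             isotonic = FALSE)$bin_lls))
  })
  expect_gt(observed, mean(shuffled))
})

test_that("mapping application thresholds, looks up and round-trips", {
  mk_mapping <- function(edges, lls) {
    structure(list(bin_edges = edges, bin_lls = lls,
                   pos = rep(1L, length(lls)), neg = rep(1L, length(lls)),
                   prior_odds = 0.1, pos_total = 10L, neg_total = 100L,
                   empty_bins = integer(), higher_is_stronger = TRUE,
                   name = "toy"),
              class = "lls_mapping")
  }
  m <- mk_mapping(c(-Inf, 0, 1, Inf), c(-1, 0.5, 2.5))
  layer <- evidence_layer(c("a", "c"), c("b", "d"), c(5, 5))
  net <- apply_mapping(layer, m, min_lls = 1)
  expect_equal(net$weight, c(2.5, 2.5))

  # below-threshold bin is dropped
  layer_mid <- evidence_layer("a", "b", 0.4)
  expect_warning(net0 <- apply_mapping(layer_mid, m, min_lls = 1),
                 "min_lls")
  expect_equal(nrow(net0), 0L)

  # all edges in the middle bin take that bin's LLS
  layer_all <- evidence_layer(c("a", "b", "c"), c("x", "y", "z"),
                              c(0.2, 0.5, 0.9))
  net_mid <- apply_mapping(layer_all, m, min_lls = -Inf)
  expect_equal(net_mid$weight, rep(0.5, 3L))

  # identity-style re-application preserves weights
  ident <- mk_mapping(c(-Inf, 0.75, Inf), c(0.25, 2.5))
  relayer <- evidence_layer(net$geneA, net$geneB, net$weight)
  expect_equal(sort(apply_mapping(relayer, ident, min_lls = -Inf)$weight),
               sort(net$weight))

  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m, path)
  m2 <- read_mapping(path)
  expect_equal(m2$bin_edges, m$bin_edges)
  expect_equal(m2$bin_lls, m$bin_lls)
  expect_equal(m2$higher_is_stronger, TRUE)
})
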