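# Shared fixtures: one default planted world, its emitted inputs and one
# full build, computed once per test run.  Everything is deterministic
# (world seed 1), so tests asserting on the build are reproducible.

fixture_env <- new.env(parent = emptyenv())

fx_world <- function() {
  if (is.null(fixture_env$world)) {
    fixture_env$world <- make_world(seed = 1)
  }
  fixture_env$world
}

fx_paths <- function() {
  if (is.null(fixture_env$paths)) {
    dir <- file.path(tempdir(), "llsnet-fixture-world")
    fixture_env$paths <- emit_inputs(fx_world(), dir)
  }
  fixture_env$paths
}

fx_build <- function() {
  if (is.null(fixture_env$build)) {
    fixture_env$build <- suppressMessages(run_build(fx_paths()$config))
  }
  fixture_env$build
}

# A small gold standard used by unit tests: 4 disjoint terms of 5 genes.
fx_small_gs <- function() {
  genes <- sprintf("g%02d", 1:20)
  recs <- data.frame(gene = genes,
                     term = rep(paste0("T", 1:4), each = 5L),
                     evidence_code = "IDA")
  build_gold_standard(parse_annotations(recs))
}

# Independent oracle for benchmark_layer: naive per-pair enumeration of
# bin counts and direct evaluation of the LLS formula, given bin edges.
oracle_bin_lls <- function(layer, gs, edges, pseudocount,
                           prior = "gold_standard") {
  lab <- label_pair(gs, layer$geneA, layer$geneB)
  keep <- lab != "unknown"
  score <- layer$score[keep]
  lab <- lab[keep]
  if (prior == "gold_standard") {
    pos_total <- length(gs$positives)
    neg_total <- choose(length(gs$universe), 2) - pos_total
  } else {
    pos_total <- sum(lab == "positive")
    neg_total <- sum(lab == "negative")
  }
  nb <- length(edges) - 1L
  pos <- integer(nb)
  neg <- integer(nb)
  for (i in seq_along(score)) {
    b <- NA_integer_
    for (k in seq_len(nb)) {
      lo <- edges[k]
      hi <- edges[k + 1L]
      inside <- if (k == nb) score[i] >= lo && score[i] <= hi
                else score[i] >= lo && score[i] < hi
      if (inside) { b <- k; break }
    }
    if (is.na(b)) b <- if (score[i] < edges[1L]) 1L else nb
    if (lab[i] == "positive") pos[b] <- pos[b] + 1L else neg[b] <- neg[b] + 1L
  }
  lls <- log(((pos + pseudocount) / (neg + pseudocount)) /
               (pos_total / neg_total))
  list(pos = pos, neg = neg, lls = lls)
}

# Independent oracle for set_connectivity_auc: scores accumulated by a
# plain scan over the edge list, AUC by exhaustive comparison counting
# over all (held-out member, non-member) pairs, ties as 1/2.
oracle_auc <- function(net, gene_set) {
  nodes <- network_nodes(net)
  mapped <- nodes[nodes %in% gene_set]
  negatives <- nodes[!nodes %in% gene_set]
  score_against <- function(set) {
    s <- setNames(numeric(length(nodes)), nodes)
    for (e in seq_len(nrow(net))) {
      if (net$geneB[e] %in% set) {
        s[net$geneA[e]] <- s[net$geneA[e]] + net$weight[e]
      }
      if (net$geneA[e] %in% set) {
        s[net$geneB[e]] <- s[net$geneB[e]] + net$weight[e]
      }
    }
    s
  }
  per_member <- vapply(mapped, function(g) {
    s <- score_against(setdiff(mapped, g))
    sn <- s[negatives]
    (sum(sn < s[g]) + 0.5 * sum(sn == s[g])) / length(sn)
  }, numeric(1))
  mean(per_member)
}

# Random small weighted network for property tests.
random_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  a <- sample(nodes, n_edges * 2L, replace = TRUE)
  b <- sample(nodes, n_edges * 2L, replace = TRUE)
  keep <- a != b
  # weights on a dyadic grid so connectivity sums are exact regardless of
  # accumulation order (keeps tie handling comparable across code paths)
  weighted_network(a[keep], b[keep], sample(1:20, sum(keep),
                                            replace = TRUE) / 4,
                   name = "random")
}
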