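test_that("pathway-centric search ranks the best-connected candidate first", {
  # star: hub connected to all three query genes, others to none
  net <- weighted_network(c("hub", "hub", "hub", "o1"),
                          c("q1", "q2", "q3", "o2"),
                          c(1, 1, 1, 0.5))
  res <- find_new_members(net, c("q1", "q2", "q3"))
  expect_equal(res$ranked_items$item[1L], "hub")
  expect_equal(res$ranked_items$rank, seq_len(nrow(res$ranked_items)))
  expect_true(all(diff(res$ranked_items$score) <= 0))
  expect_error(find_new_members(net, c("q1", "zz")), "zz")

  # additivity: adding a query gene never lowers a candidate's score
  res2 <- find_new_members(net, c("q1", "q2"))
  s1 <- setNames(res2$ranked_items$score, res2$ranked_items$item)
  res3 <- find_new_members(net, c("q1", "q2", "q3"))
  s2 <- setNames(res3$ranked_items$score, res3$ranked_items$item)
  common <- intersect(names(s1), names(s2))
  expect_true(all(s2[common] >= s1[common] - 1e-12))
})

test_that("held-out module members are recovered near the top", {
  world <- fx_world()
  net <- fx_build()$network
  set.seed(22)
  ranks <- unlist(lapply(names(world$modules), function(mod) {
    members <- world$modules[[mod]]
    held_out <- sample(members, 3L)
    res <- find_new_members(net, setdiff(members, held_out))
    res$ranked_items$rank[match(held_out, res$ranked_items$item)]
  }))
  expect_lt(median(ranks), 10)
  # a planted module is a high-quality guide set
  res <- find_new_members(net, world$modules[[1L]])
  expect_gte(res$auc, 0.75)
})

test_that("function inference agrees across schemes on a pure query", {
  # query connected only to genes of term T
  net <- weighted_network(c("q", "q", "q", "a"), c("t1", "t2", "t3", "b"),
                          c(2, 1, 1, 1))
  catalog <- list(T = c("t1", "t2", "t3"), U = c("a", "b"))
  for (scheme in c("weight_sum", "hypergeometric")) {
    res <- infer_functions(net, "q", catalog, scheme = scheme)
    expect_equal(res$ranked_items$item[1L], "T")
  }

  # hypergeometric tail matches exhaustive enumeration
  nodes <- c(sprintf("n%02d", 1:19), "q")
  edges_b <- sprintf("n%02d", 1:5)
  net2 <- weighted_network(rep("q", 5L), edges_b, rep(1, 5L))
  # embed remaining nodes so the universe has 20 genes
  net2 <- weighted_network(c(rep("q", 5L), sprintf("n%02d", 6:19)),
                           c(edges_b, sprintf("n%02d", c(7:19, 6))),
                           rep(1, 19L))
  term <- c("n01", "n02", "n03", "n10")  # overlap 3 of neighbors
  res2 <- infer_functions(net2, "q", list(TT = term),
                          scheme = "hypergeometric")
  # exhaustive tail: universe 19 (q excluded), draw 5, term size 4
  exhaustive <- sum(vapply(3:4, function(k) {
    choose(4, k) * choose(15, 5 - k)
  }, numeric(1L))) / choose(19, 5)
  expect_equal(res2$ranked_items$p[1L], exhaustive)

  # identical overlap and weights: ties broken by term identifier
  net3 <- weighted_network(c("q", "q"), c("x", "y"), c(1, 1))
  cat3 <- list(B = c("x", "y"), A = c("x", "y"))
  res3 <- infer_functions(net3, "q", cat3)
  expect_equal(res3$ranked_items$item, c("A", "B"))
  expect_equal(res3$ranked_items$score[1L], res3$ranked_items$score[2L])

  # isolated query: empty result with flag
  net4 <- weighted_network(c("a", "q0"), c("b", "zz"), c(1, 1))
  res4 <- infer_functions(net4, "a", list(T = "zz"))
  expect_equal(res4$flag, "no_overlap")
})

test_that("retrieval rate has the right trivial limits", {
  net <- weighted_network(c("a", "b"), c("b", "c"), c(1, 1))
  catalog <- list(ALL = c("a", "b", "c"))
  expect_equal(as.numeric(topn_retrieval_rate(net, catalog,
                                              c("a", "b", "c"), n = 1L)),
               1.0)
  # n = number of terms retrieves whenever every gene has a scored term
  cat2 <- list(T1 = c("a", "b"), T2 = c("b", "c"))
  expect_equal(as.numeric(topn_retrieval_rate(net, cat2, c("a", "c"),
                                              n = 2L)), 1.0)
  expect_error(topn_retrieval_rate(net, cat2, c("zz")), "catalog term")
})

test_that("true terms are retrieved from the planted network, not its null", {
  world <- fx_world()
  net <- fx_build()$network
  catalog <- sim_catalog(world)
  genes <- unlist(world$modules, use.names = FALSE)
  rate <- topn_retrieval_rate(net, catalog, genes, n = 10L)
  expect_gte(as.numeric(rate), 0.8)
  sh <- randomize_network(net, seed = 23)
  rate0 <- topn_retrieval_rate(sh, catalog, genes, n = 10L)
  expect_lte(as.numeric(rate0), 0.2)
  # random baseline: approximately n * (mean term count) / |catalog|
  baseline <- 10 * 1 / length(catalog)
  expect_lt(abs(as.numeric(rate0) - baseline), 0.15)
})
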