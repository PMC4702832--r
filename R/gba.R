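#' Rank candidate genes for a pathway or trait
#'
#' Pathway-centric guilt-by-association: the user's known genes for a
#' pathway/trait guide the search.  Every non-query network gene is scored
#' by its edge-weighted connectivity to the query set,
#' `S(g) = sum of weights of edges between g and the query genes`, and
#' ranked by decreasing score (ties broken by gene identifier).  The
#' result also carries the query set's own interconnectivity AUC
#' ([set_connectivity_auc()]) as a diagnostic: a query set that is not
#' well connected in the network cannot guide a reliable search.
#'
#' @param net A [weighted_network()].
#' @param query_genes Character vector of known pathway/trait genes; at
#'   least 2 must be network nodes.
#' @return A `prioritization_result`: list with `ranked_items` (data frame
#'   `item`, `score`, `rank`), `query`, `unmapped` and `auc`.
#' @export
find_new_members <- function(net, query_genes) {
  stopifnot(inherits(net, "weighted_network"))
  query_genes <- unique(as.character(query_genes))
  nodes <- network_nodes(net)
  mapped <- intersect(query_genes, nodes)
  unmapped <- setdiff(query_genes, nodes)
  if (length(mapped) < 2L) {
    stop("fewer than 2 query genes are network nodes; unmapped: ",
         paste(unmapped, collapse = ", "))
  }
  s <- set_connectivity(net, mapped)
  s <- s[!names(s) %in% query_genes]
  ord <- order(-s, names(s))
  ranked <- data.frame(item = names(s)[ord], score = unname(s[ord]),
                       rank = seq_along(ord))
  out <- list(ranked_items = ranked, query = query_genes,
              unmapped = unmapped,
              auc = set_connectivity_auc(net, mapped))
  class(out) <- "prioritization_result"
  out
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("<prioritization_result: %d ranked items%s>\n",
              nrow(x$ranked_items),
              if (!is.null(x$auc) && !is.na(x$auc))
                sprintf(", query AUC %.3f", x$auc) else ""))
  print(head(x$ranked_items, 10L), row.names = FALSE)
  if (nrow(x$ranked_items) > 10L) cat("  ...\n")
  invisible(x)
}

#' Infer functions for a gene from its network neighbors
#'
#' Gene-centric guilt-by-association: candidate functional terms for a
#' query gene are the terms annotating its network neighbors.  Two scoring
#' schemes:
#' * `weight_sum` (default): a term's score is the summed weight of edges
#'   from the query to neighbors annotated with the term -- uses edge
#'   confidence, ranked descending;
#' * `hypergeometric`: the upper-tail probability of observing at least
#'   the overlap `|N(g) ∩ term|` given the neighborhood size, term size
#'   and the network-node universe, ranked ascending with
#'   Benjamini-Hochberg FDR reported.
#' Terms with no annotated neighbor are omitted; ties are broken by term
#' identifier.
#'
#' @param net A [weighted_network()].
#' @param query_gene A single gene present in the network.
#' @param catalog Named list: term -> character vector of member genes.
#' @param scheme `"weight_sum"` or `"hypergeometric"`.
#' @return A `prioritization_result` whose `ranked_items` has columns
#'   `item`, `score`, `rank` and, for the hypergeometric scheme, `p` and
#'   `fdr`.  An isolated query yields zero rows and `flag = "isolated"`.
#' @export
infer_functions <- function(net, query_gene, catalog,
                            scheme = c("weight_sum", "hypergeometric")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(net, "weighted_network"), length(query_gene) == 1L,
            length(catalog) > 0L)
  nodes <- network_nodes(net)
  if (!query_gene %in% nodes) stop("query gene not in network: ", query_gene)
  nb_a <- net$geneB[net$geneA == query_gene]
  nb_b <- net$geneA[net$geneB == query_gene]
  nb_w <- c(net$weight[net$geneA == query_gene],
            net$weight[net$geneB == query_gene])
  neighbors <- c(nb_a, nb_b)
  flag <- NULL
  if (!length(neighbors)) {
    out <- list(ranked_items = data.frame(item = character(),
                                          score = numeric(),
                                          rank = integer()),
                query = query_gene, flag = "isolated", auc = NA_real_)
    class(out) <- "prioritization_result"
    return(out)
  }
  wvec <- setNames(nb_w, neighbors)
  if (scheme == "weight_sum") {
    score <- vapply(catalog, function(members) {
      sum(wvec[names(wvec) %in% members])
    }, numeric(1L))
    score <- score[score > 0]
    if (!length(score)) flag <- "no_overlap"
    ord <- order(-score, names(score))
    ranked <- data.frame(item = names(score)[ord],
                         score = unname(score[ord]),
                         rank = seq_along(ord))
  } else {
    universe <- setdiff(nodes, query_gene)
    n_draw <- length(unique(neighbors))
    res <- lapply(names(catalog), function(tm) {
      members <- setdiff(catalog[[tm]], query_gene)
      k <- length(intersect(unique(neighbors), members))
      if (k == 0L) return(NULL)
      m_in <- length(intersect(members, universe))
      p <- phyper(k - 1L, m_in, length(universe) - m_in, n_draw,
                  lower.tail = FALSE)
      data.frame(item = tm, overlap = k, p = p)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) {
      flag <- "no_overlap"
      ranked <- data.frame(item = character(), score = numeric(),
                           rank = integer(), p = numeric(), fdr = numeric())
    } else {
      res$fdr <- p.adjust(res$p, method = "BH")
      ord <- order(res$p, res$item)
      ranked <- data.frame(item = res$item[ord], score = -log(res$p[ord]),
                           rank = seq_len(nrow(res)), p = res$p[ord],
                           fdr = res$fdr[ord])
    }
  }
  out <- list(ranked_items = ranked, query = query_gene, flag = flag,
              auc = NA_real_)
  class(out) <- "prioritization_result"
  out
}

#' Top-n retrieval rate of true terms
#'
#' Cross-validated summary of [infer_functions()] accuracy: for each test
#' gene, the gene is removed from every catalog term (so its own
#' annotations cannot leak into the scoring), functions are inferred from
#' its neighbors, and a gene counts as retrieved when at least one of its
#' true terms appears within the top `n` ranked candidates.
#'
#' @param net A [weighted_network()].
#' @param catalog Named list: term -> member genes.
#' @param genes Genes to evaluate; each must have at least one catalog term.
#' @param n Rank depth (default 10).
#' @param scheme Scoring scheme, as in [infer_functions()].
#' @return Fraction of evaluated genes retrieved, with per-gene detail in
#'   attribute `detail`.
#' @export
topn_retrieval_rate <- function(net, catalog, genes, n = 10L,
                                scheme = "weight_sum") {
  stopifnot(inherits(net, "weighted_network"), n >= 1L)
  genes <- unique(as.character(genes))
  true_terms <- lapply(genes, function(g) {
    names(catalog)[vapply(catalog, function(members) g %in% members,
                          logical(1L))]
  })
  if (any(lengths(true_terms) == 0L)) {
    stop("every evaluated gene needs at least one catalog term")
  }
  nodes <- network_nodes(net)
  hit <- vapply(seq_along(genes), function(i) {
    g <- genes[i]
    if (!g %in% nodes) return(NA)
    masked <- lapply(catalog, function(members) setdiff(members, g))
    res <- infer_functions(net, g, masked, scheme = scheme)
    top <- head(res$ranked_items$item, n)
    any(true_terms[[i]] %in% top)
  }, logical(1L))
  detail <- data.frame(gene = genes, retrieved = hit)
  rate <- mean(hit, na.rm = TRUE)
  attr(rate, "detail") <- detail
  rate
}
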