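#' Reference pair set for network assessment
#'
#' An assessment oracle independent of the training gold standard: positive
#' pairs (e.g. co-complex, co-pathway or co-disease genes) over a set of
#' annotated genes.  Only edges with both endpoints among the annotated
#' genes are evaluable against the reference.
#'
#' @param positives Character vector of canonical pair keys
#'   ([pair_key()]), or a two-column data frame/matrix of gene pairs.
#' @param annotated_genes Genes covered by the reference catalog.
#' @return A `reference_pair_set`.
#' @export
reference_pair_set <- function(positives, annotated_genes) {
  if (is.data.frame(positives) || is.matrix(positives)) {
    positives <- pair_key(as.character(positives[, 1L]),
                          as.character(positives[, 2L]))
  }
  positives <- unique(positives)
  annotated_genes <- sort(unique(as.character(annotated_genes)))
  member <- unique(unlist(strsplit(positives, "\t", fixed = TRUE)))
  if (!all(member %in% annotated_genes)) {
    stop("positive pairs mention genes outside annotated_genes")
  }
  structure(list(positives = positives, annotated_genes = annotated_genes),
            class = "reference_pair_set")
}

#' Precision versus genome coverage of a ranked network
#'
#' The assessment protocol for comparing networks of different sizes:
#' edges are ranked by decreasing weight and, at each rank cutoff,
#' * precision = fraction of *evaluable* edges above the cutoff (both
#'   endpoints annotated in the reference) that are reference positives;
#' * genome coverage = distinct genes above the cutoff divided by
#'   `genome_size` (the coding-genome denominator, always supplied
#'   explicitly, never inferred from the network).
#' Cutoffs with no evaluable edge are skipped.
#'
#' @param net A [weighted_network()].
#' @param ref A [reference_pair_set()].
#' @param genome_size Coding-genome size used as the coverage denominator.
#' @param n_points Number of rank cutoffs, evenly spaced in rank.
#' @return Data frame with columns `rank_cutoff`, `precision`,
#'   `genome_coverage`, ordered by increasing cutoff.
#' @export
precision_coverage_curve <- function(net, ref, genome_size,
                                     n_points = 20L) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(ref, "reference_pair_set"), genome_size >= 1)
  if (!nrow(net)) {
    return(data.frame(rank_cutoff = integer(), precision = numeric(),
                      genome_coverage = numeric()))
  }
  # constructor sorts by decreasing weight (ties by pair id): rank order
  evaluable <- net$geneA %in% ref$annotated_genes &
    net$geneB %in% ref$annotated_genes
  hit <- evaluable & (pair_key(net$geneA, net$geneB) %in% ref$positives)
  cum_eval <- cumsum(evaluable)
  cum_hit <- cumsum(hit)
  cutoffs <- unique(round(seq(1, nrow(net), length.out = n_points)))
  keep <- cum_eval[cutoffs] > 0L
  cutoffs <- cutoffs[keep]
  cover <- vapply(cutoffs, function(k) {
    length(unique(c(net$geneA[seq_len(k)], net$geneB[seq_len(k)])))
  }, numeric(1L)) / genome_size
  data.frame(rank_cutoff = cutoffs,
             precision = cum_hit[cutoffs] / cum_eval[cutoffs],
             genome_coverage = cover)
}

# Edge-weighted connectivity of every network gene to a gene set,
# excluding a gene's own membership edge-wise (S(g) sums edges from g to
# set members other than g itself).
set_connectivity <- function(net, gene_set) {
  nodes <- network_nodes(net)
  s <- setNames(numeric(length(nodes)), nodes)
  in_set_a <- net$geneA %in% gene_set
  in_set_b <- net$geneB %in% gene_set
  add_b <- net$weight[in_set_a]
  add_a <- net$weight[in_set_b]
  tb <- tapply(add_b, net$geneB[in_set_a], sum)
  ta <- tapply(add_a, net$geneA[in_set_b], sum)
  if (length(tb)) s[names(tb)] <- s[names(tb)] + tb
  if (length(ta)) s[names(ta)] <- s[names(ta)] + ta
  s
}

#' Gene-set interconnectivity AUC
#'
#' How well the network "knows" a gene set.  Each set member is held out in
#' turn: every gene is scored by its summed edge weight to the remaining
#' members, and the held-out member (the positive) is ranked against all
#' non-member network genes (the negatives) with the rank-sum
#' (Mann-Whitney) formula, ties averaged.  The reported AUC is the mean
#' over held-out members.  Because the held-out member and every negative
#' are scored against exactly the same reduced set, members carry no
#' partner-count handicap and the expected AUC under a random network is
#' exactly 0.5; an AUC of 1 means every member outranks every non-member.
#'
#' @param net A [weighted_network()].
#' @param gene_set Character vector of query genes; at least 2 must be
#'   network nodes.
#' @return The AUC (scalar in `[0, 1]`).
#' @export
set_connectivity_auc <- function(net, gene_set) {
  stopifnot(inherits(net, "weighted_network"))
  nodes <- network_nodes(net)
  mapped <- nodes[nodes %in% gene_set]
  if (length(mapped) < 2L) {
    stop("fewer than 2 gene-set members are network nodes")
  }
  negatives <- nodes[!nodes %in% gene_set]
  if (!length(negatives)) {
    stop("gene set covers every network node; no negatives")
  }
  n_neg <- length(negatives)
  auc_g <- vapply(mapped, function(g) {
    s <- set_connectivity(net, setdiff(mapped, g))
    r <- rank(c(s[g], s[negatives]))  # ties averaged
    (r[1L] - 1) / n_neg               # rank-sum formula, one positive
  }, numeric(1L))
  mean(auc_g)
}

#' Randomize a network for null comparisons
#'
#' Two null models:
#' * `label_shuffle` (default): permutes node labels over the fixed edge
#'   topology -- degree sequence, weight multiset and every topological
#'   property are preserved exactly; only the identity of the genes is
#'   destroyed.  This isolates the placement of annotations on the network.
#' * `degree_preserving`: weighted double-edge swaps (at least `10 * |E|`
#'   attempts), preserving each node's edge-endpoint count while shuffling
#'   which pairs are connected and which weight an edge carries.
#'
#' @param net A [weighted_network()].
#' @param mode `"label_shuffle"` or `"degree_preserving"`.
#' @param seed Integer seed; the same seed always yields the same network.
#' @return A randomized [weighted_network()].
#' @export
randomize_network <- function(net, mode = c("label_shuffle",
                                            "degree_preserving"),
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "weighted_network"))
  if (!nrow(net)) return(net)
  nodes <- network_nodes(net)
  with_seed(child_seed(seed, 7L), {
    if (mode == "label_shuffle") {
      perm <- setNames(sample(nodes), nodes)
      weighted_network(perm[net$geneA], perm[net$geneB], net$weight,
                       name = paste0(attr(net, "name"), "-shuffled"))
    } else {
      a <- net$geneA
      b <- net$geneB
      w <- net$weight
      ne <- length(w)
      existing <- new.env(hash = TRUE, size = ne * 2L)
      for (k in pair_key(a, b)) assign(k, TRUE, envir = existing)
      attempts <- 10L * ne
      ij <- matrix(sample.int(ne, 2L * attempts, replace = TRUE), ncol = 2L)
      for (t in seq_len(attempts)) {
        i <- ij[t, 1L]
        j <- ij[t, 2L]
        if (i == j) next
        # swap partners: (a_i,b_i),(a_j,b_j) -> (a_i,b_j),(a_j,b_i)
        na1 <- a[i]; nb1 <- b[j]; na2 <- a[j]; nb2 <- b[i]
        if (na1 == nb1 || na2 == nb2) next
        k1 <- pair_key(na1, nb1)
        k2 <- pair_key(na2, nb2)
        if (exists(k1, envir = existing, inherits = FALSE) ||
            exists(k2, envir = existing, inherits = FALSE) || k1 == k2) next
        rm(list = c(pair_key(a[i], b[i]), pair_key(a[j], b[j])),
           envir = existing)
        b[i] <- nb1
        b[j] <- nb2
        assign(k1, TRUE, envir = existing)
        assign(k2, TRUE, envir = existing)
      }
      weighted_network(a, b, w,
                       name = paste0(attr(net, "name"), "-rewired"))
    }
  })
}

#' Compare gene-set AUCs against randomized-network nulls
#'
#' For each gene set, computes the observed interconnectivity AUC and the
#' AUCs of the same set on `n_null` randomized networks, then tests whether
#' observed AUCs exceed the per-set mean null AUC with a paired Wilcoxon
#' signed-rank test across sets.  Sets with fewer than 2 members in the
#' network are dropped; with fewer than 5 usable sets the p-value is
#' reported but flagged unreliable.
#'
#' @param net A [weighted_network()].
#' @param gene_sets Named list of gene-identifier vectors.
#' @param n_null Number of randomized networks (default 10).
#' @param seed Seed governing the randomizations.
#' @param mode Null model, as in [randomize_network()].
#' @param alternative Direction of the Wilcoxon test (default `"greater"`:
#'   observed AUCs exceed null).
#' @return An `auc_null_report`: list with `per_set` (data frame: set,
#'   auc, null_mean, null_sd, n_members), `null_auc` matrix (sets x nulls),
#'   `p_value`, `reliable`, `n_sets_used`, `dropped_sets`.
#' @export
auc_null_comparison <- function(net, gene_sets, n_null = 10L, seed = 1L,
                                mode = "label_shuffle",
                                alternative = "greater") {
  stopifnot(inherits(net, "weighted_network"), n_null >= 1L)
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  }
  nodes <- network_nodes(net)
  usable <- vapply(gene_sets, function(g) {
    k <- sum(nodes %in% g)
    k >= 2L && k < length(nodes)
  }, logical(1L))
  dropped <- names(gene_sets)[!usable]
  gene_sets <- gene_sets[usable]
  if (!length(gene_sets)) stop("no gene set has >= 2 members in the network")
  obs <- vapply(gene_sets, function(g) set_connectivity_auc(net, g),
                numeric(1L))
  null_auc <- matrix(NA_real_, length(gene_sets), n_null,
                     dimnames = list(names(gene_sets), NULL))
  for (r in seq_len(n_null)) {
    rnet <- randomize_network(net, mode = mode,
                              seed = child_seed(seed, 100L + r))
    null_auc[, r] <- vapply(gene_sets,
                            function(g) set_connectivity_auc(rnet, g),
                            numeric(1L))
  }
  null_mean <- rowMeans(null_auc)
  reliable <- length(gene_sets) >= 5L
  p <- tryCatch(
    suppressWarnings(
      wilcox.test(obs, null_mean, paired = TRUE,
                  alternative = alternative)$p.value),
    error = function(e) NA_real_)
  out <- list(
    per_set = data.frame(set = names(gene_sets), auc = obs,
                         null_mean = null_mean,
                         null_sd = apply(null_auc, 1L, stats::sd),
                         n_members = vapply(gene_sets, function(g)
                           sum(nodes %in% g), integer(1L)),
                         row.names = NULL),
    null_auc = null_auc, p_value = p, reliable = reliable,
    n_sets_used = length(gene_sets), dropped_sets = dropped)
  class(out) <- "auc_null_report"
  out
}

#' @export
print.auc_null_report <- function(x, ...) {
  cat(sprintf(
    "<auc_null_report: %d sets, mean AUC %.3f vs null %.3f, p = %.3g%s>\n",
    x$n_sets_used, mean(x$per_set$auc), mean(x$per_set$null_mean),
    x$p_value, if (x$reliable) "" else " (unreliable: < 5 sets)"))
  invisible(x)
}
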