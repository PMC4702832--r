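#' Phylogenetic profile container
#'
#' A genes-by-genomes matrix of normalized homology strength in `[0, 1]`
#' (0 = gene absent from that genome), plus a taxonomic domain label per
#' genome.  Correlated profiles (co-inheritance) are evidence of shared
#' function; restricting the comparison to genomes of one domain sharpens
#' the signal because inheritance patterns differ strongly between domains.
#'
#' @param matrix Numeric matrix in `[0, 1]`; rownames = genes, colnames =
#'   genomes.
#' @param domains Named character vector mapping every genome (column) to a
#'   domain label (e.g. `"bacteria"`, `"eukaryota"`).
#' @return A `phylo_profile` object.
#' @export
phylo_profile <- function(matrix, domains) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  if (any(matrix < 0 | matrix > 1)) {
    stop("profile values must lie in [0, 1]")
  }
  missing <- setdiff(colnames(matrix), names(domains))
  if (length(missing)) {
    stop("genomes without a domain label: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  out <- list(matrix = matrix, domains = domains[colnames(matrix)])
  class(out) <- "phylo_profile"
  out
}

#' @export
print.phylo_profile <- function(x, ...) {
  cat(sprintf("<phylo_profile: %d genes x %d genomes (%s)>\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s:%d", names(table(x$domains)),
                            table(x$domains)), collapse = ", ")))
  invisible(x)
}

# Discretize profile values into n_bins equal-width bins over [0, 1];
# returns integer bins 1..n_bins.
discretize_profile <- function(v, n_bins) {
  pmin(floor(v * n_bins) + 1L, n_bins)
}

# Mutual information (nats) between two already-discretized integer vectors.
mi_discrete <- function(x, y, n_bins) {
  n <- length(x)
  joint <- table(factor(x, levels = seq_len(n_bins)),
                 factor(y, levels = seq_len(n_bins))) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Within-domain co-inheritance of two genes
#'
#' Mutual information (nats) between the two genes' profile vectors
#' restricted to the genomes of one taxonomic domain, after discretizing
#' each vector into `n_bins` equal-width bins over `[0, 1]`.  MI is
#' symmetric and non-negative; a constant profile has zero entropy and
#' hence zero MI.
#'
#' @param p A [phylo_profile()].
#' @param a,b Gene identifiers (must be rows of the profile matrix).
#' @param domain Domain label; the domain must contain at least 2 genomes.
#' @param n_bins Discretization resolution (default 2: presence/absence-like).
#' @return Mutual information in nats.
#' @export
profile_similarity <- function(p, a, b, domain, n_bins = 2L) {
  stopifnot(inherits(p, "phylo_profile"), n_bins >= 2L)
  for (g in c(a, b)) {
    if (!g %in% rownames(p$matrix)) stop("gene absent from profile: ", g)
  }
  cols <- p$domains == domain
  if (sum(cols) < 2L) stop("domain '", domain, "' has fewer than 2 genomes")
  x <- discretize_profile(p$matrix[a, cols], n_bins)
  y <- discretize_profile(p$matrix[b, cols], n_bins)
  mi_discrete(x, y, n_bins)
}

# All-pairs MI for one discretized genes x genomes matrix, via per-bin
# indicator crossproducts (n_bins^2 matrix products instead of a pair loop).
mi_matrix <- function(disc, n_bins) {
  n <- ncol(disc)
  ind <- lapply(seq_len(n_bins), function(b) (disc == b) * 1)
  marg <- lapply(ind, rowSums)
  mi <- matrix(0, nrow(disc), nrow(disc))
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      cnt <- tcrossprod(ind[[i]], ind[[j]])
      pj <- cnt / n
      ex <- outer(marg[[i]], marg[[j]]) / n^2
      term <- pj * log(pj / ex)
      term[cnt == 0] <- 0
      mi <- mi + term
    }
  }
  dimnames(mi) <- list(rownames(disc), rownames(disc))
  mi
}

#' Phylogenetic-profiling evidence layer
#'
#' Computes within-domain co-inheritance (MI) for every gene pair, domain
#' by domain, benchmarks each domain's MI scores separately against the
#' gold standard, and assigns each pair the maximum of its per-domain LLS
#' values.  Genes present (value > 0) in fewer than 2 genomes carry no
#' profile information and are excluded.
#'
#' @param p A [phylo_profile()].
#' @param gs A `gold_standard` for the per-domain calibration.
#' @param n_bins Profile discretization bins (default 2).
#' @param n_lls_bins,pseudocount,isotonic Passed to [benchmark_layer()].
#' @param combine `"max"` (default) keeps the best per-domain LLS;
#'   `"ws"` combines per-domain LLS with [weighted_sum()] at `D`.
#' @param D Degradation factor for `combine = "ws"`.
#' @param name Layer tag.
#' @return An [evidence_layer()] whose scores are already on the LLS scale
#'   (use [lls_layer_to_network()] to threshold into a component network).
#' @export
profile_layer <- function(p, gs, n_bins = 2L, n_lls_bins = 20L,
                          pseudocount = 0.5, isotonic = TRUE,
                          combine = c("max", "ws"), D = 1,
                          name = "MM-PG") {
  stopifnot(inherits(p, "phylo_profile"))
  combine <- match.arg(combine)
  present <- rowSums(p$matrix > 0) >= 2L
  m <- p$matrix[present, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 genes with informative profiles")
  genes <- rownames(m)
  ut <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
  per_domain <- list()
  for (dom in unique(p$domains)) {
    cols <- p$domains == dom
    if (sum(cols) < 2L) next
    disc <- matrix(discretize_profile(m[, cols], n_bins), nrow = nrow(m),
                   dimnames = list(genes, NULL))
    mi <- mi_matrix(disc, n_bins)
    lay <- evidence_layer(genes[ut[, 1L]], genes[ut[, 2L]], mi[ut],
                          name = paste0(name, ":", dom),
                          higher_is_stronger = TRUE)
    mapping <- benchmark_layer(lay, gs, n_bins = n_lls_bins,
                               pseudocount = pseudocount,
                               isotonic = isotonic)
    bin <- findInterval(lay$score, mapping$bin_edges,
                        rightmost.closed = TRUE, all.inside = TRUE)
    per_domain[[dom]] <- mapping$bin_lls[bin]
  }
  if (!length(per_domain)) stop("no domain with at least 2 genomes")
  scores <- do.call(cbind, per_domain)
  comb <- if (combine == "max" || ncol(scores) == 1L) {
    apply(scores, 1L, max)
  } else {
    apply(scores, 1L, weighted_sum, D = D)
  }
  lay <- evidence_layer(genes[ut[, 1L]], genes[ut[, 2L]], comb,
                        name = name, higher_is_stronger = TRUE)
  lay
}

#' Turn an LLS-scaled layer into a component network
#'
#' For layers whose scores are already log-likelihood scores (e.g.
#' [profile_layer()]), thresholding replaces re-benchmarking.
#'
#' @param layer An [evidence_layer()] on the LLS scale.
#' @param min_lls Minimum LLS to keep an edge.
#' @return A [weighted_network()].
#' @export
lls_layer_to_network <- function(layer, min_lls = 0) {
  keep <- layer$score >= min_lls
  weighted_network(layer$geneA[keep], layer$geneB[keep], layer$score[keep],
                   name = attr(layer, "name"))
}

#' Gene position table for prokaryotic genomes
#'
#' Chromosomal coordinates as gene-count ordinals (0-based index along the
#' chromosome), robust to genome-size variation.  Chromosomes are treated
#' as circular.
#'
#' @param positions Data frame with columns `genome`, `gene`, `chrom`,
#'   `index` (0-based ordinal; unique within genome+chromosome) and
#'   optionally `strand`.
#' @return A `gene_position_table` (data.table keyed by genome and gene)
#'   with per-chromosome gene counts in attribute `chrom_sizes`.
#' @export
gene_position_table <- function(positions) {
  req <- c("genome", "gene", "chrom", "index")
  stopifnot(all(req %in% names(positions)))
  dt <- as.data.table(positions)[, req, with = FALSE]
  dup <- dt[, .N, by = c("genome", "chrom", "index")][N > 1L]
  if (nrow(dup)) {
    stop("duplicate ordinal index on ", dup$genome[1L], "/", dup$chrom[1L])
  }
  sizes <- dt[, list(m = .N), by = c("genome", "chrom")]
  setkeyv(dt, c("genome", "gene"))
  structure(dt, chrom_sizes = sizes, class = c("gene_position_table",
                                               class(dt)))
}

#' Gene-neighborhood evidence from conserved chromosomal proximity
#'
#' For each query gene pair and each prokaryotic genome where both genes
#' have an ortholog on the same chromosome, computes the circular ordinal
#' distance `d` (adjacent genes have `d = 1`).  Two measures are returned
#' per pair, over the qualifying genomes:
#' * distance measure: mean of `1/d` (proximity, largest when operon-like);
#' * probability measure: `-sum(ln P(D <= d))` where
#'   `P(D <= d) = min(1, 2d/(m-1))` is the chance of being at least that
#'   close under uniform independent placement on a circular chromosome of
#'   `m` genes -- larger means the observed proximity is less likely by
#'   chance.
#' Chromosomes with fewer than 3 genes, and pairs with no qualifying
#' genome, are excluded.
#'
#' @param t A [gene_position_table()].
#' @param pairs Two-column data frame (or matrix) of query gene pairs.
#' @param orthologs Data frame with columns `gene`, `genome`, `ortholog`
#'   resolving each query gene to at most one gene per genome.
#' @return List with `dist_layer` and `prob_layer`, both [evidence_layer()]s.
#' @export
neighborhood_scores <- function(t, pairs, orthologs) {
  stopifnot(inherits(t, "gene_position_table"))
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2L)
  orth <- as.data.table(orthologs)
  stopifnot(all(c("gene", "genome", "ortholog") %in% names(orth)))
  if (nrow(orth[, .N, by = c("gene", "genome")][N > 1L])) {
    stop("ortholog mapping must resolve to at most one gene per genome")
  }
  cp <- canonical_pairs(pairs[[1L]], pairs[[2L]])
  qp <- unique(data.table(geneA = cp[, 1L], geneB = cp[, 2L]))
  qp <- qp[geneA != geneB]
  pos <- as.data.table(t)
  sizes <- attr(t, "chrom_sizes")
  loc <- merge(orth, pos, by.x = c("genome", "ortholog"),
               by.y = c("genome", "gene"))
  a <- merge(qp, loc, by.x = "geneA", by.y = "gene", allow.cartesian = TRUE)
  ab <- merge(a, loc, by.x = c("geneB", "genome"), by.y = c("gene", "genome"),
              allow.cartesian = TRUE, suffixes = c(".a", ".b"))
  ab <- ab[chrom.a == chrom.b]
  if (!nrow(ab)) {
    empty <- evidence_layer(character(), character(), numeric())
    return(list(dist_layer = empty, prob_layer = empty))
  }
  ab <- merge(ab, sizes, by.x = c("genome", "chrom.a"),
              by.y = c("genome", "chrom"))
  ab <- ab[m >= 3L]
  ab[, d := {
    raw <- abs(index.a - index.b)
    pmin(raw, m - raw)
  }]
  ab <- ab[d >= 1L]
  ab[, p_chance := pmin(1, 2 * d / (m - 1))]
  agg <- ab[, list(dist = mean(1 / d), prob = -sum(log(p_chance))),
            by = c("geneA", "geneB")]
  list(
    dist_layer = evidence_layer(agg$geneA, agg$geneB, agg$dist,
                                name = "GN-dist", higher_is_stronger = TRUE),
    prob_layer = evidence_layer(agg$geneA, agg$geneB, agg$prob,
                                name = "GN-prob", higher_is_stronger = TRUE))
}

#' Combine neighborhood measures into a gene-neighborhood network
#'
#' Benchmarks the distance- and probability-based measures separately
#' against the gold standard, converts each to LLS, and combines the two
#' per pair with the weighted-sum scheme.
#'
#' @param dist_layer,prob_layer Output of [neighborhood_scores()].
#' @param gs A `gold_standard`.
#' @param D Degradation factor for the within-data-type weighted sum.
#' @param min_lls Per-measure LLS threshold before combination.
#' @param n_bins,pseudocount,isotonic Passed to [benchmark_layer()].
#' @param name Tag of the resulting network.
#' @return A [weighted_network()] (MM-GN style).
#' @export
context_layer <- function(dist_layer, prob_layer, gs, D = 1, min_lls = 0,
                          n_bins = 20L, pseudocount = 0.5, isotonic = TRUE,
                          name = "MM-GN") {
  nets <- list()
  for (lay in list(dist_layer, prob_layer)) {
    if (is.null(lay) || !nrow(lay)) next
    mapping <- benchmark_layer(lay, gs, n_bins = n_bins,
                               pseudocount = pseudocount,
                               isotonic = isotonic)
    net <- suppressWarnings(apply_mapping(lay, mapping, min_lls = min_lls))
    nets[[attr(lay, "name")]] <- net
  }
  if (!length(nets)) stop("both neighborhood layers are empty")
  integrate_networks(nets,
                     config = integration_config(D = D,
                                                 min_component_lls = -Inf,
                                                 min_ws = -Inf),
                     name = name)
}
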