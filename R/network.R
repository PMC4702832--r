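#' Weighted co-functional network
#'
#' The central container of the package: an undirected, weighted edge list
#' with one row per unordered gene pair.  Gene identifiers are opaque
#' case-sensitive strings; pairs are stored canonically (lexicographically
#' smaller identifier first) and self-edges are never kept.  Weights are on
#' whatever scale the producing stage uses -- raw log-likelihood scores for
#' a single calibrated layer, weighted-sum scores for an integrated network.
#'
#' @param geneA,geneB Character vectors of endpoint gene identifiers.
#' @param weight Numeric edge weights; must be finite.
#' @param name Network tag carried through reports and file headers.
#' @param collapse How to resolve duplicate pairs: `"max"` keeps the largest
#'   weight (the default everywhere evidence is merged), `"sum"` adds them,
#'   `"error"` fails.
#' @return An object of class `weighted_network`: a `data.frame` with columns
#'   `geneA`, `geneB`, `weight`, sorted by decreasing weight.
#' @examples
#' net <- weighted_network(c("a", "c"), c("b", "b"), c(1.5, 2.0))
#' network_nodes(net)
#' @export
weighted_network <- function(geneA, geneB, weight, name = "network",
                             collapse = c("max", "sum", "error")) {
  collapse <- match.arg(collapse)
  stopifnot(length(geneA) == length(geneB), length(geneA) == length(weight))
  weight <- as.numeric(weight)
  if (length(weight) && any(!is.finite(weight))) {
    stop("edge weights must be finite")
  }
  keep <- geneA != geneB
  cp <- canonical_pairs(geneA[keep], geneB[keep])
  dt <- data.table(geneA = cp[, 1], geneB = cp[, 2], weight = weight[keep])
  if (nrow(dt)) {
    if (anyDuplicated(dt, by = c("geneA", "geneB"))) {
      if (collapse == "error") stop("duplicate gene pairs in network")
      fun <- if (collapse == "max") max else sum
      dt <- dt[, list(weight = fun(weight)), by = c("geneA", "geneB")]
    }
    setorderv(dt, c("weight", "geneA", "geneB"), order = c(-1L, 1L, 1L))
  }
  out <- as.data.frame(dt)
  class(out) <- c("weighted_network", "data.frame")
  attr(out, "name") <- name
  out
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network '%s': %d nodes, %d edges>\n",
              attr(x, "name") %||% "network",
              length(network_nodes(x)), nrow(x)))
  if (nrow(x)) {
    print(head(as.data.frame(x), 6L), row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("  ... %d more edges\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Nodes of a weighted network
#'
#' @param net A [weighted_network()].
#' @return Sorted character vector of distinct endpoint genes.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$geneA, net$geneB)))
}

#' Edge weights keyed by canonical pair
#'
#' @param net A [weighted_network()].
#' @return Named numeric vector; names are tab-separated canonical pair keys.
#' @export
network_edge_weights <- function(net) {
  setNames(net$weight, pair_key(net$geneA, net$geneB))
}

#' Pairwise evidence layer
#'
#' Raw pairwise scores from a single data type, before calibration against
#' the gold standard.  Structurally an edge list like [weighted_network()],
#' but the `score` column is on the data type's native scale (a Pearson
#' correlation, a mutual information, a transferred weight ...), and the
#' layer records whether larger scores mean stronger evidence.
#'
#' @param geneA,geneB Endpoint gene identifiers.
#' @param score Numeric raw scores; must be finite.
#' @param name Layer tag (e.g. `"MM-CX"`).
#' @param higher_is_stronger Does a larger raw score indicate stronger
#'   evidence of co-function?
#' @param collapse Duplicate-pair rule, as in [weighted_network()].
#' @return An object of class `evidence_layer`.
#' @export
evidence_layer <- function(geneA, geneB, score, name = "layer",
                           higher_is_stronger = TRUE,
                           collapse = c("max", "sum", "error")) {
  collapse <- match.arg(collapse)
  stopifnot(length(geneA) == length(geneB), length(geneA) == length(score))
  score <- as.numeric(score)
  if (length(score) && any(!is.finite(score))) {
    stop("evidence scores must be finite")
  }
  keep <- geneA != geneB
  cp <- canonical_pairs(geneA[keep], geneB[keep])
  dt <- data.table(geneA = cp[, 1], geneB = cp[, 2], score = score[keep])
  if (nrow(dt) && anyDuplicated(dt, by = c("geneA", "geneB"))) {
    if (collapse == "error") stop("duplicate gene pairs in layer")
    fun <- if (collapse == "max") max else sum
    dt <- dt[, list(score = fun(score)), by = c("geneA", "geneB")]
  }
  out <- as.data.frame(dt)
  class(out) <- c("evidence_layer", "data.frame")
  attr(out, "name") <- name
  attr(out, "higher_is_stronger") <- isTRUE(higher_is_stronger)
  out
}

#' @export
print.evidence_layer <- function(x, ...) {
  cat(sprintf("<evidence_layer '%s': %d pairs, higher_is_stronger=%s>\n",
              attr(x, "name") %||% "layer", nrow(x),
              attr(x, "higher_is_stronger")))
  if (nrow(x)) print(head(as.data.frame(x), 6L), row.names = FALSE)
  invisible(x)
}
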