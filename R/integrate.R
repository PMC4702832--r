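#' Weighted-sum combination of log-likelihood scores
#'
#' Combines one gene pair's per-layer LLS values into a single score.  The
#' values are sorted in descending order internally and combined as
#' \deqn{WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}}
#' so the strongest evidence enters at full weight and every further line of
#' evidence is down-weighted by its rank.  `D >= 1` models redundancy
#' between evidence sources: `D = 1` treats lines of evidence as nearly
#' independent, `D -> Inf` keeps only the single best line.  Invariant to
#' the input order of `lls_values`.
#'
#' @param lls_values Non-empty numeric vector of LLS values.
#' @param D Degradation factor, `>= 1` (may be `Inf`).
#' @return The weighted-sum score.
#' @examples
#' weighted_sum(c(3, 2), D = 2)       # 3 + 2/2 = 4
#' weighted_sum(c(1, 1, 1), D = 1)    # 1 + 1 + 1/2 = 2.5
#' @export
weighted_sum <- function(lls_values, D = 1) {
  if (!length(lls_values)) stop("weighted_sum needs at least one LLS value")
  stopifnot(D >= 1)
  v <- sort(as.numeric(lls_values), decreasing = TRUE)
  rest <- v[-1L]
  v[1L] + sum(rest / (D * seq_along(rest)))
}

#' Integration configuration
#'
#' @param D Degradation factor (`>= 1`).
#' @param min_component_lls Component weights below this do not enter the
#'   weighted sum.
#' @param min_ws Integrated edges below this weighted-sum score are dropped.
#' @return An `integration_config` list.
#' @export
integration_config <- function(D = 1, min_component_lls = 0, min_ws = 0) {
  stopifnot(D >= 1)
  structure(list(D = D, min_component_lls = min_component_lls,
                 min_ws = min_ws),
            class = "integration_config")
}

#' Integrate component networks with the weighted-sum scheme
#'
#' For every gene pair present in any component, collects that pair's
#' component weights at or above `config$min_component_lls`, combines them
#' with [weighted_sum()], and keeps the pair when the result reaches
#' `config$min_ws`.  Components must already be on the common LLS scale
#' ([apply_mapping()]).
#'
#' @param components Non-empty list of [weighted_network()]s.
#' @param config An [integration_config()].
#' @param name Tag of the integrated network.
#' @param provenance Attach a `layers` column listing contributing
#'   components per edge?
#' @return A [weighted_network()] sorted by decreasing weighted-sum score.
#' @export
integrate_networks <- function(components, config = integration_config(),
                               name = "integrated", provenance = FALSE) {
  stopifnot(length(components) >= 1L,
            inherits(config, "integration_config"))
  tags <- names(components) %||% vapply(components, function(n) {
    attr(n, "name") %||% "component"
  }, character(1L))
  all_edges <- rbindlist(lapply(seq_along(components), function(i) {
    n <- components[[i]]
    if (!nrow(n)) return(NULL)
    data.table(geneA = n$geneA, geneB = n$geneB, weight = n$weight,
               layer = tags[i])
  }))
  if (is.null(all_edges) || !nrow(all_edges)) {
    return(weighted_network(character(), character(), numeric(), name = name))
  }
  all_edges <- all_edges[weight >= config$min_component_lls]
  if (!nrow(all_edges)) {
    return(weighted_network(character(), character(), numeric(), name = name))
  }
  D <- config$D
  agg <- all_edges[, list(ws = weighted_sum(weight, D),
                          layers = paste(layer[order(-weight)],
                                         collapse = ",")),
                   by = c("geneA", "geneB")]
  agg <- agg[ws >= config$min_ws]
  net <- weighted_network(agg$geneA, agg$geneB, agg$ws, name = name)
  if (provenance && nrow(net)) {
    key <- pair_key(agg$geneA, agg$geneB)
    net$layers <- agg$layers[match(pair_key(net$geneA, net$geneB), key)]
  }
  net
}

# Area under the precision-vs-coverage curve, the criterion maximised by
# grid_search_D; trapezoidal rule over coverage (mean precision when fewer
# than two usable points).
precision_coverage_area <- function(net, ref, genome_size, n_points = 20L) {
  pts <- precision_coverage_curve(net, ref, genome_size, n_points)
  if (nrow(pts) == 0L) return(0)
  if (nrow(pts) == 1L) return(pts$precision)
  x <- pts$genome_coverage
  y <- pts$precision
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

#' Grid search for the degradation factor D
#'
#' Chooses `D` by integrating the components under each candidate and
#' scoring the result on held-out gold-standard pairs with the area under
#' the precision-vs-coverage curve.  The hold-out is a 50/50 split of the
#' gold standard at the term level (all pairs of a term stay on one side)
#' to limit leakage between calibration and evaluation.  Ties, and any flat
#' stretch of the criterion, resolve to the smallest `D` for
#' reproducibility.
#'
#' @param components List of calibrated component networks.
#' @param gs The `gold_standard` to split.
#' @param grid Candidate `D` values (all `>= 1`).
#' @param config Base [integration_config()]; its `D` is overridden.
#' @param genome_size Denominator for coverage; defaults to the node count
#'   of the union of components.
#' @param n_points Curve resolution.
#' @param seed Seed for the term split.
#' @return The selected `D` (scalar), with the per-candidate criterion in
#'   attribute `criterion`.
#' @export
grid_search_D <- function(components, gs, grid = c(1, 1.5, 2, 3, 4),
                          config = integration_config(),
                          genome_size = NULL, n_points = 20L, seed = 1L) {
  stopifnot(length(grid) >= 1L, all(grid >= 1))
  terms <- names(gs$term_index)
  if (length(terms) < 2L) {
    stop("gold standard too small to split at the term level")
  }
  half <- with_seed(child_seed(seed, 1L),
                    sample(terms, max(1L, floor(length(terms) / 2))))
  eval_terms <- setdiff(terms, half)
  eval_genes <- sort(unique(unlist(gs$term_index[eval_terms])))
  eval_pos <- unique(unlist(lapply(gs$term_index[eval_terms], function(g) {
    cmb <- utils::combn(g, 2L)
    pair_key(cmb[1L, ], cmb[2L, ])
  })))
  ref <- reference_pair_set(eval_pos, eval_genes)
  if (is.null(genome_size)) {
    genome_size <- length(unique(unlist(lapply(components, network_nodes))))
  }
  grid <- sort(grid)
  crit <- vapply(grid, function(D) {
    cfg <- config
    cfg$D <- D
    precision_coverage_area(
      integrate_networks(components, cfg), ref, genome_size, n_points)
  }, numeric(1L))
  best <- grid[which.max(crit)]  # which.max takes the first (smallest D) tie
  attr(best, "criterion") <- setNames(crit, grid)
  best
}
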