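#' Expression dataset container
#'
#' A gene-by-sample matrix of expression values for one experiment series
#' (GSE-style).  Gene identifiers must be unique within a dataset.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param id Dataset tag.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(matrix, id) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            !is.null(rownames(matrix)))
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene identifiers in dataset ", id)
  }
  out <- list(id = id, matrix = matrix, sample_count = ncol(matrix))
  class(out) <- "expression_dataset"
  out
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d genes x %d samples>\n",
              x$id, nrow(x$matrix), x$sample_count))
  invisible(x)
}

#' Co-expression evidence from one expression dataset
#'
#' Computes pairwise Pearson correlation of expression profiles.  Datasets
#' with fewer than `min_samples` samples (default 12) carry too little
#' information for reliable correlation estimates and are rejected outright:
#' the function returns `NULL` and the rejection is recorded for
#' [evaluate_dataset()].  Constant-expression genes (zero variance) cannot
#' be correlated and are excluded, with their count reported in the
#' `dropped_constant` attribute.  To keep downstream pair counts tractable
#' only the strongest `top_n` correlations per gene are retained (only
#' high-correlation strata carry co-functional signal).
#'
#' @param ds An [expression_dataset()].
#' @param min_samples Minimum sample count for the dataset to be usable.
#' @param top_n Per-gene cap on retained partners (by correlation rank).
#' @param method Correlation measure passed to [stats::cor()]
#'   (default `"pearson"`).
#' @return An [evidence_layer()] of correlations in `[-1, 1]`, or `NULL`
#'   when the dataset fails the size filter.
#' @export
correlate <- function(ds, min_samples = 12L, top_n = 100L,
                      method = "pearson") {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$sample_count < min_samples) {
    return(NULL)
  }
  m <- ds$matrix
  v <- apply(m, 1L, stats::var)
  constant <- !is.finite(v) | v == 0
  m <- m[!constant, , drop = FALSE]
  if (nrow(m) < 2L) {
    stop("dataset ", ds$id, " has fewer than 2 variable genes")
  }
  cc <- cor(t(m), method = method)
  genes <- rownames(m)
  n <- length(genes)
  # strongest |top_n| partners per gene, then union of the selected pairs
  keep <- matrix(FALSE, n, n)
  ord <- apply(cc, 1L, function(row) order(row, decreasing = TRUE))
  for (i in seq_len(n)) {
    partners <- setdiff(ord[, i], i)[seq_len(min(top_n, n - 1L))]
    keep[i, partners] <- TRUE
  }
  keep <- (keep | t(keep)) & upper.tri(keep)
  idx <- which(keep, arr.ind = TRUE)
  layer <- evidence_layer(genes[idx[, 1L]], genes[idx[, 2L]],
                          cc[idx], name = paste0("CX:", ds$id),
                          higher_is_stronger = TRUE)
  attr(layer, "dataset_id") <- ds$id
  attr(layer, "dropped_constant") <- sum(constant)
  layer
}

#' Decide whether a co-expression dataset carries gold-standard signal
#'
#' Mirrors the dataset-selection filter of the construction protocol:
#' a dataset is retained only if genes with highly correlated expression
#' show an increased tendency to share positive gold-standard annotations.
#' Operationally the correlation layer is benchmarked against the gold
#' standard and the best (maximum) bin LLS is compared to
#' `retain_threshold`.  Datasets failing the size filter, or with too few
#' labelled pairs to bin, are not retained.
#'
#' @param layer Output of [correlate()] (`NULL` when the dataset failed the
#'   size filter).
#' @param gs A `gold_standard`.
#' @param retain_threshold Minimum best-bin LLS (nats) to retain.
#' @param id Dataset tag used when `layer` is `NULL`.
#' @param n_bins,pseudocount Passed to [benchmark_layer()].
#' @return A `dataset_verdict`: list with `id`, `passed_size`,
#'   `best_bin_lls`, `retained`, `reason`, and (when retained) the fitted
#'   `mapping`.
#' @export
evaluate_dataset <- function(layer, gs, retain_threshold = 0.5,
                             id = NULL, n_bins = 20L, pseudocount = 0.5) {
  if (is.null(layer)) {
    out <- list(id = id %||% "unknown", passed_size = FALSE,
                best_bin_lls = NA_real_, retained = FALSE,
                reason = "fewer samples than min_samples", mapping = NULL)
    class(out) <- "dataset_verdict"
    return(out)
  }
  stopifnot(inherits(layer, "evidence_layer"))
  id <- id %||% attr(layer, "dataset_id") %||% attr(layer, "name")
  mapping <- tryCatch(
    benchmark_layer(layer, gs, n_bins = n_bins, pseudocount = pseudocount),
    error = function(e) e)
  if (inherits(mapping, "error")) {
    out <- list(id = id, passed_size = TRUE, best_bin_lls = NA_real_,
                retained = FALSE, reason = conditionMessage(mapping),
                mapping = NULL)
    class(out) <- "dataset_verdict"
    return(out)
  }
  best <- max(mapping$bin_lls)
  out <- list(id = id, passed_size = TRUE, best_bin_lls = best,
              retained = best >= retain_threshold,
              reason = if (best >= retain_threshold) "retained" else
                sprintf("best bin LLS %.3f below threshold %.3f",
                        best, retain_threshold),
              mapping = mapping)
  class(out) <- "dataset_verdict"
  out
}

#' @export
print.dataset_verdict <- function(x, ...) {
  cat(sprintf("<dataset_verdict '%s': passed_size=%s best_bin_lls=%s retained=%s>\n",
              x$id, x$passed_size,
              if (is.na(x$best_bin_lls)) "NA" else
                sprintf("%.3f", x$best_bin_lls),
              x$retained))
  invisible(x)
}

#' Integrate per-dataset co-expression networks into one layer
#'
#' Applies the weighted-sum scheme ([weighted_sum()]) within the
#' co-expression data type: for each gene pair the per-dataset LLS values
#' are sorted descending and combined as `L0 + sum(Li / (D * i))`.
#'
#' @param networks List of calibrated per-dataset [weighted_network()]s.
#' @param D Evidence-redundancy degradation factor (>= 1).
#' @param name Tag for the combined network.
#' @return A single [weighted_network()].
#' @export
integrate_coexpression <- function(networks, D = 1, name = "MM-CX") {
  if (!length(networks)) stop("no co-expression networks to integrate")
  integrate_networks(networks,
                     config = integration_config(D = D,
                                                 min_component_lls = -Inf,
                                                 min_ws = -Inf),
                     name = name)
}
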