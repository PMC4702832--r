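#' Log-likelihood score of a single evidence stratum
#'
#' The common currency of the framework.  For an evidence stratum E (one bin
#' of raw scores) the log-likelihood score is
#' \deqn{LLS = \ln\frac{P(L|E)/P(\neg L|E)}{P(L)/P(\neg L)}}
#' where L is the event that a gene pair is functionally linked.  With bin
#' counts it reduces to
#' `ln(((pos_in_bin + c) / (neg_in_bin + c)) / (pos_total / neg_total))`
#' with pseudocount `c`; natural log throughout, so the unit is nats.
#' The score is invariant under rescaling both totals.
#'
#' @param pos_in_bin,neg_in_bin Positive/negative labelled pairs in the bin.
#' @param pos_total,neg_total Positive/negative labelled pairs overall
#'   (the prior odds); both must be positive.
#' @param pseudocount Added to both bin cells; with 0 an empty cell is an
#'   error rather than an infinity.
#' @return The log-likelihood score in nats (vectorised over bin counts).
#' @examples
#' lls_of_counts(40, 10, 100, 400)            # ln 16
#' lls_of_counts(0, 10, 100, 100, pseudocount = 0.5)
#' @export
lls_of_counts <- function(pos_in_bin, neg_in_bin, pos_total, neg_total,
                          pseudocount = 0) {
  stopifnot(pos_total > 0, neg_total > 0, pseudocount >= 0)
  if (pseudocount == 0 && any(pos_in_bin == 0 | neg_in_bin == 0)) {
    stop("empty bin cell with pseudocount 0; supply a pseudocount > 0")
  }
  log(((pos_in_bin + pseudocount) / (neg_in_bin + pseudocount)) /
        (pos_total / neg_total))
}

# Weighted pool-adjacent-violators: smallest non-decreasing fit to y in a
# weighted least-squares sense.  Used to enforce monotone LLS along the raw
# score, with bin label counts as weights.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1L) return(y)
  val <- numeric(0)
  wt <- numeric(0)
  sz <- integer(0)
  for (i in seq_len(n)) {
    val <- c(val, y[i])
    wt <- c(wt, w[i])
    sz <- c(sz, 1L)
    k <- length(val)
    while (k > 1L && val[k - 1L] > val[k] + 1e-12) {
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) /
        (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      val <- val[-k]
      wt <- wt[-k]
      sz <- sz[-k]
      k <- k - 1L
    }
  }
  rep(val, sz)
}

#' Benchmark an evidence layer against the gold standard
#'
#' Calibrates one data type's raw pairwise scores onto the log-likelihood
#' scale.  Pairs whose gold-standard label is `unknown` are excluded; the
#' remaining pairs are binned along the raw score (equal-count bins by
#' default, or explicit thresholds), and each bin's positive/negative counts
#' are converted to an LLS against the layer-wide prior odds.  A bin with no
#' labelled pair is filled by linear interpolation from its neighbours and
#' flagged.  Optional isotonic smoothing enforces that the LLS is monotone
#' in the raw score (non-decreasing when higher scores mean stronger
#' evidence), which guards against noise in sparsely populated bins.
#'
#' @param layer An [evidence_layer()].
#' @param gs A `gold_standard` ([build_gold_standard()]).
#' @param n_bins Number of equal-count bins (ignored when `thresholds`
#'   given). Default 20, robust to skewed raw-score distributions.
#' @param thresholds Optional explicit ascending bin edges (length
#'   `n_bins + 1`, typically `-Inf`/`Inf` at the extremes).
#' @param pseudocount Per-bin-cell pseudocount (default 0.5) preventing
#'   infinite scores in pure bins.
#' @param isotonic Apply monotone smoothing to the per-bin LLS (default
#'   `TRUE`).
#' @param prior Where the prior odds `P(L)/P(not L)` come from:
#'   `"gold_standard"` (default) uses all positive pairs versus all implied
#'   negative pairs of the gold standard, so a layer that covers mostly
#'   positive pairs is credited for that enrichment; `"layer"` restricts
#'   the totals to the layer's own labelled pairs, making each bin's score
#'   relative to the layer-wide odds.
#' @return An `lls_mapping`: list with `bin_edges`, `bin_lls`, per-bin
#'   `pos`/`neg` counts, `prior_odds`, `empty_bins`, `higher_is_stronger`
#'   and the layer `name`.
#' @export
benchmark_layer <- function(layer, gs, n_bins = 20L, thresholds = NULL,
                            pseudocount = 0.5, isotonic = TRUE,
                            prior = c("gold_standard", "layer")) {
  prior <- match.arg(prior)
  stopifnot(inherits(layer, "evidence_layer"), inherits(gs, "gold_standard"))
  lab <- label_pair(gs, layer$geneA, layer$geneB)
  known <- lab != "unknown"
  if (!any(known)) {
    stop("layer '", attr(layer, "name"),
         "' has no pair with a known gold-standard label")
  }
  score <- layer$score[known]
  is_pos <- lab[known] == "positive"
  if (prior == "gold_standard") {
    pos_total <- length(gs$positives)
    neg_total <- choose(length(gs$universe), 2L) - pos_total
  } else {
    pos_total <- sum(is_pos)
    neg_total <- sum(!is_pos)
  }
  if (pos_total == 0L || neg_total == 0L) {
    stop("labelled pairs are all of one class; cannot form prior odds")
  }

  if (is.null(thresholds)) {
    stopifnot(n_bins >= 1L)
    probs <- seq(0, 1, length.out = n_bins + 1L)
    edges <- unique(as.numeric(quantile(score, probs = probs, type = 7)))
    u <- sort(unique(score))
    if (length(edges) - 1L < min(n_bins, length(u))) {
      # heavy ties collapse the equal-count quantiles; fall back to
      # splitting between distinct score values
      if (length(u) <= n_bins) {
        edges <- c(-Inf, (u[-1L] + u[-length(u)]) / 2, Inf)
      } else {
        edges <- unique(as.numeric(quantile(u, probs = probs, type = 7)))
      }
    }
    edges[1L] <- -Inf
    edges[length(edges)] <- Inf
    if (length(edges) < 2L) edges <- c(-Inf, Inf)
  } else {
    edges <- as.numeric(thresholds)
    if (is.unsorted(edges, strictly = TRUE)) {
      stop("thresholds must be strictly ascending")
    }
  }
  nb <- length(edges) - 1L
  bin <- findInterval(score, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  pos <- tabulate(bin[is_pos], nbins = nb)
  neg <- tabulate(bin[!is_pos], nbins = nb)
  empty <- (pos + neg) == 0L
  lls <- rep(NA_real_, nb)
  lls[!empty] <- lls_of_counts(pos[!empty], neg[!empty], pos_total,
                               neg_total, pseudocount)
  if (any(empty)) {
    # neighbour interpolation over bin index; flat extrapolation at the ends
    filled <- which(!empty)
    lls[empty] <- stats::approx(filled, lls[filled], xout = which(empty),
                                rule = 2)$y
  }
  if (isotonic && nb > 1L) {
    w <- pos + neg + pseudocount
    if (attr(layer, "higher_is_stronger")) {
      lls <- pava(lls, w)
    } else {
      lls <- rev(pava(rev(lls), rev(w)))
    }
  }
  out <- list(bin_edges = edges, bin_lls = lls, pos = pos, neg = neg,
              prior_odds = pos_total / neg_total,
              pos_total = pos_total, neg_total = neg_total,
              empty_bins = which(empty),
              higher_is_stronger = attr(layer, "higher_is_stronger"),
              name = attr(layer, "name"))
  class(out) <- "lls_mapping"
  out
}

#' @export
print.lls_mapping <- function(x, ...) {
  cat(sprintf(
    "<lls_mapping '%s': %d bins, prior odds %.4g, LLS range [%.3f, %.3f]>\n",
    x$name, length(x$bin_lls), x$prior_odds,
    min(x$bin_lls), max(x$bin_lls)))
  invisible(x)
}

#' Convert raw layer scores to a calibrated network
#'
#' Replaces each pair's raw score with the log-likelihood score of its bin
#' and drops pairs whose LLS falls below `min_lls`, yielding a component
#' network on the common scale.
#'
#' @param layer The [evidence_layer()] to convert (same data type and score
#'   orientation as the mapping was built from).
#' @param mapping An `lls_mapping` from [benchmark_layer()].
#' @param min_lls Minimum LLS for an edge to be kept (default 0: only
#'   evidence above the prior survives).
#' @return A [weighted_network()] of calibrated edges (possibly empty, with
#'   a warning).
#' @export
apply_mapping <- function(layer, mapping, min_lls = 0) {
  stopifnot(inherits(layer, "evidence_layer"),
            inherits(mapping, "lls_mapping"))
  if (isTRUE(attr(layer, "higher_is_stronger")) !=
      isTRUE(mapping$higher_is_stronger)) {
    stop("layer and mapping disagree on score orientation")
  }
  bin <- findInterval(layer$score, mapping$bin_edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
  w <- mapping$bin_lls[bin]
  keep <- w >= min_lls
  if (!any(keep)) {
    warning("no edge reaches min_lls = ", min_lls, " in layer '",
            attr(layer, "name"), "'")
  }
  weighted_network(layer$geneA[keep], layer$geneB[keep], w[keep],
                   name = attr(layer, "name"))
}

#' Write / read an LLS mapping as TSV
#'
#' Serialises bins as rows `bin_low  bin_high  lls` (full precision).
#'
#' @param mapping An `lls_mapping`.
#' @param path File path.
#' @return `read_mapping` returns an `lls_mapping` (counts not preserved).
#' @export
write_mapping <- function(mapping, path) {
  tab <- data.frame(
    bin_low = mapping$bin_edges[-length(mapping$bin_edges)],
    bin_high = mapping$bin_edges[-1L],
    lls = mapping$bin_lls)
  header <- sprintf("# lls_mapping name=%s higher_is_stronger=%s prior_odds=%s",
                    mapping$name, mapping$higher_is_stronger,
                    format(mapping$prior_odds, digits = 17))
  writeLines(c(header, "bin_low\tbin_high\tlls"), path)
  fwrite(tab, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(mapping)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(name = "mapping", higher_is_stronger = TRUE, prior_odds = 1)
  if (startsWith(first, "# lls_mapping")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1L]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1L]]
      meta[[parts[1L]]] <- parts[2L]
    }
  }
  tab <- fread(path, sep = "\t", skip = "bin_low\tbin_high\tlls")
  out <- list(bin_edges = c(tab$bin_low, tab$bin_high[nrow(tab)]),
              bin_lls = tab$lls, pos = NULL, neg = NULL,
              prior_odds = as.numeric(meta$prior_odds),
              empty_bins = integer(),
              higher_is_stronger = as.logical(meta$higher_is_stronger),
              name = meta$name)
  class(out) <- "lls_mapping"
  out
}
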