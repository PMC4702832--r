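#' Reliable evidence codes used by default
#'
#' Annotation provenance codes treated as experimentally or author-traceably
#' supported: IDA (direct assay), IMP (mutant phenotype), IPI (protein
#' interaction), TAS (traceable author statement).  Configurable everywhere
#' it is consumed; computational codes such as IEA are excluded by default.
#'
#' @export
RELIABLE_EVIDENCE_CODES <- c("IDA", "IMP", "IPI", "TAS")

#' Parse gene-term annotation records
#'
#' Reads annotation records either from a data frame or from a file
#' ([read_annotations()]) and keeps only records supported by an allowed
#' evidence code.  Duplicate (gene, term) records are collapsed to one;
#' input order of first occurrence is preserved.  Records carrying an
#' evidence code outside `allowed_codes` are skipped and counted in the
#' `skipped_codes` attribute of the result.
#'
#' @param records Data frame with columns `gene`, `term`, `evidence_code`
#'   (and optionally `source`), or a file path accepted by
#'   [read_annotations()].
#' @param allowed_codes Non-empty character vector of evidence codes to keep.
#' @return Data frame of retained records with attribute `skipped_codes`
#'   (named integer table of rejected codes).
#' @export
parse_annotations <- function(records,
                              allowed_codes = RELIABLE_EVIDENCE_CODES) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_annotations(records)
  }
  stopifnot(is.data.frame(records), length(allowed_codes) > 0L)
  req <- c("gene", "term", "evidence_code")
  if (!all(req %in% names(records))) {
    stop("annotation records need columns: ", paste(req, collapse = ", "))
  }
  if (!"source" %in% names(records)) {
    records$source <- rep("annotation", nrow(records))
  }
  records <- records[, c("gene", "term", "evidence_code", "source")]
  bad <- !nzchar(records$gene) | !nzchar(records$term)
  if (any(bad)) {
    stop("empty gene or term identifier at record ", which(bad)[1L])
  }
  drop <- !(records$evidence_code %in% allowed_codes)
  skipped <- table(records$evidence_code[drop])
  kept <- records[!drop, , drop = FALSE]
  kept <- kept[!duplicated(kept[, c("gene", "term")]), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "skipped_codes") <- skipped
  kept
}

#' Build a gold standard of positive gene pairs
#'
#' Two genes form a positive gold-standard pair when they share a retained
#' functional annotation term.  Terms with fewer than `min_term_size` or
#' more than `max_term_size` member genes are excluded: tiny terms carry no
#' pairs, and giant generic terms would otherwise dominate the positives.
#' Positives are deduplicated across terms and across annotation sources
#' (pair-level union).  The gold-standard universe is the union of retained
#' terms' genes; pairs of universe genes that are not positive serve as the
#' implied negatives.
#'
#' @param records Parsed annotation records ([parse_annotations()]).
#' @param min_term_size,max_term_size Retained term-size bounds (inclusive).
#' @return A `gold_standard` object: list with `positives` (character vector
#'   of canonical pair keys), `universe` (sorted gene vector) and
#'   `term_index` (named list term -> sorted member genes).
#' @examples
#' recs <- data.frame(gene = c("a", "b", "c"), term = "T1",
#'                    evidence_code = "IDA")
#' gs <- build_gold_standard(parse_annotations(recs))
#' length(gs$positives)  # choose(3, 2) = 3
#' @export
build_gold_standard <- function(records, min_term_size = 2L,
                                max_term_size = 300L) {
  stopifnot(min_term_size >= 2L, max_term_size >= min_term_size)
  members <- lapply(split(records$gene, records$term),
                    function(g) sort(unique(g)))
  sizes <- lengths(members)
  members <- members[sizes >= min_term_size & sizes <= max_term_size]
  if (!length(members)) {
    stop(sprintf(
      "no annotation term has between %d and %d member genes",
      min_term_size, max_term_size))
  }
  positives <- unique(unlist(lapply(members, function(g) {
    cmb <- utils::combn(g, 2L)
    pair_key(cmb[1L, ], cmb[2L, ])
  }), use.names = FALSE))
  out <- list(positives = positives,
              universe = sort(unique(unlist(members, use.names = FALSE))),
              term_index = members)
  class(out) <- "gold_standard"
  out
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "<gold_standard: %d positive pairs, %d genes, %d terms>\n",
    length(x$positives), length(x$universe), length(x$term_index)))
  invisible(x)
}

#' Label gene pairs against the gold standard
#'
#' A pair is `positive` when it shares a retained term, `negative` when both
#' genes belong to the gold-standard universe but the pair is not positive,
#' and `unknown` when either gene is unannotated.  Symmetric in (a, b).
#'
#' @param gs A `gold_standard`.
#' @param a,b Equal-length character vectors of gene identifiers; no element
#'   of `a` may equal its counterpart in `b`.
#' @return Character vector in `{"positive", "negative", "unknown"}`.
#' @export
label_pair <- function(gs, a, b) {
  stopifnot(inherits(gs, "gold_standard"), length(a) == length(b))
  if (any(a == b)) stop("self-pairs cannot be labelled")
  lab <- rep("unknown", length(a))
  known <- a %in% gs$universe & b %in% gs$universe
  lab[known] <- "negative"
  lab[pair_key(a, b) %in% gs$positives] <- "positive"
  lab
}

#' Export a gold standard as a labelled pair table
#'
#' Writes (or returns) every universe pair with its positive/negative label,
#' in the TSV dialect `geneA geneB label`.
#'
#' @param gs A `gold_standard`.
#' @param path Optional output path; when `NULL` the table is returned only.
#' @return Data frame with columns `geneA`, `geneB`, `label`, invisibly when
#'   written.
#' @export
export_gold_standard <- function(gs, path = NULL) {
  cmb <- utils::combn(gs$universe, 2L)
  tab <- data.frame(geneA = cmb[1L, ], geneB = cmb[2L, ])
  tab$label <- ifelse(pair_key(tab$geneA, tab$geneB) %in% gs$positives,
                      "positive", "negative")
  if (!is.null(path)) {
    fwrite(tab, path, sep = "\t")
    return(invisible(tab))
  }
  tab
}
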