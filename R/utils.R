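#' @importFrom stats cor phyper p.adjust quantile rbinom rnorm runif setNames
#'   wilcox.test
#' @importFrom utils head
#' @import data.table
NULL

# Canonical unordered-pair representation: lexicographically smaller gene
# first.  Gene identifiers are opaque, case-sensitive strings; tab is the
# field separator of every file format here, so it cannot occur in a gene id
# and is safe as the key separator.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Returns a two-column character matrix with geneA <= geneB per row.
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  cbind(geneA = a, geneB = b)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls stay referentially transparent.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a user seed, kept inside the
# 32-bit signed-integer range R requires.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".N", "N", "weight", "ws", "layer", "geneA", "geneB", "score",
  "chrom.a", "chrom.b", "index.a", "index.b", "m", "d", "p_chance",
  "target_a", "target_b", "gene", "term", "genome", "ortholog"))
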