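#' Read and write weighted networks as TSV edge lists
#'
#' The downloadable-edge-list convention: tab-separated columns
#' `geneA geneB weight`, sorted by decreasing weight; comment/header lines
#' start with `#`.  Weights are serialized at full precision (17
#' significant digits) so a write-read round trip is bit-exact.  On read,
#' duplicate pair lines keep the maximum weight (with a warning), self
#' edges are skipped with a warning, and a non-numeric weight is an error
#' naming the offending line.
#'
#' @param path File path.
#' @param name Network tag (defaults to the file name).
#' @return `read_network` returns a [weighted_network()].
#' @export
read_network <- function(path, name = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(body)
  lines <- lines[body]
  name <- name %||% basename(path)
  if (!length(lines)) {
    return(weighted_network(character(), character(), numeric(),
                            name = name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("malformed network line ", lineno[which(nf < 3L)[1L]], " in ", path)
  }
  a <- vapply(parts, `[`, character(1L), 1L)
  b <- vapply(parts, `[`, character(1L), 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1L), 3L)))
  if (anyNA(w)) {
    stop("non-numeric weight at line ", lineno[which(is.na(w))[1L]],
         " in ", path)
  }
  selfs <- a == b
  if (any(selfs)) {
    warning(sum(selfs), " self-edge line(s) skipped in ", path)
    a <- a[!selfs]
    b <- b[!selfs]
    w <- w[!selfs]
  }
  if (anyDuplicated(pair_key(a, b))) {
    warning("duplicate pair lines in ", path, "; keeping maximum weight")
  }
  weighted_network(a, b, w, name = name, collapse = "max")
}

#' @param net A [weighted_network()].
#' @rdname read_network
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weighted_network name=%s nodes=%d edges=%d",
                     attr(net, "name") %||% "network",
                     length(network_nodes(net)), nrow(net)), con)
  writeLines("# geneA\tgeneB\tweight", con)
  if (nrow(net)) {
    writeLines(paste(net$geneA, net$geneB,
                     format(net$weight, digits = 17, scientific = FALSE,
                            trim = TRUE), sep = "\t"), con)
  }
  invisible(net)
}

#' Read an evidence layer from a 3-column TSV
#'
#' Format `geneA geneB score`, `#` comments allowed.
#'
#' @param path File path.
#' @param name Layer tag.
#' @param higher_is_stronger Score orientation flag.
#' @return An [evidence_layer()].
#' @export
read_layer <- function(path, name = NULL, higher_is_stronger = TRUE) {
  net <- read_network(path, name = name %||% basename(path))
  evidence_layer(net$geneA, net$geneB, net$weight,
                 name = attr(net, "name"),
                 higher_is_stronger = higher_is_stronger)
}

#' Read annotation records
#'
#' Accepts two dialects:
#' * a headerless GAF-2-compatible file (`!` comments, >= 15 tab fields):
#'   gene symbol from column 3, term from column 5, evidence code from
#'   column 7;
#' * a simple TSV with header containing at least
#'   `gene  term  evidence_code` (optional `source`).
#' Malformed lines are an error naming the line number.
#'
#' @param path File path.
#' @return Data frame with columns `gene`, `term`, `evidence_code`,
#'   `source`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(gene = character(), term = character(),
                      evidence_code = character(), source = character()))
  }
  nfields <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
  if (nfields >= 15L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    short <- lengths(parts) < 7L
    if (any(short)) {
      stop("malformed GAF line ", which(short)[1L], " in ", path)
    }
    data.frame(gene = vapply(parts, `[`, character(1L), 3L),
               term = vapply(parts, `[`, character(1L), 5L),
               evidence_code = vapply(parts, `[`, character(1L), 7L),
               source = "GAF")
  } else {
    tab <- fread(path, sep = "\t", colClasses = "character")
    req <- c("gene", "term", "evidence_code")
    if (!all(req %in% names(tab))) {
      stop("annotation TSV must have header columns: ",
           paste(req, collapse = ", "))
    }
    if (!"source" %in% names(tab)) tab$source <- "annotation"
    as.data.frame(tab[, c(req, "source"), with = FALSE])
  }
}

#' Read and write expression matrices
#'
#' TSV matrix: first column the gene identifier, header row the sample
#' identifiers.
#'
#' @param path File path.
#' @param id Dataset tag (defaults to the file name).
#' @return `read_expression` returns an [expression_dataset()].
#' @export
read_expression <- function(path, id = NULL) {
  tab <- fread(path, sep = "\t")
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, with = FALSE])
  rownames(m) <- genes
  expression_dataset(m, id = id %||% basename(path))
}

#' @param ds An [expression_dataset()].
#' @rdname read_expression
#' @export
write_expression <- function(ds, path) {
  tab <- data.table(gene = rownames(ds$matrix))
  tab <- cbind(tab, as.data.table(ds$matrix))
  fwrite(tab, path, sep = "\t")
  invisible(ds)
}

#' Read and write phylogenetic profiles
#'
#' Profile matrix: TSV, first column the gene, header the genome
#' identifiers.  Domain table: two-column TSV `genome  domain`.
#'
#' @param path,domains_path File paths.
#' @return `read_profiles` returns a [phylo_profile()].
#' @export
read_profiles <- function(path, domains_path) {
  tab <- fread(path, sep = "\t")
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, with = FALSE])
  rownames(m) <- genes
  dom <- fread(domains_path, sep = "\t")
  phylo_profile(m, setNames(as.character(dom[[2L]]),
                            as.character(dom[[1L]])))
}

#' @param p A [phylo_profile()].
#' @rdname read_profiles
#' @export
write_profiles <- function(p, path, domains_path) {
  tab <- data.table(gene = rownames(p$matrix))
  tab <- cbind(tab, as.data.table(p$matrix))
  fwrite(tab, path, sep = "\t")
  fwrite(data.frame(genome = names(p$domains),
                    domain = unname(p$domains)),
         domains_path, sep = "\t")
  invisible(p)
}

#' Read gene positions
#'
#' TSV with header columns `genome gene chrom index` (optional `strand`).
#'
#' @param path File path.
#' @return A [gene_position_table()].
#' @export
read_positions <- function(path) {
  gene_position_table(as.data.frame(fread(path, sep = "\t")))
}

# Two-column TSV with an optional header: the header is recognised only
# when the first line carries the expected column names, so a headerless
# file never loses its first record to fread's auto-detection.
read_two_col <- function(path, col_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- all(col_names %in% first)
  tab <- fread(path, sep = "\t", header = has_header,
               colClasses = "character")
  if (!has_header) setnames(tab, seq_along(col_names), col_names)
  tab
}

#' Read an orthology map
#'
#' Two-column TSV `source_gene  target_gene` (header optional).
#'
#' @param path File path.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path) {
  tab <- read_two_col(path, c("source_gene", "target_gene"))
  orthology_map(tab$source_gene, tab$target_gene)
}

#' Read and write term catalogs
#'
#' Two-column TSV `term  gene`, one row per membership.
#'
#' @param path File path.
#' @return `read_catalog` returns a named list term -> member genes.
#' @export
read_catalog <- function(path) {
  tab <- read_two_col(path, c("term", "gene"))
  lapply(split(tab$gene, tab$term), function(g) sort(unique(g)))
}

#' @param catalog Named list term -> member genes.
#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  tab <- data.frame(term = rep(names(catalog), lengths(catalog)),
                    gene = unlist(catalog, use.names = FALSE))
  fwrite(tab, path, sep = "\t")
  invisible(catalog)
}

#' Read a reference pair set
#'
#' @param pairs_path Two-column TSV of positive gene pairs.
#' @param genes_path One gene per line: the reference's annotated genes.
#' @return A [reference_pair_set()].
#' @export
read_reference_set <- function(pairs_path, genes_path) {
  tab <- read_two_col(pairs_path, c("geneA", "geneB"))
  reference_pair_set(pair_key(tab$geneA, tab$geneB),
                     readLines(genes_path))
}
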