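#' Orthology map between a source and a target species
#'
#' @param source_gene,target_gene Equal-length character vectors; one row
#'   per orthology relation (many-to-many allowed).
#' @param taxon_pair Optional length-2 character vector
#'   `(source taxon, target taxon)`.
#' @return An `orthology_map` (data.table, deduplicated).
#' @export
orthology_map <- function(source_gene, target_gene, taxon_pair = NULL) {
  stopifnot(length(source_gene) == length(target_gene))
  dt <- unique(data.table(source_gene = as.character(source_gene),
                          target_gene = as.character(target_gene)))
  dt <- dt[nzchar(source_gene) & nzchar(target_gene)]
  structure(dt, taxon_pair = taxon_pair,
            class = c("orthology_map", class(dt)))
}

#' Identity orthology map over a gene set
#'
#' @param genes Character vector of gene identifiers.
#' @return An [orthology_map()] mapping every gene to itself.
#' @export
identity_orthology <- function(genes) {
  orthology_map(genes, genes)
}

# Expand source edges through an orthology map; returns a data.table of
# candidate target edges (possibly with duplicates and self-pairs).
expand_orthology <- function(net, om) {
  edges <- data.table(src_a = net$geneA, src_b = net$geneB,
                      weight = net$weight)
  a <- merge(edges, om, by.x = "src_a", by.y = "source_gene",
             allow.cartesian = TRUE)
  setnames(a, "target_gene", "target_a")
  ab <- merge(a, om, by.x = "src_b", by.y = "source_gene",
              allow.cartesian = TRUE)
  setnames(ab, "target_gene", "target_b")
  ab[target_a != target_b]
}

#' Transfer network edges across species (associalogs)
#'
#' A functional link between two source-species genes is transferred to
#' every target-species pair whose members are orthologous to the two
#' endpoints.  When several source edges map onto the same target pair, the
#' maximum source weight is kept (strongest evidence, order-independent).
#' The result is a raw evidence layer: transferred weights are calibrated
#' on the *source* gold standard and must be re-benchmarked against the
#' target gold standard ([benchmark_layer()]) before integration.
#'
#' @param src A source-species [weighted_network()].
#' @param om An [orthology_map()] (source gene -> target genes).
#' @param name Layer tag for the transferred evidence.
#' @return An [evidence_layer()] of transferred scores (empty, with a
#'   warning, when the map is empty).
#' @export
transfer_edges <- function(src, om, name = "associalog") {
  stopifnot(inherits(src, "weighted_network"), inherits(om, "orthology_map"))
  if (!nrow(om)) {
    warning("empty orthology map; no edges transferred")
    return(evidence_layer(character(), character(), numeric(), name = name))
  }
  ab <- expand_orthology(src, om)
  if (!nrow(ab)) {
    return(evidence_layer(character(), character(), numeric(), name = name))
  }
  evidence_layer(ab$target_a, ab$target_b, ab$weight, name = name,
                 higher_is_stronger = TRUE, collapse = "max")
}

#' Project a network to another species by orthology
#'
#' Same expansion semantics as [transfer_edges()], but the result stays a
#' [weighted_network()] with weights carried unchanged -- used to serve an
#' already-integrated network for a related species, where no target gold
#' standard is available for re-calibration.  Self-pairs created by the
#' mapping are dropped; collisions keep the maximum weight.
#'
#' @param net A [weighted_network()].
#' @param om An [orthology_map()].
#' @param name Tag of the projected network.
#' @return A [weighted_network()] over target-species genes.
#' @export
project_network <- function(net, om, name = NULL) {
  stopifnot(inherits(net, "weighted_network"), inherits(om, "orthology_map"))
  name <- name %||% paste0(attr(net, "name") %||% "network", "-projected")
  if (!nrow(om)) {
    warning("empty orthology map; projection is empty")
    return(weighted_network(character(), character(), numeric(), name = name))
  }
  ab <- expand_orthology(net, om)
  weighted_network(ab$target_a, ab$target_b, ab$weight, name = name,
                   collapse = "max")
}
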