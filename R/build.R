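#' Validate a build configuration
#'
#' A build configuration is a named list (or a YAML file) holding input
#' paths and all thresholds of the construction pipeline.  Relative paths
#' are resolved against `base` (the configuration file's directory).
#' Validation checks that every referenced file exists and thresholds are
#' in range, and fills documented defaults.
#'
#' @param config Named list or path to a YAML file.
#' @param base Directory against which relative paths resolve.
#' @return The validated configuration (list) with absolute paths and an
#'   attribute `base`.
#' @export
run_config <- function(config, base = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- base %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base <- base %||% "."
  stopifnot(is.list(config))
  defaults <- list(allowed_codes = RELIABLE_EVIDENCE_CODES,
                   min_term_size = 2L, max_term_size = 300L,
                   min_samples = 12L, retain_threshold = 0.5,
                   top_n_correlations = 100L, profile_bins = 2L,
                   n_bins = 20L, pseudocount = 0.5, min_lls = 1.0,
                   D = 1.0, min_ws = 1.0, seed = 1L)
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  stopifnot(config$min_samples >= 1L, config$n_bins >= 1L,
            config$pseudocount >= 0, config$min_term_size >= 2L,
            config$max_term_size >= config$min_term_size)
  if (!identical(config$D, "grid")) stopifnot(config$D >= 1)
  resolve <- function(p) {
    full <- ifelse(startsWith(p, "/"), p, file.path(base, p))
    missing <- !file.exists(full)
    if (any(missing)) {
      stop("configured input file not found: ", full[missing][1L])
    }
    full
  }
  path_fields <- c("annotations", "expression_manifest", "profiles",
                   "domains", "positions", "neighborhood_orthologs")
  for (nm in path_fields) {
    if (!is.null(config[[nm]])) config[[nm]] <- resolve(config[[nm]])
  }
  if (!is.null(config$source_networks)) {
    config$source_networks <- lapply(config$source_networks, function(sn) {
      sn$network <- resolve(sn$network)
      sn$orthology <- resolve(sn$orthology)
      sn
    })
  }
  attr(config, "base") <- base
  config
}

build_log <- function(report, stage, ...) {
  msg <- sprintf(...)
  message("[", stage, "] ", msg)
  report$log <- c(report$log, paste0("[", stage, "] ", msg))
  report
}

#' Run the full network construction pipeline
#'
#' Executes every construction stage on the inputs named by the
#' configuration: gold standard from annotations; per-dataset
#' co-expression inference with the sample-size and gold-standard-signal
#' filters, integrated into one co-expression component; within-domain
#' phylogenetic-profile component; distance- plus probability-based gene
#' neighborhood component; orthology-transferred components re-benchmarked
#' on the gold standard; and the final weighted-sum integration.  The run
#' is a pure function of (inputs, configuration, seed): repeated runs
#' write byte-identical artifacts.
#'
#' @param config Configuration list or YAML path ([run_config()]).
#' @param out_dir Output directory; when `NULL` nothing is written.
#' @return A `build_result`: list with `network` (the integrated
#'   [weighted_network()]), `components` (named list), `gold_standard`,
#'   `verdicts` (co-expression dataset verdicts), `mappings`, and
#'   `report` (stage-by-stage counts and log lines).
#' @export
run_build <- function(config, out_dir = NULL) {
  cfg <- run_config(config)
  report <- list(log = character(), counts = list(),
                 config = cfg[setdiff(names(cfg), "source_networks")])
  components <- list()
  mappings <- list()

  # --- gold standard -------------------------------------------------
  stage <- "gold_standard"
  records <- tryCatch(
    parse_annotations(cfg$annotations, allowed_codes = cfg$allowed_codes),
    error = function(e) stop("stage ", stage, ": ", conditionMessage(e)))
  gs <- tryCatch(
    build_gold_standard(records, cfg$min_term_size, cfg$max_term_size),
    error = function(e) stop("stage ", stage, ": ", conditionMessage(e)))
  report <- build_log(report, stage,
                      "%d records kept (%d skipped by evidence code); %d terms, %d genes, %d positive pairs",
                      nrow(records), sum(attr(records, "skipped_codes")),
                      length(gs$term_index), length(gs$universe),
                      length(gs$positives))
  report$counts$gold_standard <- list(records = nrow(records),
                                      terms = length(gs$term_index),
                                      genes = length(gs$universe),
                                      positives = length(gs$positives))

  # --- co-expression -------------------------------------------------
  verdicts <- list()
  if (!is.null(cfg$expression_manifest)) {
    stage <- "coexpression"
    manifest <- fread(cfg$expression_manifest, sep = "\t")
    cx_nets <- list()
    for (i in seq_len(nrow(manifest))) {
      id <- as.character(manifest$id[i])
      path <- manifest$path[i]
      if (!startsWith(path, "/")) {
        path <- file.path(dirname(cfg$expression_manifest), path)
      }
      if (!file.exists(path)) {
        stop("stage ", stage, ": expression file not found: ", path)
      }
      ds <- read_expression(path, id = id)
      layer <- correlate(ds, min_samples = cfg$min_samples,
                         top_n = cfg$top_n_correlations)
      verdict <- evaluate_dataset(layer, gs,
                                  retain_threshold = cfg$retain_threshold,
                                  id = id, n_bins = cfg$n_bins,
                                  pseudocount = cfg$pseudocount)
      verdicts[[id]] <- verdict
      report <- build_log(report, stage,
                          "dataset %s: %d samples, passed_size=%s, best_bin_lls=%s, retained=%s",
                          id, ds$sample_count, verdict$passed_size,
                          if (is.na(verdict$best_bin_lls)) "NA" else
                            sprintf("%.3f", verdict$best_bin_lls),
                          verdict$retained)
      if (verdict$retained) {
        cx_nets[[id]] <- suppressWarnings(
          apply_mapping(layer, verdict$mapping, min_lls = cfg$min_lls))
        mappings[[paste0("CX:", id)]] <- verdict$mapping
      }
    }
    if (length(cx_nets)) {
      components[["MM-CX"]] <- integrate_coexpression(
        cx_nets, D = if (identical(cfg$D, "grid")) 1 else cfg$D,
        name = "MM-CX")
      report <- build_log(report, stage,
                          "MM-CX: %d datasets retained of %d; %d edges",
                          length(cx_nets), nrow(manifest),
                          nrow(components[["MM-CX"]]))
    }
    report$counts$coexpression <- list(
      tested = nrow(manifest), retained = length(cx_nets),
      edges = if (length(cx_nets)) nrow(components[["MM-CX"]]) else 0L)
  }

  # --- phylogenetic profiles -----------------------------------------
  if (!is.null(cfg$profiles)) {
    stage <- "phylo_profile"
    prof <- read_profiles(cfg$profiles, cfg$domains)
    lay <- profile_layer(prof, gs, n_bins = cfg$profile_bins,
                         n_lls_bins = cfg$n_bins,
                         pseudocount = cfg$pseudocount)
    components[["MM-PG"]] <- lls_layer_to_network(lay,
                                                  min_lls = cfg$min_lls)
    report <- build_log(report, stage, "MM-PG: %d edges at min_lls %.2f",
                        nrow(components[["MM-PG"]]), cfg$min_lls)
    report$counts$phylo_profile <- list(edges = nrow(components[["MM-PG"]]))
  }

  # --- gene neighborhood ---------------------------------------------
  if (!is.null(cfg$positions)) {
    stage <- "gene_neighborhood"
    pos <- read_positions(cfg$positions)
    orth <- as.data.frame(fread(cfg$neighborhood_orthologs, sep = "\t"))
    target_genes <- sort(unique(orth$gene))
    cmb <- utils::combn(target_genes, 2L)
    layers <- neighborhood_scores(pos, data.frame(a = cmb[1L, ],
                                                  b = cmb[2L, ]), orth)
    components[["MM-GN"]] <- context_layer(
      layers$dist_layer, layers$prob_layer, gs,
      D = if (identical(cfg$D, "grid")) 1 else cfg$D,
      min_lls = cfg$min_lls, n_bins = cfg$n_bins,
      pseudocount = cfg$pseudocount)
    report <- build_log(report, stage,
                        "MM-GN: %d scored pairs -> %d edges",
                        nrow(layers$dist_layer),
                        nrow(components[["MM-GN"]]))
    report$counts$gene_neighborhood <- list(
      scored_pairs = nrow(layers$dist_layer),
      edges = nrow(components[["MM-GN"]]))
  }

  # --- associalog transfer -------------------------------------------
  for (sn in cfg$source_networks %||% list()) {
    stage <- paste0("associalog:", sn$name)
    src <- read_network(sn$network)
    om <- read_orthology(sn$orthology)
    lay <- transfer_edges(src, om, name = sn$name)
    if (!nrow(lay)) {
      report <- build_log(report, stage, "no transferable edges")
      next
    }
    mapping <- benchmark_layer(lay, gs, n_bins = cfg$n_bins,
                               pseudocount = cfg$pseudocount)
    mappings[[sn$name]] <- mapping
    components[[sn$name]] <- suppressWarnings(
      apply_mapping(lay, mapping, min_lls = cfg$min_lls))
    report <- build_log(report, stage, "%d transferred pairs -> %d edges",
                        nrow(lay), nrow(components[[sn$name]]))
    report$counts[[stage]] <- list(transferred = nrow(lay),
                                   edges = nrow(components[[sn$name]]))
  }

  if (!length(components)) stop("no component network could be built")

  # --- integration ---------------------------------------------------
  stage <- "integration"
  D <- cfg$D
  if (identical(D, "grid")) {
    grid <- cfg$D_grid %||% c(1, 1.5, 2, 3, 4)
    D <- as.numeric(grid_search_D(components, gs, grid = grid,
                                  seed = cfg$seed))
    report <- build_log(report, stage, "grid search selected D = %.2f", D)
  }
  net <- integrate_networks(
    components,
    config = integration_config(D = D, min_component_lls = cfg$min_lls,
                                min_ws = cfg$min_ws),
    name = "integrated", provenance = TRUE)
  report <- build_log(report, stage,
                      "integrated network: %d genes, %d links from %d components",
                      length(network_nodes(net)), nrow(net),
                      length(components))
  report$counts$integrated <- list(genes = length(network_nodes(net)),
                                   links = nrow(net),
                                   components = length(components))

  out <- list(network = net, components = components, gold_standard = gs,
              verdicts = verdicts, mappings = mappings, report = report)
  class(out) <- "build_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "components"), showWarnings = FALSE)
    write_network(net, file.path(out_dir, "network.tsv"))
    for (nm in names(components)) {
      write_network(components[[nm]],
                    file.path(out_dir, "components",
                              paste0(nm, ".tsv")))
    }
    if (length(verdicts)) {
      vt <- data.frame(
        id = vapply(verdicts, `[[`, character(1L), "id"),
        passed_size = vapply(verdicts, `[[`, logical(1L), "passed_size"),
        best_bin_lls = vapply(verdicts, `[[`, numeric(1L), "best_bin_lls"),
        retained = vapply(verdicts, `[[`, logical(1L), "retained"),
        reason = vapply(verdicts, `[[`, character(1L), "reason"))
      fwrite(vt, file.path(out_dir, "dataset_verdicts.tsv"), sep = "\t")
    }
    yaml::write_yaml(report["counts"], file.path(out_dir, "report.yaml"))
    writeLines(report$log, file.path(out_dir, "build.log"))
  }
  out
}

#' @export
print.build_result <- function(x, ...) {
  cat("<build_result>\n")
  cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  cat(sprintf("  integrated: %d genes, %d links\n",
              length(network_nodes(x$network)), nrow(x$network)))
  invisible(x)
}
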