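#' Create a synthetic world with planted co-functional modules
#'
#' The package's test-bed generator: a gene universe in which `k` disjoint
#' modules of `m` genes each are planted as truly co-functional, on a
#' background of unrelated genes.  Every downstream input generator (
#' expression, phylogenetic profiles, gene positions, source-species
#' network, annotations, reference sets) endows within-module pairs with
#' recoverable signal at the world's parameter levels, so each evidence
#' layer and the full pipeline can be exercised end to end without any
#' external download.
#'
#' Defaults: 10 modules of 10 genes on 100 background genes, within-module
#' expression correlation 0.8 (strongly co-regulated pathways), 10% profile
#' flip noise, 50% of prokaryotic genomes clustering a module's genes
#' (operon-like), 10% spurious source-network edges.
#'
#' @param k Number of planted modules.
#' @param m Genes per module.
#' @param n_background Background (unplanted) genes.
#' @param rho Target within-module expression correlation in `[0, 1]`.
#' @param profile_noise Per-genome flip probability of a module's
#'   inheritance pattern.
#' @param neighborhood_rate Fraction of prokaryotic genomes in which a
#'   module's genes sit in one chromosomal block.
#' @param edge_noise Spurious source-network edges, as a fraction of the
#'   planted edge count.
#' @param seed Integer seed; the world is a pure function of its
#'   parameters and seed.
#' @return A `planted_world`: list with `genes`, `modules` (named list of
#'   disjoint gene sets), `background`, `params`, `seed`.
#' @export
make_world <- function(k = 10L, m = 10L, n_background = 100L, rho = 0.8,
                       profile_noise = 0.1, neighborhood_rate = 0.5,
                       edge_noise = 0.1, seed = 1L) {
  stopifnot(k >= 0L, m >= 2L || k == 0L, n_background >= 0L,
            rho >= 0 && rho <= 1, profile_noise >= 0 && profile_noise <= 1,
            neighborhood_rate >= 0 && neighborhood_rate <= 1,
            edge_noise >= 0)
  n_mod_genes <- k * m
  if (n_mod_genes + n_background < 2L) stop("world needs at least 2 genes")
  mod_genes <- if (n_mod_genes) sprintf("G%04d", seq_len(n_mod_genes))
               else character()
  bg_genes <- if (n_background) sprintf("B%04d", seq_len(n_background))
              else character()
  modules <- if (k) {
    setNames(split(mod_genes, rep(seq_len(k), each = m)),
             sprintf("MOD%02d", seq_len(k)))
  } else {
    list()
  }
  out <- list(genes = c(mod_genes, bg_genes), modules = modules,
              background = bg_genes,
              params = list(k = k, m = m, n_background = n_background,
                            rho = rho, profile_noise = profile_noise,
                            neighborhood_rate = neighborhood_rate,
                            edge_noise = edge_noise),
              seed = as.integer(seed))
  class(out) <- "planted_world"
  out
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf(
    "<planted_world: %d genes (%d modules x %d + %d background), seed %d>\n",
    length(x$genes), x$params$k, x$params$m, x$params$n_background, x$seed))
  invisible(x)
}

# All within-module canonical pair keys of a world.
world_module_pairs <- function(world) {
  unlist(lapply(world$modules, function(g) {
    cmb <- utils::combn(g, 2L)
    pair_key(cmb[1L, ], cmb[2L, ])
  }), use.names = FALSE)
}

#' Synthetic annotation records
#'
#' Each module is one annotation term; member genes are annotated with a
#' reliable evidence code.  A sprinkle of computationally-inferred (IEA)
#' records to decoy terms, and duplicate records, exercise the
#' evidence-code filter and deduplication.
#'
#' @param world A `planted_world`.
#' @return Data frame with columns `gene`, `term`, `evidence_code`,
#'   `source`.
#' @export
sim_annotations <- function(world) {
  with_seed(child_seed(world$seed, 11L), {
    recs <- do.call(rbind, lapply(names(world$modules), function(mod) {
      genes <- world$modules[[mod]]
      data.frame(gene = genes, term = mod,
                 evidence_code = sample(RELIABLE_EVIDENCE_CODES,
                                        length(genes), replace = TRUE),
                 source = "GOBP-like")
    }))
    # unreliable computational annotations that the filter must drop
    n_iea <- max(1L, length(world$genes) %/% 10L)
    iea <- data.frame(gene = sample(world$genes, n_iea, replace = TRUE),
                      term = "IEA_TERM",
                      evidence_code = "IEA", source = "GOBP-like")
    dup <- recs[seq_len(min(3L, nrow(recs))), , drop = FALSE]
    out <- rbind(recs, iea, dup)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic expression dataset
#'
#' Module genes follow a shared latent factor model
#' `x = sqrt(rho) * f_module + sqrt(1 - rho) * eps` so the expected
#' within-module Pearson correlation equals the world's `rho`; background
#' genes are independent noise.
#'
#' @param world A `planted_world`.
#' @param n_samples Number of samples (columns).
#' @param id Dataset tag.
#' @param stream Seed stream offset (vary to obtain independent datasets).
#' @return An [expression_dataset()].
#' @export
sim_expression <- function(world, n_samples = 20L, id = "DS1",
                           stream = 20L) {
  rho <- world$params$rho
  with_seed(child_seed(world$seed, stream), {
    mat <- matrix(rnorm(length(world$genes) * n_samples),
                  nrow = length(world$genes),
                  dimnames = list(world$genes,
                                  sprintf("S%03d", seq_len(n_samples))))
    for (mod in names(world$modules)) {
      f <- rnorm(n_samples)
      genes <- world$modules[[mod]]
      mat[genes, ] <- sqrt(rho) * matrix(f, length(genes), n_samples,
                                         byrow = TRUE) +
        sqrt(1 - rho) * mat[genes, ]
    }
    expression_dataset(mat, id = id)
  })
}

#' Synthetic phylogenetic profiles over two domains
#'
#' Each module draws one presence/absence inheritance pattern per domain
#' (presence probability 0.5 per genome); member genes copy the module
#' pattern with per-genome flip probability `profile_noise`.  Background
#' genes draw independent patterns, so their pairwise co-inheritance is
#' chance-level.
#'
#' @param world A `planted_world`.
#' @param genomes_per_domain Named integer vector: domain -> genome count.
#' @return A [phylo_profile()] with binary values.
#' @export
sim_profiles <- function(world,
                         genomes_per_domain = c(bacteria = 60L,
                                                eukaryota = 60L)) {
  noise <- world$params$profile_noise
  with_seed(child_seed(world$seed, 31L), {
    domains <- rep(names(genomes_per_domain), genomes_per_domain)
    genomes <- sprintf("%s_%03d", domains,
                       unlist(lapply(genomes_per_domain, seq_len)))
    names(domains) <- genomes
    mat <- matrix(0, length(world$genes), length(genomes),
                  dimnames = list(world$genes, genomes))
    for (g in world$background) {
      mat[g, ] <- rbinom(length(genomes), 1L, 0.5)
    }
    for (mod in names(world$modules)) {
      pattern <- rbinom(length(genomes), 1L, 0.5)
      for (g in world$modules[[mod]]) {
        flip <- rbinom(length(genomes), 1L, noise) == 1L
        v <- pattern
        v[flip] <- 1L - v[flip]
        mat[g, ] <- v
      }
    }
    phylo_profile(mat, domains)
  })
}

#' Synthetic prokaryotic gene positions and ortholog map
#'
#' Every genome carries one circular chromosome holding an ortholog of
#' each world gene in random order; with probability `neighborhood_rate`
#' (per module and genome) a module's orthologs are packed into one
#' contiguous block, emulating operon-like organization.
#'
#' @param world A `planted_world`.
#' @param n_genomes Number of prokaryotic genomes.
#' @return List with `positions` (a [gene_position_table()]) and
#'   `orthologs` (data frame `gene`, `genome`, `ortholog`; identity
#'   naming).
#' @export
sim_positions <- function(world, n_genomes = 40L) {
  rate <- world$params$neighborhood_rate
  with_seed(child_seed(world$seed, 41L), {
    rows <- vector("list", n_genomes)
    for (gi in seq_len(n_genomes)) {
      genome <- sprintf("PK%03d", gi)
      ord <- sample(world$genes)
      for (mod in names(world$modules)) {
        if (runif(1L) < rate) {
          genes <- world$modules[[mod]]
          ord <- ord[!ord %in% genes]
          at <- sample.int(length(ord) + 1L, 1L)
          ord <- append(ord, sample(genes), after = at - 1L)
        }
      }
      rows[[gi]] <- data.frame(genome = genome, gene = ord, chrom = "c1",
                               index = seq_along(ord) - 1L, strand = "+")
    }
    pos <- do.call(rbind, rows)
    orth <- pos[, c("gene", "genome")]
    orth$ortholog <- orth$gene
    list(positions = gene_position_table(pos), orthologs = orth)
  })
}

#' Synthetic source-species network and orthology map
#'
#' A source-species functional network encoding the world's planted
#' modules: every within-module pair is linked with an LLS-like weight in
#' `[2, 4]`, plus `edge_noise x |planted pairs|` spurious random edges
#' with weights in `[0.5, 1.5]`.  Source genes are named `s_<gene>` and a
#' one-to-one orthology map connects them to the world's genes.
#'
#' @param world A `planted_world`.
#' @return List with `network` (a [weighted_network()] over source genes)
#'   and `orthology` (an [orthology_map()] source -> target).
#' @export
sim_source_network <- function(world) {
  edge_noise <- world$params$edge_noise
  with_seed(child_seed(world$seed, 53L), {
    keys <- world_module_pairs(world)
    planted <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    if (is.null(planted)) {
      planted <- matrix(character(), ncol = 2L)
    }
    wa <- paste0("s_", planted[, 1L])
    wb <- paste0("s_", planted[, 2L])
    wt <- runif(nrow(planted), 2, 4)
    n_noise <- round(edge_noise * nrow(planted))
    if (n_noise > 0L) {
      na_ <- paste0("s_", sample(world$genes, n_noise, replace = TRUE))
      nb_ <- paste0("s_", sample(world$genes, n_noise, replace = TRUE))
      keep <- na_ != nb_
      wa <- c(wa, na_[keep])
      wb <- c(wb, nb_[keep])
      wt <- c(wt, runif(sum(keep), 0.5, 1.5))
    }
    list(network = weighted_network(wa, wb, wt, name = "source-net"),
         orthology = orthology_map(paste0("s_", world$genes), world$genes))
  })
}

#' Synthetic term catalog with decoy terms
#'
#' The planted module terms plus `n_decoys` decoy gene sets drawn from the
#' background genes -- unrelated pathway-like terms, disjoint from the
#' planted modules, so each module gene has exactly one true catalog term.
#' The mixture is what a function-inference search has to discriminate.
#'
#' @param world A `planted_world`.
#' @param n_decoys Number of random decoy terms.
#' @param decoy_size Genes per decoy term.
#' @return Named list: term -> member genes.
#' @export
sim_catalog <- function(world, n_decoys = 90L, decoy_size = 10L) {
  pool <- if (length(world$background) >= decoy_size) world$background
          else world$genes
  with_seed(child_seed(world$seed, 61L), {
    decoys <- setNames(lapply(seq_len(n_decoys), function(i) {
      sort(sample(pool, decoy_size))
    }), sprintf("DECOY%03d", seq_len(n_decoys)))
    c(world$modules, decoys)
  })
}

#' Synthetic reference pair sets
#'
#' Two assessment references built from disjoint halves of the planted
#' modules, standing in for independent complex- and disease-derived pair
#' catalogs.
#'
#' @param world A `planted_world`.
#' @return Named list of [reference_pair_set()]s (`complexes`,
#'   `diseases`).
#' @export
sim_reference_sets <- function(world) {
  k <- world$params$k
  if (k < 2L) stop("reference sets need at least 2 planted modules")
  first <- names(world$modules)[seq_len(ceiling(k / 2))]
  second <- setdiff(names(world$modules), first)
  build <- function(mods) {
    genes <- sort(unique(unlist(world$modules[mods])))
    keys <- unlist(lapply(world$modules[mods], function(g) {
      cmb <- utils::combn(g, 2L)
      pair_key(cmb[1L, ], cmb[2L, ])
    }), use.names = FALSE)
    reference_pair_set(keys, genes)
  }
  list(complexes = build(first), diseases = build(second))
}

#' Synthetic query gene sets for null-comparison analyses
#'
#' Random subsets (5-8 genes) of randomly chosen planted modules --
#' phenotype-like gene sets whose members are truly interconnected.
#'
#' @param world A `planted_world`.
#' @param n_sets Number of sets.
#' @return Named list of gene vectors.
#' @export
sim_gene_sets <- function(world, n_sets = 50L) {
  stopifnot(world$params$k >= 1L)
  with_seed(child_seed(world$seed, 71L), {
    setNames(lapply(seq_len(n_sets), function(i) {
      mod <- sample(names(world$modules), 1L)
      genes <- world$modules[[mod]]
      size <- sample(5:min(8L, length(genes)), 1L)
      sort(sample(genes, size))
    }), sprintf("SET%03d", seq_len(n_sets)))
  })
}

#' Write every synthetic input of a world to disk
#'
#' Emits, in the package's declared plain-text formats, everything a full
#' build consumes: annotations, three expression datasets (20, 12 and 11
#' samples -- the last deliberately below the co-expression size filter),
#' phylogenetic profiles over two domains with a genome-domain table,
#' prokaryotic gene positions with an ortholog table, a source-species
#' network with its orthology map, a term catalog, and reference pair
#' sets.  A ready-to-run build configuration pointing at the emitted files
#' is written as `config.yaml`.
#'
#' @param world A `planted_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the emitted file paths.
#' @export
emit_inputs <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  paths <- list()

  ann <- sim_annotations(world)
  paths$annotations <- p("annotations.tsv")
  fwrite(ann, paths$annotations, sep = "\t")

  specs <- list(DS1 = list(n = 20L, stream = 21L),
                DS2 = list(n = 12L, stream = 22L),
                DS3 = list(n = 11L, stream = 23L))
  manifest <- data.frame(id = character(), path = character())
  for (id in names(specs)) {
    ds <- sim_expression(world, n_samples = specs[[id]]$n, id = id,
                         stream = specs[[id]]$stream)
    f <- p(sprintf("expr_%s.tsv", id))
    write_expression(ds, f)
    manifest <- rbind(manifest, data.frame(id = id, path = basename(f)))
    paths[[paste0("expr_", id)]] <- f
  }
  paths$expression_manifest <- p("expression_manifest.tsv")
  fwrite(manifest, paths$expression_manifest, sep = "\t")

  prof <- sim_profiles(world)
  paths$profiles <- p("profiles.tsv")
  paths$domains <- p("domains.tsv")
  write_profiles(prof, paths$profiles, paths$domains)

  posorth <- sim_positions(world)
  paths$positions <- p("positions.tsv")
  fwrite(as.data.frame(posorth$positions), paths$positions, sep = "\t")
  paths$neighborhood_orthologs <- p("neighborhood_orthologs.tsv")
  fwrite(posorth$orthologs, paths$neighborhood_orthologs, sep = "\t")

  src <- sim_source_network(world)
  paths$source_network <- p("source_network.tsv")
  write_network(src$network, paths$source_network)
  paths$source_orthology <- p("source_orthology.tsv")
  fwrite(data.frame(source_gene = src$orthology$source_gene,
                    target_gene = src$orthology$target_gene),
         paths$source_orthology, sep = "\t")

  catalog <- sim_catalog(world)
  paths$catalog <- p("catalog.tsv")
  write_catalog(catalog, paths$catalog)

  refs <- sim_reference_sets(world)
  for (nm in names(refs)) {
    pair_f <- p(sprintf("reference_%s_pairs.tsv", nm))
    gene_f <- p(sprintf("reference_%s_genes.txt", nm))
    mat <- do.call(rbind, strsplit(refs[[nm]]$positives, "\t", fixed = TRUE))
    fwrite(data.frame(geneA = mat[, 1L], geneB = mat[, 2L]), pair_f,
           sep = "\t")
    writeLines(refs[[nm]]$annotated_genes, gene_f)
    paths[[paste0("reference_", nm, "_pairs")]] <- pair_f
    paths[[paste0("reference_", nm, "_genes")]] <- gene_f
  }

  cfg <- list(
    annotations = "annotations.tsv",
    allowed_codes = RELIABLE_EVIDENCE_CODES,
    min_term_size = 2L, max_term_size = 300L,
    expression_manifest = "expression_manifest.tsv",
    min_samples = 12L, retain_threshold = 0.5, top_n_correlations = 100L,
    profiles = "profiles.tsv", domains = "domains.tsv",
    profile_bins = 2L,
    positions = "positions.tsv",
    neighborhood_orthologs = "neighborhood_orthologs.tsv",
    source_networks = list(list(name = "HS-TR",
                                network = "source_network.tsv",
                                orthology = "source_orthology.tsv")),
    n_bins = 20L, pseudocount = 0.5, min_lls = 1.0,
    D = 1.0, min_ws = 1.0,
    genome_size = length(world$genes),
    seed = world$seed)
  paths$config <- p("config.yaml")
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
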