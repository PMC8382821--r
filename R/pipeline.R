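#' Pipeline configuration
#'
#' Collects every tunable of the full run. Accepts a YAML/JSON file path
#' or named arguments; unknown keys are rejected before any compute.
#'
#' @param ... named settings, or a single unnamed string naming a
#'   YAML/JSON config file. Recognised keys and defaults:
#'   `rng_seed` (1), `identity_thresholds` (40, 50, 60, 70),
#'   `evalue_cutoff` (1e-5), `window` (3), `cooccurrence` (0.2),
#'   `min_genus_count` (5), `mismatch_budget` (0), `schema`
#'   (activity-schema override as a named list), `synthetic`
#'   (list of [synthetic_config()] arguments for the simulated input).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      is.character(args[[1]])) {
    path <- args[[1]]
    args <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  defaults <- list(
    rng_seed = 1L,
    identity_thresholds = c(40, 50, 60, 70),
    evalue_cutoff = 1e-5,
    window = 3L,
    cooccurrence = 0.20,
    min_genus_count = 5L,
    mismatch_budget = 0L,
    schema = NULL,
    synthetic = list()
  )
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, args)
  stopifnot(cfg$evalue_cutoff > 0, cfg$window >= 1,
            cfg$cooccurrence >= 0, cfg$cooccurrence <= 1,
            all(cfg$identity_thresholds >= 0),
            all(cfg$identity_thresholds <= 100))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full discovery pipeline on a synthetic dataset
#'
#' Simulate -> align -> SSN (threshold sweep) -> colour -> detect 3GCs
#' (aminotransferase- and dehydrogenase-focal, unioned) -> consensus
#' screen -> gene tree, writing every stage product plus a
#' machine-readable manifest into `out_dir`. Rerunning with the same
#' config reproduces identical non-log outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; pre-existing files are
#'   overwritten).
#' @return list with the in-memory stage results (`dataset`, `hits`,
#'   `sweep`, `network`, `clusters_at`, `clusters_dh`, `producers`,
#'   `merged`, `screen`, `tree`, `manifest`), invisibly; files under
#'   `out_dir` are the primary product.
#' @export
run_full <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  schema <- if (is.null(config$schema)) activity_schema() else
    do.call(activity_schema, config$schema)

  dataset <- stage("simulate", {
    syn_args <- config$synthetic
    syn_args$rng_seed <- syn_args$rng_seed %||% config$rng_seed
    ds <- generate_dataset(do.call(synthetic_config, syn_args))
    write_dataset(ds, file.path(out_dir, "synthetic"))
    ds
  })

  ## SSN over the planted focal enzymes plus decoy look-alikes: all
  ## proteins annotated with a schema family
  focal <- stage("align", {
    keep <- unlist(lapply(dataset$genomes, function(g) {
      g$features$protein_id[vapply(g$features$families, function(f)
        any(f %in% unlist(schema)), logical(1))]
    }))
    dataset$proteome[dataset$proteome$protein_id %in% keep, ,
                     drop = FALSE]
  })
  hits <- stage("align", {
    h <- all_vs_all(focal, evalue_cutoff = config$evalue_cutoff)
    write_hits(h, file.path(out_dir, "hits.tsv"))
    h
  })

  sweep <- stage("ssn", {
    sw <- threshold_sweep(hits, config$identity_thresholds,
                          proteins = focal)
    utils::write.table(sw[, c("threshold", "n_clusters", "n_singletons")],
                       file.path(out_dir, "threshold_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sw
  })

  network <- stage("color", {
    net <- build_network(hits,
                         list(metric = "percent_identity",
                              value = min(config$identity_thresholds)),
                         focal)
    net <- cluster_network(net)
    net <- color_nodes(net, dataset$genomes, focal, schema,
                       config$window)
    write_network(net, file.path(out_dir, "ssn_colored.graphml"),
                  "graphml")
    co <- cluster_cooccurrence(net, dataset$genomes, focal,
                               config$window, config$cooccurrence)
    utils::write.table(co, file.path(out_dir, "cooccurrence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    net
  })

  clusters_at <- stage("detect", {
    cl <- find_3gc(dataset$genomes, schema, "aminotransferase",
                   config$window)
    write_gc3_table(cl, file.path(out_dir, "gc3_at.tsv"))
    cl
  })
  clusters_dh <- stage("detect", {
    cl <- find_3gc(dataset$genomes, schema, "dehydrogenase",
                   config$window)
    write_gc3_table(cl, file.path(out_dir, "gc3_dh.tsv"))
    cl
  })
  merged <- stage("detect", {
    m <- merge_hit_sets(at_ssn = unique(clusters_at$genome_id),
                        dh_ssn = unique(clusters_dh$genome_id))
    m
  })
  producers <- stage("detect", {
    tabulate_producers(clusters_at, config$min_genus_count)
  })

  screen <- stage("screen", {
    sc <- screen_and_validate(dataset$proteome, aza_at_motif(),
                              clusters_at, config$mismatch_budget)
    utils::write.table(sc$hits, file.path(out_dir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })

  tree <- stage("tree", {
    at_ids <- dataset$proteome$source_gene %in% clusters_at$at_feature
    at_prot <- dataset$proteome[at_ids, , drop = FALSE]
    if (nrow(at_prot) >= 3L) {
      msa <- progressive_msa(at_prot)
      tr <- neighbor_joining(p_distance(msa))
      write_newick(tr, file.path(out_dir, "at_gene_tree.nwk"))
      tr
    } else NULL
  })

  manifest <- stage("manifest", {
    man <- list(
      package = "azamine",
      version = as.character(utils::packageVersion("azamine")),
      rng_seed = config$rng_seed,
      parameters = config[setdiff(names(config), "schema")],
      inputs = list(
        synthetic_genomes = length(dataset$genomes),
        proteome_md5 = unname(tools::md5sum(
          file.path(out_dir, "synthetic", "proteome.fasta")))
      ),
      n_3gc_at = nrow(clusters_at),
      n_3gc_dh = nrow(clusters_dh),
      n_merged_producers = nrow(merged)
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })

  invisible(list(dataset = dataset, hits = hits, sweep = sweep,
                 network = network, clusters_at = clusters_at,
                 clusters_dh = clusters_dh, producers = producers,
                 merged = merged, screen = screen, tree = tree,
                 manifest = manifest))
}
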