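#' Activity-to-family schema
#'
#' Maps the three cluster activities to their protein family accessions.
#' Defaults: aminotransferase PF00202; dehydrogenase PF00107, PF08240,
#' PF16912; phosphatase PF13419, PF00459, PF12710, PF07081. The
#' phosphatase families split into two classes: inositol phosphatase
#' (PF00459) and HAD hydrolase (PF13419, PF12710, PF07081).
#'
#' @param aminotransferase,dehydrogenase,phosphatase character vectors of
#'   family accessions; the three sets must be pairwise disjoint and
#'   non-empty.
#' @return a named list of class `activity_schema`.
#' @export
activity_schema <- function(
    aminotransferase = "PF00202",
    dehydrogenase = c("PF00107", "PF08240", "PF16912"),
    phosphatase = c("PF13419", "PF00459", "PF12710", "PF07081")) {
  schema <- list(aminotransferase = aminotransferase,
                 dehydrogenase = dehydrogenase,
                 phosphatase = phosphatase)
  if (any(lengths(schema) == 0L)) {
    stop("every activity needs at least one family", call. = FALSE)
  }
  all_fams <- unlist(schema)
  if (anyDuplicated(all_fams)) {
    stop("activity family sets must be pairwise disjoint", call. = FALSE)
  }
  structure(schema, class = c("activity_schema", "list"))
}

## Phosphatase class of a set of family accessions.
phosphatase_class_of <- function(families) {
  has_ino <- "PF00459" %in% families
  has_had <- any(c("PF13419", "PF12710", "PF07081") %in% families)
  if (has_ino && has_had) "both"
  else if (has_ino) "inositol_phosphatase"
  else if (has_had) "HAD_hydrolase"
  else "none"
}

#' Extract the +/- w ORF neighborhood of a gene
#'
#' Neighbors are the `window` ORFs on each side of the focal gene in
#' start-coordinate rank order on its contig, strand-agnostic. The window
#' truncates at the ends of a linear contig and wraps around a circular
#' one without duplicating features. Neighborhoods never cross contig
#' boundaries.
#'
#' @param genome a [genome_record()].
#' @param focal_feature_id feature id of the focal gene.
#' @param window ORFs on each side (>= 1; default 3).
#' @return list of class `neighborhood_profile` with `focal_feature_id`,
#'   `window`, and `neighbors` (data frame with an `offset` column in
#'   `-w..w`, offset 0 excluded, plus the feature columns).
#' @export
extract_neighborhood <- function(genome, focal_feature_id, window = 3L) {
  stopifnot(inherits(genome, "genome_record"), window >= 1L)
  ft <- genome$features
  i <- match(focal_feature_id, ft$feature_id)
  if (is.na(i)) {
    stop("unknown feature: ", focal_feature_id, call. = FALSE)
  }
  contig <- ft$contig_id[i]
  circular <- genome$contigs$circular[
    match(contig, genome$contigs$contig_id)]
  on_contig <- which(ft$contig_id == contig)  # already in rank order
  rank <- match(i, on_contig)
  n <- length(on_contig)
  offsets <- setdiff(seq(-window, window), 0L)
  rows <- lapply(offsets, function(o) {
    j <- rank + o
    if (circular) {
      j <- ((j - 1L) %% n) + 1L
      if (j == rank) return(NULL)      # wrapped onto the focal gene
    } else if (j < 1L || j > n) {
      return(NULL)
    }
    cbind(offset = o, ft[on_contig[j], , drop = FALSE])
  })
  ## circular wrap: drop duplicate features, keeping the smaller |offset|
  nb <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(nb) && nrow(nb)) {
    keep <- order(abs(nb$offset), nb$offset)
    nb <- nb[keep, , drop = FALSE]
    nb <- nb[!duplicated(nb$feature_id), , drop = FALSE]
    nb <- nb[order(nb$offset), , drop = FALSE]
    rownames(nb) <- NULL
  } else {
    nb <- cbind(offset = integer(), empty_features())
  }
  structure(list(focal_feature_id = focal_feature_id,
                 window = as.integer(window), neighbors = nb),
            class = "neighborhood_profile")
}

## Map SSN nodes to genes: proteins carry source_gene ids; genomes are
## searched by protein_id first, then feature_id.
locate_protein <- function(protein_id, source_gene, genomes) {
  for (g in genomes) {
    ft <- g$features
    j <- match(protein_id, ft$protein_id)
    if (is.na(j) && !is.na(source_gene)) {
      j <- match(source_gene, ft$feature_id)
    }
    if (!is.na(j)) return(list(genome = g, feature_id = ft$feature_id[j]))
  }
  NULL
}

#' Colour SSN nodes with neighborhood family content
#'
#' For each node, finds its encoding gene, extracts the +/- window ORF
#' neighborhood, and records which activities of the schema are present
#' and the phosphatase class (`inositol_phosphatase`, `HAD_hydrolase`,
#' `both` -- reported with a warning -- or `none`). Nodes without a
#' genomic mapping are flagged `unmapped`, never dropped.
#'
#' @param net an `ssn` (clustered or not).
#' @param genomes list of [genome_record()].
#' @param proteins the [protein_set()] behind the nodes (for source-gene
#'   links).
#' @param schema an [activity_schema()].
#' @param window neighborhood size in ORFs (default 3).
#' @return the network with node columns `activities` (list column),
#'   `phosphatase_class` and `unmapped` added.
#' @export
color_nodes <- function(net, genomes, proteins = NULL,
                        schema = activity_schema(), window = 3L) {
  stopifnot(inherits(net, "ssn"))
  nodes <- net$nodes
  src <- if (!is.null(proteins)) {
    proteins$source_gene[match(nodes$protein_id, proteins$protein_id)]
  } else rep(NA_character_, nrow(nodes))
  acts <- vector("list", nrow(nodes))
  ph <- character(nrow(nodes))
  unmapped <- logical(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    loc <- locate_protein(nodes$protein_id[i], src[i], genomes)
    if (is.null(loc)) {
      unmapped[i] <- TRUE
      acts[[i]] <- character()
      ph[i] <- "none"
      next
    }
    nb <- extract_neighborhood(loc$genome, loc$feature_id, window)
    fams <- unique(unlist(nb$neighbors$families))
    present <- names(schema)[vapply(schema, function(f)
      any(f %in% fams), logical(1))]
    acts[[i]] <- present
    ph[i] <- phosphatase_class_of(fams)
    if (ph[i] == "both") {
      warning("node ", nodes$protein_id[i],
              ": neighborhood contains both phosphatase classes",
              call. = FALSE)
    }
  }
  nodes$activities <- acts
  nodes$phosphatase_class <- ph
  nodes$unmapped <- unmapped
  net$nodes <- nodes
  net
}

#' Per-cluster family co-occurrence (GNN summary)
#'
#' For every cluster, the fraction of its nodes whose +/- window ORF
#' neighborhood contains at least one gene of each family. Families at or
#' above the reporting threshold (default 20%) form the summary; the full
#' table retains every family.
#'
#' @param net a clustered, coloured `ssn`.
#' @param genomes list of [genome_record()].
#' @param proteins the [protein_set()] behind the nodes.
#' @param window neighborhood size in ORFs.
#' @param threshold reporting threshold on the co-occurrence fraction.
#' @return a `data.frame` with columns `cluster_id`, `family`, `fraction`,
#'   `reported` (fraction >= threshold).
#' @export
cluster_cooccurrence <- function(net, genomes, proteins = NULL,
                                 window = 3L, threshold = 0.20) {
  stopifnot(inherits(net, "ssn"))
  nodes <- net$nodes
  if (all(is.na(nodes$cluster_id))) {
    stop("network has no clusters; run cluster_network() first",
         call. = FALSE)
  }
  src <- if (!is.null(proteins)) {
    proteins$source_gene[match(nodes$protein_id, proteins$protein_id)]
  } else rep(NA_character_, nrow(nodes))
  rows <- list()
  for (cid in sort(unique(stats::na.omit(nodes$cluster_id)))) {
    idx <- which(nodes$cluster_id == cid)
    fam_sets <- lapply(idx, function(i) {
      loc <- locate_protein(nodes$protein_id[i], src[i], genomes)
      if (is.null(loc)) return(character())
      nb <- extract_neighborhood(loc$genome, loc$feature_id, window)
      unique(unlist(nb$neighbors$families))
    })
    fams <- sort(unique(unlist(fam_sets)))
    for (f in fams) {
      frac <- mean(vapply(fam_sets, function(s) f %in% s, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cid, family = f, fraction = frac,
        reported = frac >= threshold, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_id = integer(), family = character(),
                      fraction = numeric(), reported = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
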