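#' Detect three-gene clusters (3GCs)
#'
#' Scans every gene carrying a family of the focal activity and reports
#' one cluster per focal gene whose +/- window ORF neighborhood contains
#' at least one gene from each of the two other activities' family sets
#' (family-set semantics: any family of an activity counts). When several
#' candidates exist for an activity, the nearest by absolute ORF offset is
#' chosen, ties going to the lower start coordinate. Detection is
#' annotation-driven and strand-agnostic; output order is by genome id,
#' then focal feature id, so results are invariant to input ordering.
#'
#' @param genomes a [genome_record()] or list of them.
#' @param schema an [activity_schema()].
#' @param focal_activity activity whose genes anchor the search
#'   (default `"aminotransferase"`).
#' @param window ORFs on each side (default 3, the neighborhood size used
#'   for colouring).
#' @param verbose if `TRUE`, also return every in-window triple per focal
#'   gene in an attribute `"triples"`.
#' @return a `data.frame` of class `gc3_table`: `genome_id`, `organism`,
#'   `contig_id`, `at_feature`, `ph_feature`, `dh_feature` (with
#'   start/end coordinates), `order_signature` (permutation of `"ADP"`
#'   letters in ascending start order), `phosphatase_class`, `span_orfs`
#'   (largest absolute offset used), `focal_feature`.
#' @export
find_3gc <- function(genomes, schema = activity_schema(),
                     focal_activity = "aminotransferase", window = 3L,
                     verbose = FALSE) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!focal_activity %in% names(schema)) {
    stop("unknown focal activity: ", focal_activity, call. = FALSE)
  }
  others <- setdiff(names(schema), focal_activity)
  act_letter <- c(aminotransferase = "A", dehydrogenase = "D",
                  phosphatase = "P")
  ord <- order(vapply(genomes, function(g) g$genome_id, character(1)))
  genomes <- genomes[ord]
  rows <- list()
  triples <- list()
  for (g in genomes) {
    ft <- g$features
    if (!nrow(ft)) next
    act_of_feature <- function(fams) {
      names(schema)[vapply(schema, function(f) any(f %in% fams),
                           logical(1))]
    }
    feat_acts <- lapply(ft$families, act_of_feature)
    focal_idx <- which(vapply(feat_acts, function(a)
      focal_activity %in% a, logical(1)))
    for (i in focal_idx) {
      nb <- extract_neighborhood(g, ft$feature_id[i], window)
      nbdf <- nb$neighbors
      if (!nrow(nbdf)) next
      nb_acts <- lapply(nbdf$families, act_of_feature)
      cand <- lapply(others, function(a) {
        which(vapply(nb_acts, function(x) a %in% x, logical(1)))
      })
      names(cand) <- others
      if (any(lengths(cand) == 0L)) next
      pick <- vapply(others, function(a) {
        j <- cand[[a]]
        j <- j[order(abs(nbdf$offset[j]), nbdf$start[j])]
        j[1]
      }, integer(1))
      members <- stats::setNames(
        c(ft$feature_id[i], nbdf$feature_id[pick]),
        c(focal_activity, others))
      starts <- stats::setNames(
        c(ft$start[i], nbdf$start[pick]),
        c(focal_activity, others))
      ends <- stats::setNames(
        c(ft$end[i], nbdf$end[pick]),
        c(focal_activity, others))
      sig <- paste(act_letter[names(sort(starts + ends / 1e9))],
                   collapse = "")
      ph_fams <- if ("phosphatase" %in% others) {
        unlist(nbdf$families[pick[["phosphatase"]]])
      } else unlist(ft$families[i])
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g$genome_id, organism = g$organism,
        contig_id = ft$contig_id[i],
        at_feature = members[["aminotransferase"]],
        ph_feature = members[["phosphatase"]],
        dh_feature = members[["dehydrogenase"]],
        at_start = starts[["aminotransferase"]],
        ph_start = starts[["phosphatase"]],
        dh_start = starts[["dehydrogenase"]],
        order_signature = sig,
        phosphatase_class = phosphatase_class_of(ph_fams),
        span_orfs = max(abs(nbdf$offset[pick])),
        focal_feature = ft$feature_id[i],
        stringsAsFactors = FALSE)
      if (verbose) {
        combs <- expand.grid(lapply(cand, identity))
        triples[[length(triples) + 1L]] <- data.frame(
          genome_id = g$genome_id, focal_feature = ft$feature_id[i],
          first = nbdf$feature_id[combs[[1]]],
          second = nbdf$feature_id[combs[[2]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    genome_id = character(), organism = character(),
    contig_id = character(), at_feature = character(),
    ph_feature = character(), dh_feature = character(),
    at_start = integer(), ph_start = integer(), dh_start = integer(),
    order_signature = character(), phosphatase_class = character(),
    span_orfs = integer(), focal_feature = character(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gc3_table", "data.frame")
  if (verbose) attr(out, "triples") <- do.call(rbind, triples)
  out
}

#' Gene-order signature of a detected cluster
#'
#' Letters `A` (aminotransferase), `D` (dehydrogenase), `P` (phosphatase)
#' sorted by ascending start coordinate on the contig; reverse-strand
#' blocks are not flipped (coordinates only). Start ties (impossible for
#' distinct features in practice) break by end coordinate.
#'
#' @param cluster one row of a [find_3gc()] table, or a list with
#'   `at_start`, `dh_start`, `ph_start`.
#' @return a 3-letter permutation of `"ADP"`.
#' @export
classify_order <- function(cluster) {
  starts <- c(A = cluster$at_start, D = cluster$dh_start,
              P = cluster$ph_start)
  paste(names(sort(starts)), collapse = "")
}

#' Tally putative producer genera
#'
#' Counts, per genus, the genomes with at least one detected cluster
#' (each genome counted once), in descending order. Genera below the
#' minimum count are omitted from the main table but retained in the full
#' listing.
#'
#' @param clusters a [find_3gc()] table.
#' @param min_genus_count minimum hits for the main table (default 5).
#' @return list with `main` and `full` data frames (`genus`, `n_genomes`).
#' @export
tabulate_producers <- function(clusters, min_genus_count = 5L) {
  uniq <- unique(clusters[, c("genome_id", "organism")])
  tab <- table(genus_of(uniq$organism))
  full <- data.frame(genus = names(tab),
                     n_genomes = as.integer(tab),
                     stringsAsFactors = FALSE)
  full <- full[order(-full$n_genomes, full$genus), , drop = FALSE]
  rownames(full) <- NULL
  list(main = full[full$n_genomes >= min_genus_count, , drop = FALSE],
       full = full)
}

#' Merge producer hit sets from several detection routes
#'
#' Unions genome-level hit sets (e.g. aminotransferase-focal SSN,
#' dehydrogenase-focal SSN, consensus screen) and records which routes
#' found each genome.
#'
#' @param ... named character vectors of genome ids.
#' @return a `data.frame` with `genome_id` and `found_by` (list column of
#'   source names), sorted by genome id.
#' @export
merge_hit_sets <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  ids <- sort(unique(unlist(sets)))
  found <- lapply(ids, function(id) {
    names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
  })
  out <- data.frame(genome_id = ids, stringsAsFactors = FALSE)
  out$found_by <- found
  out
}

#' Write a 3GC table as TSV
#'
#' @param clusters a [find_3gc()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gc3_table <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
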