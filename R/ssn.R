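#' Build a sequence similarity network
#'
#' Nodes are proteins, edges are pairwise hits whose chosen metric passes
#' the threshold. Proteins without any passing edge are retained as
#' isolated nodes (so that the network always covers the full input set).
#'
#' @param hits pairwise hits from [all_vs_all()].
#' @param threshold_spec list with `metric` (`"percent_identity"` or
#'   `"alignment_score"`, the EFI-style `-log10` E-value scale) and
#'   `value`.
#' @param proteins optional [protein_set()] supplying the node universe
#'   and organism metadata; defaults to the proteins appearing in `hits`.
#' @return an object of class `ssn`: list with `nodes` (data frame:
#'   `protein_id`, `organism`, `genus`, `cluster_id`, `is_singleton`),
#'   `edges` (hit columns for passing pairs) and `threshold_spec`.
#' @export
build_network <- function(hits, threshold_spec, proteins = NULL) {
  metric <- threshold_spec$metric %||% "percent_identity"
  if (!metric %in% c("percent_identity", "alignment_score")) {
    stop("unknown threshold metric: ", metric, call. = FALSE)
  }
  value <- threshold_spec$value
  stopifnot(is.numeric(value), length(value) == 1L)
  keep <- hits[[metric]] >= value
  edges <- hits[keep, , drop = FALSE]
  rownames(edges) <- NULL

  if (is.null(proteins)) {
    ids <- sort(unique(c(hits$query_id, hits$subject_id)))
    organism <- rep(NA_character_, length(ids))
  } else {
    ids <- proteins$protein_id
    organism <- proteins$organism
  }
  missing <- setdiff(unique(c(edges$query_id, edges$subject_id)), ids)
  if (length(missing)) {
    stop("edges reference proteins absent from the node set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(protein_id = ids, organism = organism,
                      genus = genus_of(organism),
                      cluster_id = NA_integer_, is_singleton = NA,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 threshold_spec = list(metric = metric, value = value)),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("<ssn> %d nodes, %d edges (%s >= %s)\n",
              nrow(x$nodes), nrow(x$edges),
              x$threshold_spec$metric, x$threshold_spec$value))
  invisible(x)
}

#' Assign connected-component cluster ids
#'
#' Clusters are connected components of the thresholded network (EFI-EST
#' semantics). Components with >= 2 members are numbered 1..C by strictly
#' non-increasing size, ties broken by the lexicographically smallest
#' member id; single-node components keep `cluster_id = NA` and are
#' flagged as singletons.
#'
#' @param net an [build_network()] result.
#' @return the network with `cluster_id` and `is_singleton` filled in.
#' @export
cluster_network <- function(net) {
  stopifnot(inherits(net, "ssn"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("query_id", "subject_id"), drop = FALSE],
    directed = FALSE, vertices = net$nodes$protein_id)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  sizes <- lengths(member)
  minid <- vapply(member, function(x) min(x), character(1))
  ord <- order(-sizes, minid)
  big <- ord[sizes[ord] >= 2L]
  nodes <- net$nodes
  nodes$cluster_id <- NA_integer_
  for (ci in seq_along(big)) {
    nodes$cluster_id[nodes$protein_id %in% member[[big[ci]]]] <- ci
  }
  nodes$is_singleton <- is.na(nodes$cluster_id)
  net$nodes <- nodes
  net
}

#' Cluster and singleton census across thresholds
#'
#' Re-thresholds the same hit set at each value and reports the number of
#' multi-member clusters, the number of post-threshold singletons, and the
#' co-membership partition of a tracked node set.
#'
#' @param hits pairwise hits from [all_vs_all()].
#' @param thresholds numeric vector (at least one value).
#' @param metric threshold metric (default `"percent_identity"`).
#' @param proteins optional node universe (see [build_network()]).
#' @param tracked optional protein ids whose co-membership is reported.
#' @return a `data.frame` with one row per threshold: `threshold`,
#'   `n_clusters`, `n_singletons`, and (when `tracked` is given) a
#'   `partition` list column mapping tracked ids to component labels.
#' @export
threshold_sweep <- function(hits, thresholds, metric = "percent_identity",
                            proteins = NULL, tracked = NULL) {
  if (length(thresholds) < 1L) stop("need >= 1 threshold", call. = FALSE)
  rows <- lapply(thresholds, function(t) {
    net <- cluster_network(build_network(
      hits, list(metric = metric, value = t), proteins))
    part <- NULL
    if (!is.null(tracked)) {
      idx <- match(tracked, net$nodes$protein_id)
      lab <- net$nodes$cluster_id[idx]
      ## singletons get unique negative labels so they never co-cluster
      lab[is.na(lab)] <- -seq_len(sum(is.na(lab)))
      part <- stats::setNames(lab, tracked)
    }
    out <- data.frame(threshold = t,
                      n_clusters = length(unique(
                        stats::na.omit(net$nodes$cluster_id))),
                      n_singletons = sum(net$nodes$is_singleton))
    out$partition <- list(part)
    out
  })
  do.call(rbind, rows)
}

#' Label clusters by genus majority
#'
#' A cluster whose most common genus reaches the majority fraction
#' (default 75%) is labelled with that genus; otherwise the two most
#' populous genera are joined with `/` (ties broken alphabetically).
#'
#' @param net a clustered [cluster_network()] result with organisms.
#' @param majority_fraction minimum share for a single-genus label.
#' @return named character vector: cluster id -> label.
#' @export
label_clusters_by_genus <- function(net, majority_fraction = 0.75) {
  stopifnot(inherits(net, "ssn"))
  nodes <- net$nodes[!is.na(net$nodes$cluster_id), , drop = FALSE]
  if (!nrow(nodes)) return(stats::setNames(character(), character()))
  out <- vapply(split(nodes$genus, nodes$cluster_id), function(gn) {
    tab <- sort(table(gn), decreasing = TRUE)
    ## stable tie order: count desc, then genus name
    tab <- tab[order(-as.integer(tab), names(tab))]
    if (tab[1] / length(gn) >= majority_fraction) {
      names(tab)[1]
    } else {
      paste(sort(names(tab)[1:2]), collapse = "/")
    }
  }, character(1))
  out
}
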