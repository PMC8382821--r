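#' Export a similarity network
#'
#' GraphML carries node attributes (organism, genus, cluster id, the
#' neighborhood colours when present) and edge attributes (percent
#' identity, bit score, E-value, alignment score) for Cytoscape-style
#' viewing; the edge-list format is a TSV with a header row.
#'
#' @param net an `ssn`.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml",
                                                "edgelist_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "ssn"))
  bad <- setdiff(unique(c(net$edges$query_id, net$edges$subject_id)),
                 net$nodes$protein_id)
  if (length(bad)) {
    stop("edges reference absent nodes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (format == "edgelist_tsv") {
    cols <- intersect(c("query_id", "subject_id", "percent_identity",
                        "bit_score", "evalue", "alignment_score"),
                      names(net$edges))
    utils::write.table(net$edges[, cols, drop = FALSE], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  vdf <- data.frame(name = net$nodes$protein_id,
                    stringsAsFactors = FALSE)
  for (col in c("organism", "genus", "cluster_id", "phosphatase_class")) {
    if (!is.null(net$nodes[[col]])) {
      v <- net$nodes[[col]]
      if (is.numeric(v)) v[is.na(v)] <- -1 else v[is.na(v)] <- ""
      vdf[[col]] <- v
    }
  }
  if (!is.null(net$nodes$activities)) {
    vdf$activities <- vapply(net$nodes$activities, paste,
                             character(1), collapse = ",")
  }
  edf <- net$edges
  g <- igraph::graph_from_data_frame(
    if (nrow(edf)) edf else
      data.frame(query_id = character(), subject_id = character()),
    directed = FALSE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a GraphML network
#'
#' Reconstructs an `ssn` (nodes with attributes, edges with metrics) from
#' a file written by [write_network()].
#'
#' @param path GraphML file.
#' @return an `ssn` (threshold spec unknown: metric `NA`).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(protein_id = va$name, stringsAsFactors = FALSE)
  for (col in c("organism", "genus", "phosphatase_class")) {
    if (!is.null(va[[col]])) {
      v <- va[[col]]
      v[v == ""] <- NA_character_
      nodes[[col]] <- v
    }
  }
  if (!is.null(va$cluster_id)) {
    ci <- as.numeric(va$cluster_id)
    ci[ci < 0] <- NA
    nodes$cluster_id <- as.integer(ci)
    nodes$is_singleton <- is.na(nodes$cluster_id)
  }
  if (!is.null(va$activities)) {
    nodes$activities <- strsplit(va$activities, ",", fixed = TRUE)
  }
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("query_id", "subject_id")
  structure(list(nodes = nodes, edges = el,
                 threshold_spec = list(metric = NA_character_,
                                       value = NA_real_)),
            class = "ssn")
}
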