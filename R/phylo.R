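#' Uncorrected p-distance matrix from an alignment
#'
#' `d(i, j)` = mismatches / columns where neither row has a gap (no
#' multiple-hit correction, matching a "without correction"
#' neighbor-joining tree). A pair with zero comparable columns is an
#' error.
#'
#' @param msa a [protein_msa()] with >= 3 rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  n <- length(msa$ids)
  if (n < 3L) stop("need >= 3 aligned sequences", call. = FALSE)
  mat <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     msa$ids[i], msa$ids[j]), call. = FALSE)
      }
      D[i, j] <- D[j, i] <- mean(mat[i, ok] != mat[j, ok])
    }
  }
  D
}

nwk_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.-]", x),
         paste0("'", gsub("'", "_", x), "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking: when
#' several pairs minimise the Q criterion, the pair with the
#' lexicographically smallest label pair is joined first. Additive inputs
#' are recovered exactly. Negative branch lengths are clamped to zero and
#' flagged via the `"clamped"` attribute.
#'
#' @param D symmetric distance matrix (or `dist`) with >= 3 labelled taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0) || any(D < 0) ||
      any(!is.finite(D))) {
    stop("distance matrix must be symmetric, finite, non-negative, ",
         "with zero diagonal", call. = FALSE)
  }
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  sub <- nwk_label(rownames(D))  # newick fragment per active node
  act <- rownames(D)             # sort keys (smallest member label)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- NULL
    qmin <- min(Q)
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (Q[i, j] <= qmin + 1e-12) {
          key <- sort(c(act[i], act[j]))
          if (is.null(best) || key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])) {
            best <- list(i = i, j = j, key = key)
          }
        }
      }
    }
    i <- best$i; j <- best$j
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    newkey <- min(act[i], act[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lbl <- c(rownames(D)[keep], paste0("__u", m))
    rownames(D2) <- colnames(D2) <- lbl
    D <- D2
    sub <- c(sub[keep], newsub)
    act <- c(act[keep], newkey)
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(l1),
                 sub[2], fmt(l2), sub[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' trees, plus the value normalised by `2 (n - 3)`. The trees must share
#' an identical leaf set.
#'
#' @param t1,t2 `ape::phylo` trees.
#' @return list with `rf` (integer) and `normalized` (in `[0, 1]`).
#' @export
robinson_foulds <- function(t1, t2) {
  d1 <- setdiff(t1$tip.label, t2$tip.label)
  d2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(d1) || length(d2)) {
    stop("leaf sets differ; only in tree 1: [",
         paste(d1, collapse = ", "), "], only in tree 2: [",
         paste(d2, collapse = ", "), "]", call. = FALSE)
  }
  rf <- as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                                     normalize = FALSE))
  n <- length(t1$tip.label)
  norm <- if (n > 3L) rf / (2 * (n - 3)) else as.numeric(rf > 0)
  list(rf = rf, normalized = norm)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape preserving topology and branch lengths to at
#' least 6 decimals on a round trip.
#'
#' @param path file path.
#' @return [read_newick()]: an `ape::phylo`; [write_newick()]: `path`,
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @param tree an `ape::phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a distance matrix (square TSV or PHYLIP lower-triangle)
#'
#' @param path input file. Square TSV: header of labels, one labelled row
#'   per taxon. PHYLIP-style: first line the taxon count, then
#'   `label d(1) ... d(i-1)` lower-triangle rows.
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    lines <- readLines(path, warn = FALSE)[-1]
    lines <- lines[nzchar(trimws(lines))]
    labs <- character(n)
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      labs[i] <- tok[1]
      if (i > 1L) {
        v <- as.numeric(tok[-1])[seq_len(i - 1L)]
        D[i, seq_len(i - 1L)] <- v
        D[seq_len(i - 1L), i] <- v
      }
    }
    dimnames(D) <- list(labs, labs)
    return(D)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  D <- as.matrix(tab)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  D
}

#' @param D symmetric labelled matrix.
#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(as.data.frame(D), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
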