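#' Multiple alignment container
#'
#' Equal-length aligned sequences over the amino-acid alphabet plus `-`
#' gaps. Degapping a row reproduces the input sequence exactly.
#'
#' @param ids row identifiers.
#' @param seqs aligned sequences (equal lengths).
#' @return list of class `protein_msa` with `ids`, `seqs`, `ncol`.
#' @export
protein_msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 ncol = if (length(seqs)) nchar(seqs[1]) else 0L),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns\n",
              length(x$ids), x$ncol))
  invisible(x)
}

#' Remove gaps from MSA rows
#'
#' @param msa a [protein_msa()].
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(msa) {
  vapply(msa$seqs, function(s) gsub("-", "", s, fixed = TRUE),
         character(1), USE.NAMES = TRUE)
}

## column frequency profile (21 x L: 20 residues + gap), counts.
msa_profile <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  alpha <- c(AA_STANDARD, "-")
  prof <- vapply(seq_len(ncol(mat)), function(j) {
    tabulate(match(mat[, j], alpha), nbins = length(alpha))
  }, integer(length(alpha)))
  rownames(prof) <- alpha
  prof
}

## expected substitution score between two profile columns; gaps
## contribute zero. Frequencies are over all rows (including gap rows).
profile_col_scores <- function(pa, pb, S) {
  fa <- sweep(pa[AA_STANDARD, , drop = FALSE], 2,
              pmax(colSums(pa), 1), "/")
  fb <- sweep(pb[AA_STANDARD, , drop = FALSE], 2,
              pmax(colSums(pb), 1), "/")
  t(fa) %*% S[AA_STANDARD, AA_STANDARD] %*% fb
}

#' Progressive multiple sequence alignment
#'
#' Neighbor-joining guide tree on pairwise p-distances (from local
#' pairwise alignments), followed by profile-profile progressive merges
#' scored with the pairwise substitution matrix under affine gaps.
#' Deterministic. Column-for-column parity with Clustal is not promised;
#' for substitution-only divergence (no indels) the alignment is gap-free.
#'
#' @param proteins a [protein_set()] with >= 2 rows.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties for profile merges.
#' @return a [protein_msa()] in input row order.
#' @export
progressive_msa <- function(proteins, matrix = NULL, gap_open = 11,
                            gap_extend = 1) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) < 2L) {
    stop("need >= 2 sequences to align", call. = FALSE)
  }
  matrix <- matrix %||% blosum62()
  ids <- proteins$protein_id
  seqs <- stats::setNames(proteins$sequence, ids)
  n <- length(seqs)

  merge_pair <- function(rows_a, rows_b) {
    pa <- msa_profile(rows_a)
    pb <- msa_profile(rows_b)
    sc <- profile_col_scores(pa, pb, matrix)
    path <- nw_profile_cpp(sc, gap_open, gap_extend)
    expand <- function(rows, idx) {
      vapply(rows, function(s) {
        ch <- strsplit(s, "")[[1]]
        paste(ifelse(idx > 0, ch[pmax(idx, 1)], "-"), collapse = "")
      }, character(1), USE.NAMES = TRUE)
    }
    c(expand(rows_a, path$a_idx), expand(rows_b, path$b_idx))
  }

  if (n == 2L) {
    aligned <- merge_pair(seqs[1], seqs[2])
  } else {
    ## guide tree from p-distances (1 - fractional identity of the local
    ## alignment); joined in ape::nj merge order
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        h <- smith_waterman(seqs[[i]], seqs[[j]], matrix,
                            gap_open, gap_extend)
        d[i, j] <- d[j, i] <- 1 - h$percent_identity / 100
      }
    }
    tree <- neighbor_joining(as.dist(d))
    aligned <- align_by_tree(tree, seqs, merge_pair)
  }
  protein_msa(ids, aligned[ids])
}

## post-order traversal of the guide tree, merging child alignments.
align_by_tree <- function(tree, seqs, merge_pair) {
  nt <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(seqs[tree$tip.label[node]])
    kids <- children[[as.character(node)]]
    sub <- lapply(sort(kids), rec)
    out <- sub[[1]]
    for (k in seq(2, length(sub))) out <- merge_pair(out, sub[[k]])
    out
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  rec(root)
}

#' Read an alignment in aligned-FASTA or Clustal format
#'
#' @param path input file; format guessed from the first line
#'   (`CLUSTAL` header) unless given.
#' @param format `"fasta"` or `"clustal"`.
#' @return a [protein_msa()].
#' @export
read_msa <- function(path, format = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  format <- format %||%
    (if (grepl("^CLUSTAL", first)) "clustal" else "fasta")
  if (format == "fasta") {
    aa <- Biostrings::readAAMultipleAlignment(path, format = "fasta")
    m <- as.character(aa)
    return(protein_msa(names(m), unname(m)))
  }
  lines <- readLines(path, warn = FALSE)[-1]
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s+[.:*\\s]*$", lines)]
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)", lines))
  parts <- parts[lengths(parts) == 3L]
  ids <- vapply(parts, `[`, "", 2)
  chunks <- vapply(parts, `[`, "", 3)
  seqs <- vapply(split(chunks, factor(ids, levels = unique(ids))),
                 paste, character(1), collapse = "")
  protein_msa(unique(ids), unname(seqs[unique(ids)]))
}

#' Write an alignment
#'
#' @param msa a [protein_msa()].
#' @param path output file.
#' @param format `"fasta"` (60-column wrap) or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    aa <- Biostrings::AAStringSet(unname(msa$seqs))
    names(aa) <- msa$ids
    Biostrings::writeXStringSet(aa, path, width = 60L)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL multiple sequence alignment", con)
    writeLines("", con)
    wid <- max(nchar(msa$ids)) + 3L
    for (off in seq(1L, max(msa$ncol, 1L), by = 60L)) {
      for (k in seq_along(msa$ids)) {
        writeLines(sprintf("%-*s%s", wid, msa$ids[k],
                           substr(msa$seqs[k], off,
                                  min(off + 59L, msa$ncol))), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}
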