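#' Default protein scoring scheme
#'
#' BLOSUM62 with gap open 11 / gap extend 1 (blastp defaults). A gap of
#' length k costs `open + k * extend`.
#'
#' @return a list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(matrix = blosum62(), gap_open = 11, gap_extend = 1)
}

## BLOSUM62 from Biostrings, restricted to the package alphabet.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      cache <<- m[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix files distributed with BLAST
#' (comment lines start with `#`; first non-comment row is the column
#' alphabet).
#'
#' @param path matrix file.
#' @return a symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(0, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, "", 1), cols))
  for (i in seq_along(rows)) m[i, ] <- as.numeric(rows[[i]][-1])
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("substitution matrix is not symmetric", call. = FALSE)
  }
  m
}

encode_seq <- function(seq, matrix) {
  codes <- match(strsplit(seq, "")[[1]], rownames(matrix)) - 1L
  if (anyNA(codes)) {
    stop("sequence contains residues absent from the scoring matrix",
         call. = FALSE)
  }
  codes
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gap penalties (Gotoh). The traceback is
#' deterministic: ties are resolved diagonal > up > left and the traced
#' cell is the first score maximum in row-major order.
#'
#' @param a,b amino-acid sequences (non-empty strings).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @return a list with `raw_score`, `aligned_a`, `aligned_b` (gapped
#'   strings), alignment bounds `a_start`/`a_end`/`b_start`/`b_end`,
#'   `alignment_length` (columns including gaps), `n_identical` and
#'   `percent_identity` (identical pairs / alignment length, BLAST
#'   convention).
#' @export
smith_waterman <- function(a, b, matrix = NULL, gap_open = 11,
                           gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (gap_open < gap_extend || gap_extend < 0) {
    stop("need gap_open >= gap_extend >= 0", call. = FALSE)
  }
  matrix <- matrix %||% blosum62()
  ## canonical orientation so that swapping the arguments returns the
  ## same alignment (co-optimal local alignments are not unique; aligning
  ## the lexicographically smaller sequence first makes the choice
  ## orientation-independent)
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  res <- sw_align_cpp(encode_seq(a, matrix), encode_seq(b, matrix),
                      matrix, gap_open, gap_extend)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  aa <- ifelse(res$a_idx > 0, ca[pmax(res$a_idx, 1)], "-")
  bb <- ifelse(res$b_idx > 0, cb[pmax(res$b_idx, 1)], "-")
  len <- length(aa)
  nid <- sum(res$a_idx > 0 & res$b_idx > 0 & aa == bb)
  out <- list(
    raw_score = res$score,
    aligned_a = paste(aa, collapse = ""),
    aligned_b = paste(bb, collapse = ""),
    a_start = res$a_start, a_end = res$a_end,
    b_start = res$b_start, b_end = res$b_end,
    alignment_length = len,
    n_identical = nid,
    percent_identity = if (len) 100 * nid / len else 0
  )
  if (swapped) {
    out[c("aligned_a", "aligned_b")] <- out[c("aligned_b", "aligned_a")]
    out[c("a_start", "a_end", "b_start", "b_end")] <-
      out[c("b_start", "b_end", "a_start", "a_end")]
  }
  out
}

#' BLAST-like statistics for a raw alignment score
#'
#' Karlin-Altschul statistics with gapped BLOSUM62 constants:
#' `bit_score = (lambda * raw_score - ln K) / ln 2`,
#' `evalue = m * n * 2^-bit_score`, and the EFI-style
#' `alignment_score = max(0, -log10(evalue))` used as an SSN edge
#' threshold.
#'
#' @param raw_score raw alignment score.
#' @param m,n query and subject sequence lengths.
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267 / 0.041,
#'   gapped BLOSUM62 with gap 11/1).
#' @return a list with `bit_score`, `evalue`, `alignment_score`.
#' @export
score_hit <- function(raw_score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m <= 0) || any(n <= 0)) {
    stop("sequence lengths must be positive", call. = FALSE)
  }
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0", call. = FALSE)
  bit <- (lambda * raw_score - log(K)) / log(2)
  ev <- m * n * 2^(-bit)
  list(bit_score = bit, evalue = ev,
       alignment_score = pmax(0, -log10(ev)))
}

#' All-versus-all local alignment
#'
#' Aligns every unordered pair of distinct proteins and keeps pairs whose
#' E-value passes the cutoff (default `1e-5`, the SSN edge-inclusion expect
#' score). Self-pairs are excluded.
#'
#' @param proteins a [protein_set()] with at least 2 rows.
#' @param evalue_cutoff maximum E-value for a reported hit.
#' @param matrix,gap_open,gap_extend scoring scheme (BLOSUM62 11/1).
#' @param lambda,K Karlin-Altschul parameters passed to [score_hit()].
#' @return a `data.frame` of pairwise hits with columns `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `evalue`, `alignment_score`,
#'   `percent_identity`, `alignment_length`, `query_coverage`,
#'   `subject_coverage`.
#' @export
all_vs_all <- function(proteins, evalue_cutoff = 1e-5, matrix = NULL,
                       gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  stopifnot(is.data.frame(proteins))
  if (nrow(proteins) < 2L) stop("need at least 2 proteins", call. = FALSE)
  matrix <- matrix %||% blosum62()
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  lens <- nchar(seqs)
  rows <- vector("list", length(ids) * (length(ids) - 1L) / 2L)
  k <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      res <- smith_waterman(seqs[i], seqs[j], matrix, gap_open,
                            gap_extend)
      st <- score_hit(res$raw_score, lens[i], lens[j], lambda, K)
      if (st$evalue > evalue_cutoff) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        query_id = ids[i], subject_id = ids[j],
        raw_score = res$raw_score, bit_score = st$bit_score,
        evalue = st$evalue, alignment_score = st$alignment_score,
        percent_identity = res$percent_identity,
        alignment_length = res$alignment_length,
        query_coverage = 100 * (res$a_end - res$a_start + 1L) / lens[i],
        subject_coverage = 100 * (res$b_end - res$b_start + 1L) / lens[j],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(query_id = character(), subject_id = character(),
               raw_score = numeric(), bit_score = numeric(),
               evalue = numeric(), alignment_score = numeric(),
               percent_identity = numeric(), alignment_length = integer(),
               query_coverage = numeric(), subject_coverage = numeric(),
               stringsAsFactors = FALSE)
  class(out) <- c("pairwise_hits", "data.frame")
  out
}

#' Export hits as BLAST-tabular-like TSV
#'
#' @param hits result of [all_vs_all()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$percent_identity, 3),
    length = hits$alignment_length,
    bitscore = round(hits$bit_score, 2),
    evalue = signif(hits$evalue, 3),
    qcovs = round(hits$query_coverage, 1),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
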