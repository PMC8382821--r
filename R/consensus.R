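#' The packaged aminotransferase consensus motif
#'
#' The degenerate 30-mer diagnostic for aminotransferases of azasugar
#' three-gene clusters: `SGNXFRXXXFPNXXXXXXXLXVPXPYCXRC`. `X` matches any
#' residue; the 16 non-X positions are the constrained ones.
#'
#' @return the motif pattern string.
#' @export
aza_at_motif <- function() "SGNXFRXXXFPNXXXXXXXLXVPXPYCXRC"

#' Consensus motif object
#'
#' @param pattern string over amino acids and `X`; uppercase marks strong
#'   (well-conserved) positions, lowercase weak ones. Matching is
#'   case-insensitive; case is display information only.
#' @param mismatch_budget allowed mismatches at constrained positions when
#'   scanning (default 0).
#' @return list of class `consensus_motif` with `pattern`,
#'   `constrained_count`, `mismatch_budget`.
#' @export
consensus_motif <- function(pattern, mismatch_budget = 0L) {
  stopifnot(nchar(pattern) >= 1L, mismatch_budget >= 0L)
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad)) {
    stop("invalid motif characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(pattern = pattern,
                 constrained_count = sum(chars != "X"),
                 mismatch_budget = as.integer(mismatch_budget)),
            class = "consensus_motif")
}

#' Case-encoded plurality consensus of an alignment
#'
#' Per column, the plurality residue with gaps excluded: uppercase if its
#' gap-free fraction reaches `strong_fraction`, lowercase if it reaches
#' `weak_fraction`, else `X`. Plurality ties and all-gap columns give `X`.
#' The rule is column-local, so row order never changes the pattern.
#'
#' @param msa a [protein_msa()].
#' @param strong_fraction,weak_fraction case thresholds,
#'   `0 < weak <= strong <= 1`.
#' @return a [consensus_motif()].
#' @export
derive_consensus <- function(msa, strong_fraction = 0.9,
                             weak_fraction = 0.5) {
  stopifnot(inherits(msa, "protein_msa"))
  if (!(weak_fraction > 0 && weak_fraction <= strong_fraction &&
        strong_fraction <= 1)) {
    stop("need 0 < weak_fraction <= strong_fraction <= 1", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(msa$seqs), ""))
  pattern <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (!length(col)) return("X")
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return("X")
    frac <- tab[1] / length(col)
    res <- names(tab)[1]
    if (frac >= strong_fraction) res
    else if (frac >= weak_fraction) tolower(res)
    else "X"
  }, character(1))
  consensus_motif(paste(pattern, collapse = ""))
}

#' Extract a diagnostic span from a consensus
#'
#' Coordinates are 1-based inclusive positions in the consensus pattern.
#'
#' @param motif a [consensus_motif()].
#' @param start,end span bounds.
#' @return a [consensus_motif()] for the span.
#' @export
consensus_span <- function(motif, start, end) {
  stopifnot(inherits(motif, "consensus_motif"),
            start >= 1L, end >= start, end <= nchar(motif$pattern))
  consensus_motif(substr(motif$pattern, start, end),
                  motif$mismatch_budget)
}

#' Scan a sequence with a degenerate motif
#'
#' Reports every offset (1-based, overlapping matches included) where the
#' number of mismatching constrained (non-X) motif positions is within
#' the budget. `X` matches anything; comparison is case-insensitive.
#' A motif longer than the sequence yields an empty result.
#'
#' @param sequence protein sequence.
#' @param motif a [consensus_motif()] or pattern string.
#' @param mismatch_budget allowed mismatches (overrides the motif's own).
#' @return `data.frame` with `position` and `mismatches`.
#' @export
scan_motif <- function(sequence, motif, mismatch_budget = NULL) {
  if (is.character(motif)) motif <- consensus_motif(motif)
  budget <- mismatch_budget %||% motif$mismatch_budget
  pat <- strsplit(toupper(motif$pattern), "")[[1]]
  constrained <- which(pat != "X")
  L <- nchar(sequence)
  k <- length(pat)
  if (L < k) {
    return(data.frame(position = integer(), mismatches = integer()))
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  n_off <- L - k + 1L
  mism <- integer(n_off)
  for (j in constrained) {
    mism <- mism + (chars[seq_len(n_off) + j - 1L] != pat[j])
  }
  hit <- which(mism <= budget)
  data.frame(position = hit, mismatches = mism[hit])
}

#' Screen proteomes with a motif and validate against detected 3GCs
#'
#' Scans every protein, flags each hit `in_3gc` when its source gene is a
#' member of a detected cluster, and reports precision
#' (`in_3gc / (in_3gc + off_target)`). Hits on proteins without a gene
#' mapping are counted `unmapped` and excluded from the precision
#' denominator with a warning. With no hits at all the precision is
#' undefined (`NA`), not 0. Counts are reported both at protein and at
#' organism level.
#'
#' @param proteome a [protein_set()] (source-gene links required for
#'   in-3GC attribution).
#' @param motif a [consensus_motif()] or pattern string.
#' @param clusters a [find_3gc()] table.
#' @param mismatch_budget allowed mismatches (default the motif's own).
#' @return list of class `motif_screen` with `hits` (per-hit table),
#'   `n_hits`, `n_in_3gc`, `n_off_target`, `n_unmapped`, `precision`,
#'   and organism-level counts `n_organisms_hit`, `n_organisms_in_3gc`.
#' @export
screen_and_validate <- function(proteome, motif, clusters,
                                mismatch_budget = NULL) {
  if (is.character(motif)) motif <- consensus_motif(motif)
  member_features <- unique(c(clusters$at_feature, clusters$ph_feature,
                              clusters$dh_feature))
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    h <- scan_motif(proteome$sequence[i], motif, mismatch_budget)
    if (!nrow(h)) next
    src <- proteome$source_gene[i]
    status <- if (is.na(src)) "unmapped"
      else if (src %in% member_features) "in_3gc" else "off_target"
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = proteome$protein_id[i],
      organism = proteome$organism[i],
      position = h$position, mismatches = h$mismatches,
      status = status, stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), organism = character(),
               position = integer(), mismatches = integer(),
               status = character(), stringsAsFactors = FALSE)
  per_prot <- unique(hits[, c("protein_id", "organism", "status")])
  n_in <- sum(per_prot$status == "in_3gc")
  n_off <- sum(per_prot$status == "off_target")
  n_unm <- sum(per_prot$status == "unmapped")
  if (n_unm > 0L) {
    warning(n_unm, " hit protein(s) without a gene mapping excluded ",
            "from the precision denominator", call. = FALSE)
  }
  denom <- n_in + n_off
  structure(list(
    hits = hits,
    n_hits = nrow(per_prot),
    n_in_3gc = n_in,
    n_off_target = n_off,
    n_unmapped = n_unm,
    precision = if (denom > 0L) n_in / denom else NA_real_,
    n_organisms_hit = length(unique(per_prot$organism)),
    n_organisms_in_3gc = length(unique(
      per_prot$organism[per_prot$status == "in_3gc"]))
  ), class = "motif_screen")
}

#' @export
print.motif_screen <- function(x, ...) {
  cat(sprintf(paste0("<motif_screen> %d hit protein(s): %d in 3GC, ",
                     "%d off-target, %d unmapped; precision %s\n"),
              x$n_hits, x$n_in_3gc, x$n_off_target, x$n_unmapped,
              ifelse(is.na(x$precision), "undefined",
                     sprintf("%.3f", x$precision))))
  invisible(x)
}
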