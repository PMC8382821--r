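#' Protein sets
#'
#' A protein set is a plain `data.frame` with one row per protein and columns
#' `protein_id` (unique), `organism`, `sequence` (20-letter amino-acid
#' alphabet plus `X`) and `source_gene` (feature id of the encoding gene, or
#' `NA`). It is the node payload of a sequence similarity network.
#'
#' @param protein_id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param organism organism names; the genus is taken to be the first
#'   whitespace-delimited token.
#' @param source_gene optional feature ids linking proteins back to genes.
#' @return a `data.frame` with class `protein_set`.
#' @export
protein_set <- function(protein_id, sequence, organism = NA_character_,
                        source_gene = NA_character_) {
  protein_id <- as.character(protein_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(protein_id)) {
    dup <- unique(protein_id[duplicated(protein_id)])
    stop("duplicate protein_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  mapply(assert_aa_sequence, sequence, protein_id)
  out <- data.frame(
    protein_id = protein_id,
    organism = rep_len(as.character(organism), length(protein_id)),
    sequence = sequence,
    source_gene = rep_len(as.character(source_gene), length(protein_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes `protein_id`. When
#' the description contains an `organism=` key (e.g.
#' `>p1 organism=Bacillus velezensis`), everything after it up to the next
#' `key=` token (or end of line) becomes the organism; likewise a
#' `source_gene=` key populates the gene link.
#'
#' @param path FASTA file path.
#' @return a [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(protein_set(character(), character()))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(aa)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for id: ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  protein_set(
    protein_id = ids,
    sequence = seqs,
    organism = parse_fasta_key(desc, "organism"),
    source_gene = parse_fasta_key(desc, "source_gene")
  )
}

## Pull "key=value words" out of a FASTA description; the value runs until
## the next "word=" token or end of line.
parse_fasta_key <- function(desc, key) {
  pat <- paste0(".*\\b", key, "=")
  out <- ifelse(grepl(paste0("\\b", key, "="), desc),
                sub("\\s+\\S+=.*$", "", sub(pat, "", desc)),
                NA_character_)
  trimws(out)
}

#' Write a protein set as FASTA
#'
#' Sequences are wrapped at 60 columns. Organism and source-gene metadata are
#' carried in the description as `organism=` / `source_gene=` keys so that
#' [read_fasta()] round-trips all fields.
#'
#' @param proteins a [protein_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins))
  desc <- character(nrow(proteins))
  has_org <- !is.na(proteins$organism)
  desc[has_org] <- paste0(" organism=", proteins$organism[has_org])
  has_src <- !is.na(proteins$source_gene)
  desc[has_src] <- paste0(desc[has_src],
                          " source_gene=", proteins$source_gene[has_src])
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- paste0(proteins$protein_id, desc)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
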