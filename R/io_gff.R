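#' Gene features and genome records
#'
#' A genome record holds the annotation substrate for neighborhood analysis:
#' an ordered table of contigs (id, length, circular flag) and a table of
#' located, stranded CDS features. Coordinates are 1-based inclusive
#' throughout (GFF3/GenBank convention). Features are kept sorted by contig,
#' then start, then end, and feature ids are unique per genome.
#'
#' @param genome_id genome identifier.
#' @param organism organism name (genus = first whitespace token).
#' @param contigs `data.frame` with columns `contig_id`, `length`,
#'   `circular` (logical).
#' @param features `data.frame` with columns `feature_id`, `contig_id`,
#'   `start`, `end`, `strand` (`"+"` or `"-"`), `protein_id`, `product`,
#'   and `families` (list column of character vectors, e.g. `"PF00202"`).
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, organism, contigs, features) {
  stopifnot(is.data.frame(contigs), is.data.frame(features))
  contigs$contig_id <- as.character(contigs$contig_id)
  contigs$length <- as.integer(contigs$length)
  if (is.null(contigs$circular)) contigs$circular <- FALSE
  if (nrow(features)) {
    features$feature_id <- as.character(features$feature_id)
    features$contig_id <- as.character(features$contig_id)
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$strand <- as.character(features$strand)
    if (is.null(features$protein_id)) features$protein_id <- NA_character_
    if (is.null(features$product)) features$product <- NA_character_
    if (is.null(features$families)) {
      features$families <- replicate(nrow(features), character(), FALSE)
    }
    if (anyDuplicated(features$feature_id)) {
      stop("duplicate feature_id in genome '", genome_id, "'",
           call. = FALSE)
    }
    bad_strand <- !features$strand %in% c("+", "-")
    if (any(bad_strand)) {
      stop("unknown strand for feature(s): ",
           paste(features$feature_id[bad_strand], collapse = ", "),
           call. = FALSE)
    }
    if (any(features$start < 1L) || any(features$start > features$end)) {
      stop("malformed coordinates (need 1 <= start <= end) in genome '",
           genome_id, "'", call. = FALSE)
    }
    if (!all(features$contig_id %in% contigs$contig_id)) {
      stop("feature on unknown contig in genome '", genome_id, "'",
           call. = FALSE)
    }
    clen <- contigs$length[match(features$contig_id, contigs$contig_id)]
    if (any(features$end > clen)) {
      over <- features$feature_id[features$end > clen]
      stop("feature(s) exceed contig length: ",
           paste(over, collapse = ", "), call. = FALSE)
    }
    ord <- order(match(features$contig_id, contigs$contig_id),
                 features$start, features$end)
    features <- features[ord, , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(
    list(genome_id = as.character(genome_id),
         organism = as.character(organism),
         contigs = contigs, features = features),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s): %d contig(s), %d feature(s)\n",
              x$genome_id, x$organism, nrow(x$contigs), nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(feature_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             protein_id = character(), product = character(),
             families = I(list()), stringsAsFactors = FALSE)
}

#' Read genome annotations from GFF3
#'
#' CDS rows become gene features. Family accessions are taken from both
#' `Dbxref=Pfam:PFxxxxx` entries and a custom comma-separated `pfam=`
#' attribute. Contig lengths come from `##sequence-region` directives or
#' `region` feature rows, with an optional contig FASTA as fallback;
#' `Is_circular=true` on a region row marks a circular contig. Genome id
#' and organism are recovered from `genome_id=` / `organism=` attributes on
#' region rows when present.
#'
#' @param gff_path GFF3 file.
#' @param fasta_path optional contig FASTA used for contig lengths.
#' @param genome_id,organism overrides for the genome metadata.
#' @return a [genome_record()].
#' @export
read_annotations <- function(gff_path, fasta_path = NULL,
                             genome_id = NULL, organism = NULL) {
  if (!file.exists(gff_path)) stop("no such file: ", gff_path, call. = FALSE)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  regions <- gr[as.character(md$type) == "region"]
  is_cds <- as.character(md$type) == "CDS"
  cds <- gr[is_cds]
  cmd <- S4Vectors::mcols(cds)

  ## contig lengths: ##sequence-region directive > region rows > FASTA
  seq_lines <- grep("^##sequence-region",
                    readLines(gff_path, warn = FALSE), value = TRUE)
  lens <- list()
  for (ln in seq_lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) >= 4L) lens[[tok[2]]] <- as.integer(tok[4])
  }
  for (i in seq_along(regions)) {
    cid <- as.character(GenomicRanges::seqnames(regions))[i]
    if (is.null(lens[[cid]])) lens[[cid]] <- BiocGenerics::end(regions)[i]
  }
  if (!is.null(fasta_path)) {
    fa <- Biostrings::readDNAStringSet(fasta_path)
    for (i in seq_along(fa)) {
      cid <- sub("\\s.*$", "", names(fa)[i])
      if (is.null(lens[[cid]])) lens[[cid]] <- Biostrings::width(fa)[i]
    }
  }
  contig_ids <- unique(c(names(lens),
                         as.character(GenomicRanges::seqnames(gr))))
  missing_len <- setdiff(contig_ids,
                         c(names(lens)))
  if (length(missing_len)) {
    stop("no length available for contig(s): ",
         paste(missing_len, collapse = ", "),
         " (need ##sequence-region, a region row, or a FASTA)",
         call. = FALSE)
  }
  circ <- vapply(contig_ids, function(cid) {
    i <- which(as.character(GenomicRanges::seqnames(regions)) == cid)
    length(i) && identical(tolower(
      as.character(S4Vectors::mcols(regions)$Is_circular[i[1]] %||% "false")),
      "true")
  }, logical(1))
  contigs <- data.frame(contig_id = contig_ids,
                        length = unlist(lens[contig_ids]),
                        circular = unname(circ),
                        stringsAsFactors = FALSE)

  features <- if (length(cds)) {
    fam <- lapply(seq_along(cds), function(i) {
      f <- character()
      dbx <- cmd$Dbxref[[i]]
      if (!is.null(dbx)) {
        f <- c(f, sub("^Pfam:", "", grep("^Pfam:", dbx, value = TRUE)))
      }
      pf <- if (is.null(cmd$pfam)) NULL else unlist(cmd$pfam[i])
      pf <- pf[!is.na(pf)]
      if (length(pf)) {
        f <- c(f, unlist(strsplit(pf, ",")))
      }
      sort(unique(trimws(f)))
    })
    strands <- as.character(BiocGenerics::strand(cds))
    if (any(!strands %in% c("+", "-"))) {
      stop("unknown strand in ", gff_path, call. = FALSE)
    }
    data.frame(
      feature_id = as.character(cmd$ID),
      contig_id = as.character(GenomicRanges::seqnames(cds)),
      start = BiocGenerics::start(cds),
      end = BiocGenerics::end(cds),
      strand = strands,
      protein_id = as.character(cmd$protein_id %||% cmd$ID),
      product = as.character(cmd$product %||% NA_character_),
      stringsAsFactors = FALSE
    )
  } else {
    empty_features()
  }
  if (length(cds)) features$families <- fam

  rmd <- if (length(regions)) S4Vectors::mcols(regions) else NULL
  gid <- genome_id %||%
    (if (!is.null(rmd) && !is.null(rmd$genome_id)) rmd$genome_id[1] else
       sub("\\.gff3?$", "", basename(gff_path)))
  org <- organism %||%
    (if (!is.null(rmd) && !is.null(rmd$organism)) rmd$organism[1] else
       NA_character_)
  genome_record(gid, org, contigs, features)
}

#' Write a genome record as GFF3
#'
#' Emits `##sequence-region` directives, one `region` row per contig
#' (carrying `genome_id`, `organism` and `Is_circular`), and one CDS row per
#' feature with `Dbxref=Pfam:` family annotations, so that
#' [read_annotations()] reproduces the record.
#'
#' @param genome a [genome_record()].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  ct <- genome$contigs
  ft <- genome$features
  seqinfo <- GenomeInfoDb::Seqinfo(seqnames = ct$contig_id,
                                   seqlengths = ct$length)
  reg <- GenomicRanges::GRanges(
    seqnames = ct$contig_id,
    ranges = IRanges::IRanges(start = 1L, end = ct$length),
    strand = "+", seqinfo = seqinfo
  )
  S4Vectors::mcols(reg)$type <- "region"
  S4Vectors::mcols(reg)$ID <- ct$contig_id
  S4Vectors::mcols(reg)$Is_circular <-
    ifelse(ct$circular, "true", NA_character_)
  S4Vectors::mcols(reg)$genome_id <- genome$genome_id
  S4Vectors::mcols(reg)$organism <- genome$organism
  grs <- reg
  if (nrow(ft)) {
    cds <- GenomicRanges::GRanges(
      seqnames = ft$contig_id,
      ranges = IRanges::IRanges(start = ft$start, end = ft$end),
      strand = ft$strand, seqinfo = seqinfo
    )
    S4Vectors::mcols(cds)$type <- "CDS"
    S4Vectors::mcols(cds)$phase <- 0L
    S4Vectors::mcols(cds)$ID <- ft$feature_id
    S4Vectors::mcols(cds)$protein_id <- ft$protein_id
    S4Vectors::mcols(cds)$product <- ft$product
    S4Vectors::mcols(cds)$Dbxref <- IRanges::CharacterList(
      lapply(ft$families, function(f) {
        if (length(f)) paste0("Pfam:", f) else character()
      })
    )
    S4Vectors::mcols(cds)$Is_circular <- NA_character_
    S4Vectors::mcols(cds)$genome_id <- NA_character_
    S4Vectors::mcols(cds)$organism <- NA_character_
    S4Vectors::mcols(reg)$Dbxref <-
      IRanges::CharacterList(rep(list(character()), length(reg)))
    S4Vectors::mcols(reg)$protein_id <- NA_character_
    S4Vectors::mcols(reg)$product <- NA_character_
    S4Vectors::mcols(reg)$phase <- NA_integer_
    grs <- c(reg, cds)
  }
  rtracklayer::export(grs, path, format = "gff3")
  invisible(path)
}
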