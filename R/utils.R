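## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific sub-seed from a master seed; keeps every
## consumer on its own reproducible stream while staying within 32-bit range.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

## First whitespace-delimited token of an organism string == genus.
genus_of <- function(organism) {
  vapply(strsplit(as.character(organism), "\\s+"),
         function(x) if (length(x)) x[[1]] else NA_character_,
         character(1))
}

assert_aa_sequence <- function(seq, id = "<sequence>") {
  if (!nzchar(seq)) {
    stop(sprintf("sequence for '%s' is empty", id), call. = FALSE)
  }
  bad <- setdiff(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("sequence for '%s' contains invalid residues: %s",
                 id, paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
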