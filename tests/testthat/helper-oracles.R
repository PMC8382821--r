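## Independent oracles, written against the definitions rather than the
## package internals.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

blosum62_ref <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

## Brute-force affine-gap local alignment score: three-state DP written
## directly from the recurrences (gap of length k costs open + k*extend).
oracle_sw_score <- function(a, b, S = blosum62_ref,
                            gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -Inf
  M <- matrix(0, n + 1, m + 1)   # best ending in a match/mismatch or empty
  X <- matrix(NEG, n + 1, m + 1) # ending with gap in b
  Y <- matrix(NEG, n + 1, m + 1) # ending with gap in a
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      M[i + 1, j + 1] <- max(0,
                             S[ca[i], cb[j]] +
                               max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

## Union-find connected components over an edge list.
oracle_components <- function(nodes, from, to) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ri <- find(match(from[k], nodes))
    rj <- find(match(to[k], nodes))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  split(nodes, roots)
}

## Exhaustive in-window triple enumeration: for every gene with a family
## of the focal activity, list neighborhoods by rank and test whether each
## remaining activity is represented within +/- window ORFs.
oracle_find_3gc_genomes <- function(genomes, schema, focal, window) {
  hits <- character()
  for (g in genomes) {
    ft <- g$features
    for (contig in unique(ft$contig_id)) {
      sub <- ft[ft$contig_id == contig, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      acts <- lapply(sub$families, function(f) {
        names(schema)[vapply(schema, function(s) any(s %in% f),
                             logical(1))]
      })
      for (i in seq_len(nrow(sub))) {
        if (!focal %in% acts[[i]]) next
        lo <- max(1, i - window); hi <- min(nrow(sub), i + window)
        nb <- setdiff(seq(lo, hi), i)
        others <- setdiff(names(schema), focal)
        ok <- all(vapply(others, function(a) {
          any(vapply(nb, function(j) a %in% acts[[j]], logical(1)))
        }, logical(1)))
        if (ok) hits <- c(hits, g$genome_id)
      }
    }
  }
  unique(hits)
}

## Unrooted bipartition set of a binary/multifurcating tree, as a
## canonical character vector (each split = sorted smaller side).
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  desc <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  internal <- setdiff(unique(tree$edge[, 1]), seq_len(n))
  splits <- character()
  for (nd in internal) {
    side <- sort(desc(nd))
    if (length(side) <= 1L || length(side) >= n - 1L) next
    other <- setdiff(tips, side)
    canon <- if (length(side) < length(other) ||
                 (length(side) == length(other) &&
                  paste(side, collapse = ",") <
                  paste(other, collapse = ","))) side else other
    splits <- c(splits, paste(canon, collapse = ","))
  }
  unique(splits)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(ape::unroot(t1))
  b2 <- oracle_bipartitions(ape::unroot(t2))
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

## Random unrooted binary tree with positive branch lengths, as both a
## phylo object and its additive (patristic) distance matrix.
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 0.5))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

## Tiny hand-built genome: consecutive genes on one linear contig with
## given family annotations.
toy_genome <- function(id, fam_list, organism = "Testus exemplaris",
                       circular = FALSE, starts = NULL) {
  k <- length(fam_list)
  if (is.null(starts)) starts <- seq(100, by = 1500, length.out = k)
  ft <- data.frame(
    feature_id = sprintf("%s_f%02d", id, seq_len(k)),
    contig_id = paste0(id, "_c"), start = starts,
    end = starts + 900, strand = rep(c("+", "-"), length.out = k),
    protein_id = sprintf("%s_p%02d", id, seq_len(k)),
    product = "x", stringsAsFactors = FALSE)
  ft$families <- fam_list
  ct <- data.frame(contig_id = paste0(id, "_c"),
                   length = max(ft$end) + 500, circular = circular)
  genome_record(id, organism, ct, ft)
}
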