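test_that("the packaged motif is the expected degenerate 30-mer", {
  m <- consensus_motif(aza_at_motif())
  expect_equal(nchar(m$pattern), 30L)
  expect_equal(m$constrained_count, 16L)
})

test_that("progressive MSA handles identical and near-identical inputs", {
  s <- random_aa(80)
  two <- protein_set(c("a", "b"), c(s, s))
  msa <- progressive_msa(two)
  expect_false(any(grepl("-", msa$seqs)))
  expect_equal(unname(degap(msa)), c(s, s))

  sub <- s
  substr(sub, 40, 40) <- if (substr(s, 40, 40) == "A") "R" else "A"
  msa2 <- progressive_msa(protein_set(c("a", "b"), c(s, sub)))
  expect_false(any(grepl("-", msa2$seqs)))
  expect_equal(msa2$ncol, 80L)

  expect_error(progressive_msa(protein_set("solo", s)), ">= 2")
})

test_that("substitution-only copies align gap-free at seed length", {
  set.seed(91)
  seed <- random_aa(150)
  ps <- protein_set(sprintf("c%d", 1:6),
                    vapply(1:6, function(i)
                      mutate_protein(seed, 0.8, 900 + i), ""))
  msa <- progressive_msa(ps)
  expect_equal(msa$ncol, 150L)
  expect_false(any(grepl("-", msa$seqs)))
  expect_equal(unname(degap(msa)), ps$sequence)
})

test_that("consensus applies plurality, case and tie rules per column", {
  msa <- protein_msa(paste0("r", 1:6),
                     c("AAGC-A", "AAGC-A", "AAGC-A",
                       "AAGAGA", "AGGAGA", "ACGAGC"))
  cons <- derive_consensus(msa, strong_fraction = 0.9,
                           weak_fraction = 0.5)
  pat <- strsplit(cons$pattern, "")[[1]]
  expect_equal(pat[1], "A")        # 6/6 unanimity, strong
  expect_equal(pat[2], "a")        # 4/6 = 0.67 weak
  expect_equal(pat[3], "G")        # unanimity
  expect_equal(pat[4], "X")        # 3 C vs 3 A plurality tie
  expect_equal(pat[5], "G")        # gaps excluded: 3/3 gap-free are G
  expect_equal(pat[6], "a")        # 5/6 = 0.83 weak
})

test_that("consensus of identical rows is the sequence, all uppercase", {
  s <- random_aa(60)
  msa <- protein_msa(paste0("r", 1:5), rep(s, 5))
  cons <- derive_consensus(msa)
  expect_equal(cons$pattern, s)
})

test_that("consensus is invariant to row order", {
  set.seed(92)
  seed <- random_aa(100)
  seqs <- vapply(1:8, function(i) mutate_protein(seed, 0.7, i), "")
  c1 <- derive_consensus(protein_msa(paste0("r", 1:8), seqs))
  perm <- sample(8)
  c2 <- derive_consensus(protein_msa(paste0("r", perm), seqs[perm]))
  expect_equal(c1$pattern, c2$pattern)
})

test_that("consensus_span extracts by explicit coordinates", {
  cons <- consensus_motif("ACDEFGHIKL")
  expect_equal(consensus_span(cons, 3, 7)$pattern, "DEFGH")
  expect_error(consensus_span(cons, 0, 5))
})

test_that("scan_motif equals a position-by-position oracle", {
  oracle_scan <- function(seq, pattern, budget) {
    pc <- strsplit(toupper(pattern), "")[[1]]
    sc <- strsplit(toupper(seq), "")[[1]]
    hits <- integer(); mm <- integer()
    if (length(sc) < length(pc)) {
      return(data.frame(position = hits, mismatches = mm))
    }
    for (off in 1:(length(sc) - length(pc) + 1)) {
      bad <- 0L
      for (k in seq_along(pc)) {
        if (pc[k] != "X" && sc[off + k - 1] != pc[k]) bad <- bad + 1L
      }
      if (bad <= budget) { hits <- c(hits, off); mm <- c(mm, bad) }
    }
    data.frame(position = hits, mismatches = mm)
  }
  set.seed(93)
  for (i in 1:100) {
    seq <- random_aa(sample(10:60, 1))
    k <- sample(3:8, 1)
    pat <- paste(sample(c(AA20, "X", "X", "X"), k, TRUE), collapse = "")
    budget <- sample(0:2, 1)
    expect_equal(scan_motif(seq, pat, budget),
                 oracle_scan(seq, pat, budget),
                 info = paste(seq, pat, budget))
  }
})

test_that("motif scanning honours X, case, budget, and short sequences", {
  expect_equal(scan_motif("MKVLAW", "kXl")$position, 2L)
  expect_equal(nrow(scan_motif("MK", "MKVLAW")), 0L)
  h <- scan_motif("MKVLAW", "KGL", 1)
  expect_equal(h$position, 2L)
  expect_equal(h$mismatches, 1L)
  ## overlapping matches all reported
  expect_equal(scan_motif("AAAA", "AA")$position, c(1L, 2L, 3L))
})

test_that("an exact planted 30-mer instantiation is found once", {
  set.seed(94)
  motif <- aza_at_motif()
  chars <- strsplit(motif, "")[[1]]
  chars[chars == "X"] <- sample(AA20, sum(chars == "X"), TRUE)
  inst <- paste(chars, collapse = "")
  host <- random_aa(300)
  substr(host, 101, 130) <- inst
  h <- scan_motif(host, motif)
  expect_equal(h$position, 101L)
  expect_equal(h$mismatches, 0L)
})

test_that("random-sequence hit rate matches the analytic null", {
  ## 16 constrained positions: exact-match probability 20^-16 per offset;
  ## over 2e5 offsets the expected count is ~0 well within 3 sigma
  set.seed(95)
  s <- random_aa(200029)
  h <- scan_motif(s, aza_at_motif())
  n_off <- 200000
  expected <- n_off * 20^-16
  sigma <- sqrt(n_off * 20^-16)
  expect_lte(nrow(h), expected + 3 * sigma)  # i.e. zero hits
})

test_that("screen precision counts in-3GC vs off-target hits", {
  ds <- generate_dataset(synthetic_config(
    rng_seed = 96, n_planted_3gc = 6, motif_plants = 6,
    motif_decoy_plants = 0,
    decoy_spec = c(two_gene = 1, scattered = 1, none = 1)))
  cl <- find_3gc(ds$genomes)
  sc <- screen_and_validate(ds$proteome, aza_at_motif(), cl)
  expect_equal(sc$n_hits, 6L)
  expect_equal(sc$precision, 1.0)
  expect_equal(sc$n_organisms_in_3gc,
               length(unique(ds$truth$clusters$organism)))

  ## one decoy instantiation drags precision below 1
  ds2 <- generate_dataset(synthetic_config(
    rng_seed = 97, n_planted_3gc = 6, motif_plants = 6,
    motif_decoy_plants = 1,
    decoy_spec = c(two_gene = 1, scattered = 1, none = 1)))
  cl2 <- find_3gc(ds2$genomes)
  sc2 <- screen_and_validate(ds2$proteome, aza_at_motif(), cl2)
  expect_equal(sc2$n_hits, 7L)
  expect_equal(sc2$precision, 6 / 7)

  ## no hits -> undefined precision, not zero
  ps <- protein_set("q", random_aa(100), organism = "Quietus q")
  sc3 <- screen_and_validate(ps, aza_at_motif(), cl[0, ])
  expect_true(is.na(sc3$precision))

  ## unmapped hits excluded from the denominator with a warning
  inst <- ds$proteome$sequence[ds$proteome$protein_id ==
                                 ds$truth$motif_plants$protein_id[1]]
  ps4 <- protein_set("floating", inst, organism = "Nowherus n")
  expect_warning(sc4 <- screen_and_validate(ps4, aza_at_motif(),
                                            cl[0, ]), "mapping")
  expect_equal(sc4$n_unmapped, 1L)
  expect_true(is.na(sc4$precision))
})
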