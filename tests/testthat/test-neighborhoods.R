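schema <- activity_schema()
fam <- function(...) list(...)

test_that("activity schema validates disjointness", {
  expect_error(activity_schema(aminotransferase = "PF00107"),
               "disjoint")
  expect_error(activity_schema(phosphatase = character()), "at least one")
})

test_that("window truncates at linear contig ends", {
  g <- toy_genome("lin", replicate(6, character(), simplify = FALSE))
  nb <- extract_neighborhood(g, "lin_f01", 3)
  expect_equal(nb$neighbors$offset, c(1L, 2L, 3L))
  nb_end <- extract_neighborhood(g, "lin_f06", 3)
  expect_equal(nb_end$neighbors$offset, c(-3L, -2L, -1L))
  nb_mid <- extract_neighborhood(g, "lin_f04", 3)
  expect_equal(nb_mid$neighbors$offset, c(-3L, -2L, -1L, 1L, 2L))
  expect_error(extract_neighborhood(g, "nope", 3), "unknown feature")
})

test_that("circular contigs wrap without duplicating features", {
  g <- toy_genome("cir", replicate(5, character(), simplify = FALSE),
                  circular = TRUE)
  for (f in g$features$feature_id) {
    nb <- extract_neighborhood(g, f, 3)
    ## 5 genes, window 3: all 4 non-focal genes, each exactly once
    expect_equal(sort(nb$neighbors$feature_id),
                 sort(setdiff(g$features$feature_id, f)))
  }
  ## enumeration oracle on a larger circle: window 2 each side
  g8 <- toy_genome("c8", replicate(8, character(), simplify = FALSE),
                   circular = TRUE)
  nb <- extract_neighborhood(g8, "c8_f01", 2)
  expect_setequal(nb$neighbors$feature_id,
                  c("c8_f07", "c8_f08", "c8_f02", "c8_f03"))
})

test_that("neighborhood extraction ignores strand", {
  g <- toy_genome("s", replicate(5, character(), simplify = FALSE))
  g$features$strand <- c("-", "+", "-", "-", "+")
  nb <- extract_neighborhood(g, "s_f03", 2)
  expect_equal(nb$neighbors$offset, c(-2L, -1L, 1L, 2L))
})

test_that("a cluster-like layout places the dehydrogenase at offset +2", {
  ## aminotransferase, phosphatase, dehydrogenase consecutive,
  ## transporters beyond
  g <- toy_genome("bv", fam("PF00202", "PF00459", "PF00107",
                            "PF90001", "PF90002"))
  nb <- extract_neighborhood(g, "bv_f01", 3)
  dh_off <- nb$neighbors$offset[vapply(nb$neighbors$families,
                                       function(f) "PF00107" %in% f,
                                       logical(1))]
  expect_equal(dh_off, 2L)
})

test_that("colouring records activities and phosphatase class", {
  pos <- toy_genome("pos", fam("PF90009", "PF00202", "PF00459",
                               "PF00107", "PF90010"))
  two <- toy_genome("two", fam("PF00202", "PF00107", "PF90011"))
  both <- toy_genome("mix", fam("PF00202", "PF00459", "PF13419"))
  ps <- protein_set(
    c("pos_p02", "two_p01", "mix_p01"),
    rep("MKVLAWMKVLAW", 3),
    organism = "Testus exemplaris",
    source_gene = c("pos_f02", "two_f01", "mix_f01"))
  hits <- data.frame(query_id = "pos_p02", subject_id = "two_p01",
                     raw_score = 100, bit_score = 40, evalue = 1e-9,
                     alignment_score = 9, percent_identity = 90,
                     alignment_length = 100L, query_coverage = 95,
                     subject_coverage = 95)
  net <- build_network(hits, list(metric = "percent_identity",
                                  value = 40), ps)
  expect_warning(
    net <- color_nodes(net, list(pos, two, both), ps, schema, 3),
    "both")
  nd <- net$nodes
  row <- function(id) which(nd$protein_id == id)
  expect_setequal(nd$activities[[row("pos_p02")]],
                  c("dehydrogenase", "phosphatase"))
  expect_equal(nd$phosphatase_class[row("pos_p02")],
               "inositol_phosphatase")
  expect_equal(nd$phosphatase_class[row("two_p01")], "none")
  expect_equal(nd$phosphatase_class[row("mix_p01")], "both")
  expect_false(any(nd$unmapped))

  ## nodes without a genomic mapping are flagged, never dropped
  ps_un <- protein_set("ghost", "MKVLAWMKVLAW")
  net_un <- build_network(hits[0, ], list(metric = "percent_identity",
                                          value = 40), ps_un)
  net_un <- color_nodes(net_un, list(pos), ps_un, schema, 3)
  expect_true(net_un$nodes$unmapped)
  expect_equal(nrow(net_un$nodes), 1L)
})

test_that("co-occurrence fractions equal a brute-force recount", {
  set.seed(71)
  ds <- generate_dataset(synthetic_config(rng_seed = 71,
                                          n_planted_3gc = 6,
                                          decoy_spec = c(two_gene = 0,
                                                         scattered = 0,
                                                         none = 0)))
  focal_ids <- ds$truth$clusters$at_feature
  prot <- ds$proteome[ds$proteome$source_gene %in% focal_ids, ]
  ## all planted aminotransferases in one cluster
  n <- nrow(prot)
  hits <- data.frame(query_id = prot$protein_id[-n],
                     subject_id = prot$protein_id[-1],
                     raw_score = 100, bit_score = 40, evalue = 1e-9,
                     alignment_score = 9, percent_identity = 90,
                     alignment_length = 100L, query_coverage = 95,
                     subject_coverage = 95)
  net <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 40), prot))
  net <- color_nodes(net, ds$genomes, prot, schema, 3)
  co <- cluster_cooccurrence(net, ds$genomes, prot, 3, 0.20)

  ## brute-force recount over neighborhoods
  recount <- list()
  for (i in seq_len(nrow(prot))) {
    g <- ds$genomes[[match(sub("_p.*", "", prot$protein_id[i]),
                           vapply(ds$genomes, `[[`, "", "genome_id"))]]
    nb <- extract_neighborhood(g, prot$source_gene[i], 3)
    recount[[i]] <- unique(unlist(nb$neighbors$families))
  }
  for (r in seq_len(nrow(co))) {
    expected <- mean(vapply(recount, function(s) co$family[r] %in% s,
                            logical(1)))
    expect_equal(co$fraction[r], expected)
  }
  ## planted cluster: dehydrogenase & phosphatase families co-occur fully
  dh_ph <- co[co$family %in% unlist(schema[c("dehydrogenase",
                                             "phosphatase")]), ]
  expect_equal(sum(dh_ph$fraction[dh_ph$family %in%
                                    schema$dehydrogenase]), 1)
  expect_equal(sum(dh_ph$fraction[dh_ph$family %in% schema$phosphatase]),
               1)

  ## reporting threshold: below-threshold families retained, not reported
  expect_true(all(co$reported == (co$fraction >= 0.20)))
})
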