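## small synthetic hit table helper
mk_hits <- function(from, to, pident) {
  n <- length(from)
  data.frame(query_id = from, subject_id = to,
             raw_score = rep(100, n), bit_score = rep(40, n),
             evalue = rep(1e-9, n), alignment_score = rep(9, n),
             percent_identity = pident, alignment_length = rep(100L, n),
             query_coverage = rep(95, n), subject_coverage = rep(95, n),
             stringsAsFactors = FALSE)
}

test_that("edges are included iff the metric passes the threshold", {
  hits <- mk_hits(c("a", "a", "b"), c("b", "c", "c"), c(80, 45, 30))
  ps <- protein_set(letters[1:4], rep("MKVLAWMKVLAW", 4))
  net0 <- build_network(hits, list(metric = "percent_identity",
                                   value = 0), ps)
  expect_equal(nrow(net0$edges), 3L)  # threshold 0 keeps every hit pair
  net50 <- build_network(hits, list(metric = "percent_identity",
                                    value = 50), ps)
  expect_equal(nrow(net50$edges), 1L)
  ## isolated query nodes are retained
  expect_equal(nrow(net50$nodes), 4L)
  expect_error(build_network(hits, list(metric = "weirdness", value = 1)),
               "metric")
})

test_that("raising the threshold never adds edges (sweep 40..70)", {
  set.seed(52)
  hits <- mk_hits(paste0("n", 1:30), paste0("n", 31:60),
                  runif(30, 20, 90))
  prev <- NULL
  for (t in seq(40, 70, by = 5)) {
    net <- build_network(hits, list(metric = "percent_identity",
                                    value = t))
    key <- paste(net$edges$query_id, net$edges$subject_id)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("clusters are numbered by size with lexicographic tie-break", {
  ## two components of size 3 (tie) and one of size 2
  hits <- mk_hits(c("m1", "m2", "b1", "b2", "z1"),
                  c("m2", "m3", "b2", "b3", "z2"),
                  rep(90, 5))
  ps <- protein_set(c("m1", "m2", "m3", "b1", "b2", "b3", "z1", "z2",
                      "lonely"),
                    rep("MKVLAWMKVLAW", 9))
  net <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 40), ps))
  nodes <- net$nodes
  cid <- function(id) nodes$cluster_id[nodes$protein_id == id]
  ## tie between {m1,m2,m3} and {b1,b2,b3}: 'b1' < 'm1' so b-component
  ## gets cluster 1
  expect_equal(cid("b1"), 1L)
  expect_equal(cid("m1"), 2L)
  expect_equal(cid("z1"), 3L)
  expect_true(nodes$is_singleton[nodes$protein_id == "lonely"])
  expect_true(is.na(cid("lonely")))
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(53)
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    nodes <- paste0("v", seq_len(n))
    m <- sample(0:60, 1)
    from <- sample(nodes, m, replace = TRUE)
    to <- sample(nodes, m, replace = TRUE)
    keep <- from != to
    hits <- mk_hits(from[keep], to[keep], rep(90, sum(keep)))
    ps <- protein_set(nodes, rep("MKVLAWMKVLAW", n))
    net <- cluster_network(build_network(
      hits, list(metric = "percent_identity", value = 40), ps))
    comp <- oracle_components(nodes, hits$query_id, hits$subject_id)
    sizes <- sort(lengths(comp))
    expect_equal(length(unique(na.omit(net$nodes$cluster_id))),
                 sum(sizes >= 2))
    expect_equal(sum(net$nodes$is_singleton), sum(sizes == 1))
    ## partitions agree, not just counts
    for (cc in comp) {
      ids <- net$nodes$cluster_id[match(cc, net$nodes$protein_id)]
      expect_equal(length(unique(ids)), 1L)
    }
  }
})

test_that("cluster partition is invariant to hit ordering", {
  set.seed(54)
  hits <- mk_hits(paste0("n", sample(1:20, 30, TRUE)),
                  paste0("n", sample(21:40, 30, TRUE)), runif(30, 50, 90))
  ps <- protein_set(paste0("n", 1:40), rep("MKVLAWMKVLAW", 40))
  n1 <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 60), ps))
  n2 <- cluster_network(build_network(
    hits[sample(nrow(hits)), ], list(metric = "percent_identity",
                                     value = 60), ps))
  expect_equal(n1$nodes$cluster_id, n2$nodes$cluster_id)
})

test_that("threshold_sweep is consistent and monotone", {
  set.seed(55)
  hits <- mk_hits(paste0("n", sample(1:15, 40, TRUE)),
                  paste0("n", sample(1:15, 40, TRUE)), runif(40, 30, 95))
  hits <- hits[hits$query_id != hits$subject_id, ]
  ps <- protein_set(paste0("n", 1:15), rep("MKVLAWMKVLAW", 15))

  ## single-threshold sweep equals build+cluster
  sw <- threshold_sweep(hits, 50, proteins = ps)
  net <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 50), ps))
  expect_equal(sw$n_clusters,
               length(unique(na.omit(net$nodes$cluster_id))))
  expect_equal(sw$n_singletons, sum(net$nodes$is_singleton))

  ## clusters + singletons never decreases with threshold (20 datasets)
  for (rep in 1:20) {
    h <- mk_hits(paste0("n", sample(1:12, 25, TRUE)),
                 paste0("n", sample(1:12, 25, TRUE)),
                 runif(25, 10, 100))
    h <- h[h$query_id != h$subject_id, ]
    if (!nrow(h)) next
    p <- protein_set(paste0("n", 1:12), rep("MKVLAWMKVLAW", 12))
    sw <- threshold_sweep(h, seq(40, 70, 10), proteins = p)
    tot <- sw$n_clusters + sw$n_singletons
    expect_true(all(diff(tot) >= 0))
  }
})

test_that("tracked genus families merge at 40 and split at 70", {
  fams <- make_protein_families(n_families = 3, members_per_family = 4,
                                rng_seed = 61)
  hits <- all_vs_all(fams)
  tracked <- fams$protein_id
  sw <- threshold_sweep(hits, c(40, 70), proteins = fams,
                        tracked = tracked)
  expect_equal(sw$n_clusters[1], 1L)
  expect_equal(sw$n_clusters[2], 3L)
  part70 <- sw$partition[[2]]
  genus <- sub("\\s.*$", "", fams$organism[match(tracked,
                                                 fams$protein_id)])
  expect_equal(length(unique(part70)), 3L)
  ## at 70 co-membership coincides with genus
  expect_true(all(tapply(part70, genus,
                         function(x) length(unique(x)) == 1L)))
})

test_that("families below the identity threshold stay separate", {
  ## cross-family identity well under 40%: the two families must form
  ## exactly two components at the 40% threshold (local-alignment
  ## identity runs a few points above the nominal substitution identity,
  ## so the cross level is set clear of the threshold)
  fams <- make_protein_families(n_families = 2, members_per_family = 6,
                                within_identity = 0.8,
                                cross_identity = 0.30, rng_seed = 62)
  hits <- all_vs_all(fams)
  net <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 40), fams))
  expect_equal(length(unique(na.omit(net$nodes$cluster_id))), 2L)
  expect_equal(sum(net$nodes$is_singleton), 0L)
  genus <- sub("\\s.*$", "", fams$organism)
  expect_true(all(tapply(net$nodes$cluster_id, genus,
                         function(x) length(unique(x)) == 1L)))
})

test_that("genus labels follow the 75% majority rule", {
  hits <- mk_hits(c("a1", "a2", "a3", "x1"), c("a2", "a3", "x1", "a1"),
                  rep(90, 4))
  ps <- protein_set(c("a1", "a2", "a3", "x1"), rep("MKVLAWMKVLAW", 4),
                    organism = c("Alpha a", "Alpha b", "Alpha c",
                                 "Xi z"))
  net <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 40), ps))
  ## 3 of 4 = 75% -> single-genus label
  expect_equal(unname(label_clusters_by_genus(net)), "Alpha")

  ps2 <- protein_set(c("a1", "a2", "a3", "x1"), rep("MKVLAWMKVLAW", 4),
                     organism = c("Alpha a", "Alpha b", "Xi y", "Xi z"))
  net2 <- cluster_network(build_network(
    hits, list(metric = "percent_identity", value = 40), ps2))
  expect_equal(unname(label_clusters_by_genus(net2)), "Alpha/Xi")
})
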