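#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions the simulator emulates: bacterial contigs
#' carrying planted aminotransferase/phosphatase/dehydrogenase three-gene
#' clusters (3GCs) in either observed gene order, with either phosphatase
#' family, at a controlled sequence identity to fixed seed enzymes;
#' decoy genomes with incomplete or scattered clusters; and proteomes with
#' planted consensus-motif instances.
#'
#' @param rng_seed integer master seed; all randomness flows from it.
#' @param n_planted_3gc number of positive genomes (one planted 3GC each).
#' @param target_identity_to_seed fraction in (0, 1]: ungapped identity of
#'   planted enzyme copies to the bundled seed enzymes.
#' @param order_signature `"A-P-D"`, `"A-D-P"`, or both (recycled across
#'   positive genomes): gene order of the planted cluster.
#' @param phosphatase_class `"inositol_phosphatase"`, `"HAD_hydrolase"`, or
#'   both (recycled across positive genomes).
#' @param window_spacing maximum ORF offset between any two cluster
#'   members (>= 2; three genes in fixed order cannot fit in less).
#' @param decoy_spec named counts of decoy genomes:
#'   `two_gene` (one activity omitted), `scattered` (all three activities
#'   placed more than a detection window apart) and `none` (no schema
#'   genes at all).
#' @param motif_plants number of positive genomes whose planted
#'   aminotransferase carries an exact instantiation of the packaged
#'   consensus motif.
#' @param motif_decoy_plants number of decoy (non-3GC) proteins carrying an
#'   exact motif instantiation.
#' @param n_decoy_orfs_range range of background ORF counts per genome.
#' @param genus_pool genus names recycled across genomes (invented names;
#'   the genus is the first token of the organism string).
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(rng_seed = 1L,
                             n_planted_3gc = 10L,
                             target_identity_to_seed = 0.6,
                             order_signature = c("A-P-D", "A-D-P"),
                             phosphatase_class = c("inositol_phosphatase",
                                                   "HAD_hydrolase"),
                             window_spacing = 2L,
                             decoy_spec = c(two_gene = 3L, scattered = 3L,
                                            none = 4L),
                             motif_plants = 0L,
                             motif_decoy_plants = 0L,
                             n_decoy_orfs_range = c(12L, 20L),
                             genus_pool = c("Bacillimimus", "Paenimimus",
                                            "Chitinomimus")) {
  stopifnot(n_planted_3gc >= 0, motif_plants >= 0, motif_decoy_plants >= 0)
  if (target_identity_to_seed <= 0 || target_identity_to_seed > 1) {
    stop("target_identity_to_seed must be in (0, 1]", call. = FALSE)
  }
  if (!all(order_signature %in% c("A-P-D", "A-D-P"))) {
    stop("order_signature must be 'A-P-D' or 'A-D-P'", call. = FALSE)
  }
  if (!all(phosphatase_class %in% c("inositol_phosphatase",
                                    "HAD_hydrolase"))) {
    stop("unknown phosphatase_class", call. = FALSE)
  }
  if (window_spacing < 2) {
    stop("window_spacing < 2 cannot fit three genes in a fixed order",
         call. = FALSE)
  }
  decoy_spec <- decoy_spec[c("two_gene", "scattered", "none")]
  decoy_spec[is.na(decoy_spec)] <- 0L
  names(decoy_spec) <- c("two_gene", "scattered", "none")
  if (any(decoy_spec < 0)) stop("decoy counts must be >= 0", call. = FALSE)
  if (motif_plants > n_planted_3gc) {
    stop("motif_plants cannot exceed n_planted_3gc", call. = FALSE)
  }
  structure(
    list(rng_seed = as.integer(rng_seed),
         n_planted_3gc = as.integer(n_planted_3gc),
         n_genomes = as.integer(n_planted_3gc + sum(decoy_spec)),
         target_identity_to_seed = target_identity_to_seed,
         order_signature = order_signature,
         phosphatase_class = phosphatase_class,
         window_spacing = as.integer(window_spacing),
         decoy_spec = decoy_spec,
         motif_plants = as.integer(motif_plants),
         motif_decoy_plants = as.integer(motif_decoy_plants),
         n_decoy_orfs_range = as.integer(n_decoy_orfs_range),
         genus_pool = genus_pool),
    class = "synthetic_config"
  )
}

#' Bundled synthetic seed enzymes
#'
#' Four fixed, synthetic length-400 protein sequences standing in for the
#' seed enzymes of the three cluster activities (aminotransferase-like,
#' dehydrogenase-like, and one phosphatase-like seed per phosphatase
#' class). The aminotransferase-like seed carries one exact instantiation
#' of [aza_at_motif()] at positions 145-174. These are synthetic sequences,
#' not real enzymes.
#'
#' @return a [protein_set()] with ids `seed_at`, `seed_dh`,
#'   `seed_ph_inositol`, `seed_ph_had`.
#' @export
seed_proteins <- function() {
  path <- system.file("extdata", "synthetic_seed_proteins.fasta",
                      package = "azamine", mustWork = TRUE)
  read_fasta(path)
}

#' Mutate a protein to a target ungapped identity
#'
#' Substitutes exactly `round((1 - target_identity) * L)` positions, chosen
#' without replacement, each replaced by a uniformly drawn *different*
#' residue. Deterministic given `rng_seed`; indels are never introduced.
#'
#' @param seed_sequence protein sequence (length >= 20).
#' @param target_identity fraction in (0, 1].
#' @param rng_seed integer seed.
#' @return the mutated sequence.
#' @export
mutate_protein <- function(seed_sequence, target_identity, rng_seed) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]", call. = FALSE)
  }
  chars <- strsplit(seed_sequence, "")[[1]]
  L <- length(chars)
  if (L < 20L) stop("seed sequence must have length >= 20", call. = FALSE)
  n_sub <- round((1 - target_identity) * L)
  if (n_sub == 0L) return(seed_sequence)
  with_seed(rng_seed, {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1L)
    }
  })
  paste(chars, collapse = "")
}

random_protein <- function(length) {
  paste(sample(AA_STANDARD, length, replace = TRUE), collapse = "")
}

## One random decoy family accession from a dummy space disjoint from the
## activity schema ("PF9xxxx").
decoy_family <- function() sprintf("PF9%04d", sample.int(10000L, 1L) - 1L)

## Fill the X wildcards of a motif with random residues -> one exact
## instantiation (constrained positions preserved).
instantiate_motif <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  chars[chars == "X"] <- sample(AA_STANDARD, sum(chars == "X"),
                                replace = TRUE)
  paste(chars, collapse = "")
}

activity_families_draw <- function(activity, phosphatase_class = NULL) {
  switch(activity,
    aminotransferase = "PF00202",
    dehydrogenase = sample(c("PF00107", "PF08240", "PF16912"), 1L),
    phosphatase = if (identical(phosphatase_class, "inositol_phosphatase"))
      "PF00459" else sample(c("PF13419", "PF12710", "PF07081"), 1L),
    stop("unknown activity: ", activity, call. = FALSE))
}

#' Generate a synthetic dataset with ground truth
#'
#' Emits annotated genomes (in memory; see [write_dataset()] for GFF3/FASTA
#' output), a combined proteome, and a ground-truth record of every planted
#' cluster and motif instance. Positive genomes carry one 3GC whose members
#' are mutated copies of the bundled seed enzymes placed in the configured
#' order; decoy genomes carry incomplete or scattered clusters, or none.
#' Intergenic gaps are drawn uniformly from 50-500 bp and genes take either
#' strand with probability 1/2 (detection must be strand-agnostic).
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `genomes` (list of [genome_record()]),
#'   `proteome` (a [protein_set()]), and `truth` (list with `clusters`,
#'   `motif_plants`, and `genome_labels` data frames).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- seed_proteins()
  seed_seq <- stats::setNames(seeds$sequence, seeds$protein_id)
  motif <- aza_at_motif()

  types <- c(rep("positive", config$n_planted_3gc),
             rep("two_gene", config$decoy_spec[["two_gene"]]),
             rep("scattered", config$decoy_spec[["scattered"]]),
             rep("none", config$decoy_spec[["none"]]))
  n <- length(types)
  genomes <- vector("list", n)
  prot_rows <- vector("list", n)
  clusters <- list()
  plants <- list()
  labels <- data.frame(genome_id = character(n), organism = character(n),
                       type = types, stringsAsFactors = FALSE)

  with_seed(config$rng_seed, {
    orders <- rep_len(config$order_signature, config$n_planted_3gc)
    ph_classes <- rep_len(config$phosphatase_class, config$n_planted_3gc)
    motif_idx <- if (config$motif_plants > 0)
      sort(sample.int(config$n_planted_3gc, config$motif_plants)) else
        integer()

    for (g in seq_len(n)) {
      gid <- sprintf("syng%03d", g)
      genus <- config$genus_pool[(g - 1L) %% length(config$genus_pool) + 1L]
      organism <- paste(genus, "synthetica", gid)
      labels$genome_id[g] <- gid
      labels$organism[g] <- organism
      type <- types[g]

      n_bg <- sample(seq(config$n_decoy_orfs_range[1],
                         config$n_decoy_orfs_range[2]), 1L)
      ## per-ORF plan: list of (role, activity)
      roles <- rep("decoy", n_bg)
      acts <- rep(NA_character_, n_bg)
      if (type == "positive") {
        ord <- orders[g]
        letters3 <- strsplit(gsub("-", "", ord), "")[[1]]
        act_of <- c(A = "aminotransferase", P = "phosphatase",
                    D = "dehydrogenase")
        ## gaps between consecutive members, pairwise offsets <= spacing
        combos <- expand.grid(s1 = seq_len(config$window_spacing - 1L),
                              s2 = seq_len(config$window_spacing - 1L))
        combos <- combos[combos$s1 + combos$s2 <= config$window_spacing, ,
                         drop = FALSE]
        pick <- combos[sample.int(nrow(combos), 1L), ]
        ins <- sample.int(n_bg - 6L, 1L) + 2L
        pos3 <- c(ins, ins + pick$s1, ins + pick$s1 + pick$s2)
        orf_roles <- rep("decoy", n_bg + 3L)
        orf_acts <- rep(NA_character_, n_bg + 3L)
        orf_roles[pos3] <- "member"
        orf_acts[pos3] <- act_of[letters3]
      } else if (type == "two_gene") {
        keep <- sample(c("aminotransferase", "dehydrogenase",
                         "phosphatase"), 2L)
        ins <- sample.int(n_bg - 3L, 1L) + 1L
        orf_roles <- rep("decoy", n_bg + 2L)
        orf_acts <- rep(NA_character_, n_bg + 2L)
        orf_roles[c(ins, ins + 1L)] <- "lookalike"
        orf_acts[c(ins, ins + 1L)] <- sort(keep)
      } else if (type == "scattered") {
        sep <- config$window_spacing + 3L
        need <- 1L + 2L * sep
        if (n_bg < need + 2L) n_bg <- need + 2L
        start <- sample.int(n_bg - need, 1L)
        pos3 <- c(start, start + sep, start + 2L * sep)
        orf_roles <- rep("decoy", n_bg)
        orf_acts <- rep(NA_character_, n_bg)
        orf_roles[pos3] <- "lookalike"
        orf_acts[pos3] <- c("aminotransferase", "dehydrogenase",
                            "phosphatase")
      } else {
        orf_roles <- rep("decoy", n_bg)
        orf_acts <- rep(NA_character_, n_bg)
      }

      n_orf <- length(orf_roles)
      ph_class <- if (type == "positive") ph_classes[g] else
        sample(c("inositol_phosphatase", "HAD_hydrolase"), 1L)
      feats <- vector("list", n_orf)
      prots <- vector("list", n_orf)
      cursor <- sample(50:500, 1L)
      for (k in seq_len(n_orf)) {
        fid <- sprintf("%s_f%03d", gid, k)
        pid <- sprintf("%s_p%03d", gid, k)
        role <- orf_roles[k]
        act <- orf_acts[k]
        if (role == "decoy") {
          seqk <- random_protein(sample(200:450, 1L))
          fams <- decoy_family()
        } else {
          seed_id <- switch(act,
            aminotransferase = "seed_at",
            dehydrogenase = "seed_dh",
            phosphatase = if (ph_class == "inositol_phosphatase")
              "seed_ph_inositol" else "seed_ph_had")
          seqk <- mutate_protein(seed_seq[[seed_id]],
                                 config$target_identity_to_seed,
                                 sample.int(2^30, 1L))
          fams <- activity_families_draw(act, ph_class)
        }
        ## exact motif instantiation in selected planted aminotransferases
        if (role == "member" && identical(act, "aminotransferase") &&
            type == "positive" && match(g, motif_idx, nomatch = 0L) > 0L) {
          inst <- instantiate_motif(motif)
          substr(seqk, 145L, 174L) <- inst
          plants[[length(plants) + 1L]] <- data.frame(
            protein_id = pid, position = 145L, in_3gc = TRUE,
            stringsAsFactors = FALSE)
        }
        gene_len <- 3L * nchar(seqk) + 3L
        start <- cursor
        feats[[k]] <- data.frame(
          feature_id = fid, contig_id = paste0(gid, "_c1"),
          start = start, end = start + gene_len - 1L,
          strand = sample(c("+", "-"), 1L),
          protein_id = pid,
          product = if (role == "decoy") "hypothetical protein" else act,
          stringsAsFactors = FALSE)
        feats[[k]]$families <- list(fams)
        prots[[k]] <- data.frame(
          protein_id = pid, organism = organism, sequence = seqk,
          source_gene = fid, stringsAsFactors = FALSE)
        cursor <- start + gene_len - 1L + sample(50:500, 1L)
      }
      ft <- do.call(rbind, feats)
      contigs <- data.frame(contig_id = paste0(gid, "_c1"),
                            length = max(ft$end) + sample(50:500, 1L),
                            circular = FALSE, stringsAsFactors = FALSE)
      genomes[[g]] <- genome_record(gid, organism, contigs, ft)
      prot_rows[[g]] <- do.call(rbind, prots)

      if (type == "positive") {
        member_acts <- orf_acts[orf_roles == "member"]
        member_fids <- sprintf("%s_f%03d", gid,
                               which(orf_roles == "member"))
        at_f <- member_fids[member_acts == "aminotransferase"]
        dh_f <- member_fids[member_acts == "dehydrogenase"]
        ph_f <- member_fids[member_acts == "phosphatase"]
        clusters[[length(clusters) + 1L]] <- data.frame(
          genome_id = gid, organism = organism,
          at_feature = at_f, ph_feature = ph_f, dh_feature = dh_f,
          order_signature = gsub("-", "", orders[g]),
          phosphatase_class = ph_classes[g],
          stringsAsFactors = FALSE)
      }
    }

    ## decoy-protein motif plants (never inside a 3GC member)
    proteome_df <- do.call(rbind, prot_rows)
    if (config$motif_decoy_plants > 0L) {
      member_pids <- unlist(lapply(clusters, function(cl) {
        g <- genomes[[match(cl$genome_id, labels$genome_id)]]
        g$features$protein_id[g$features$feature_id %in%
                                c(cl$at_feature, cl$ph_feature,
                                  cl$dh_feature)]
      }))
      eligible <- which(!proteome_df$protein_id %in% member_pids &
                          nchar(proteome_df$sequence) >= 230L)
      sel <- sample(eligible, config$motif_decoy_plants)
      for (i in sel) {
        pos <- sample.int(nchar(proteome_df$sequence[i]) - 29L, 1L)
        substr(proteome_df$sequence[i], pos, pos + 29L) <-
          instantiate_motif(motif)
        plants[[length(plants) + 1L]] <- data.frame(
          protein_id = proteome_df$protein_id[i], position = pos,
          in_3gc = FALSE, stringsAsFactors = FALSE)
      }
    }
  })

  proteome <- protein_set(proteome_df$protein_id, proteome_df$sequence,
                          proteome_df$organism, proteome_df$source_gene)
  truth <- list(
    clusters = if (length(clusters)) do.call(rbind, clusters) else
      data.frame(genome_id = character(), organism = character(),
                 at_feature = character(), ph_feature = character(),
                 dh_feature = character(), order_signature = character(),
                 phosphatase_class = character(), stringsAsFactors = FALSE),
    motif_plants = if (length(plants)) do.call(rbind, plants) else
      data.frame(protein_id = character(), position = integer(),
                 in_3gc = logical(), stringsAsFactors = FALSE),
    genome_labels = labels
  )
  list(genomes = genomes, proteome = proteome, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' One GFF3 per genome, one combined proteome FASTA, and the ground truth
#' as JSON.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in dataset$genomes) {
    write_annotations(g, file.path(dir, paste0(g$genome_id, ".gff3")))
  }
  write_fasta(dataset$proteome, file.path(dir, "proteome.fasta"))
  jsonlite::write_json(dataset$truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Planted genus-like protein subfamilies
#'
#' Builds `n_families` subfamilies of mutated copies of a common synthetic
#' ancestor so that within-family pairwise identity is about
#' `within_identity` and cross-family pairwise identity about
#' `cross_identity`. Used to reproduce threshold-sweep clustering
#' behaviour: families co-cluster at permissive identity thresholds and
#' split at stringent ones.
#'
#' @param n_families number of subfamilies (each gets an invented genus).
#' @param members_per_family sequences per subfamily.
#' @param within_identity,cross_identity target pairwise identities.
#' @param length ancestor length.
#' @param rng_seed integer seed.
#' @return a [protein_set()]; organisms encode the family genus.
#' @export
make_protein_families <- function(n_families = 3, members_per_family = 8,
                                  within_identity = 0.8,
                                  cross_identity = 0.58,
                                  length = 400, rng_seed = 1L) {
  stopifnot(n_families >= 1, members_per_family >= 1,
            cross_identity < within_identity)
  ## member-to-family-seed divergence d: (1-d)^2 + d^2/19 = within
  solve_d <- function(target) {
    f <- function(d) (1 - d)^2 + d^2 / 19 - target
    stats::uniroot(f, c(0, 0.95))$root
  }
  d <- solve_d(within_identity)
  ## family-seed-to-ancestor divergence: (1-f)^2 ~ cross / within
  f_div <- 1 - sqrt(cross_identity / within_identity)
  with_seed(rng_seed, {
    ancestor <- random_protein(length)
    ids <- character(); seqs <- character(); orgs <- character()
    for (i in seq_len(n_families)) {
      fam_seed <- mutate_protein(ancestor, 1 - f_div,
                                 sample.int(2^30, 1L))
      genus <- paste0("Genus", LETTERS[i])
      for (j in seq_len(members_per_family)) {
        ids <- c(ids, sprintf("fam%d_m%02d", i, j))
        seqs <- c(seqs, mutate_protein(fam_seed, 1 - d,
                                       sample.int(2^30, 1L)))
        orgs <- c(orgs, sprintf("%s synthetica s%d%02d", genus, i, j))
      }
    }
  })
  protein_set(ids, seqs, orgs)
}
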