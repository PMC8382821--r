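---
title: "Mining genomes for azasugar three-gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for azasugar three-gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azamine)
```

## The discovery problem

Bacterial azasugar biosynthesis runs through three clustered enzyme
activities: an aminotransferase aminates a phospho-ketose, a phosphatase
unmasks a hydroxyl, and an aminopolyol dehydrogenase oxidises it; the
oxo-aminopolyol then cyclises spontaneously to the iminosugar. Because
the three genes sit next to each other in every characterised producer,
the *three-gene cluster* (3GC) is a genomic signature that can be mined
without any chemistry: find a gene with an aminotransferase family
annotation whose immediate neighborhood also codes a phosphatase and a
dehydrogenase.

`azamine` implements that search and the comparative analyses around it:
sequence similarity networks (SSNs) to organise candidate enzymes into
subfamilies, genome-neighborhood "colouring" to attach cluster content to
network nodes, a degenerate consensus motif as an orthogonal detector,
and gene-tree/taxonomy-tree comparison to look for horizontal transfer
of the cluster.

## Pairwise alignment and network statistics

The similarity kernel is Smith–Waterman local alignment with affine gaps
(Gotoh's algorithm), BLOSUM62, gap open 11, gap extend 1 — the standard
protein-BLAST parameterisation. A gap of length $k$ costs
$11 + 1 \cdot k$. Raw scores $S$ are converted to BLAST-like statistics
with gapped BLOSUM62 Karlin–Altschul constants
$\lambda = 0.267$, $K = 0.041$:

$$\mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2},\qquad
  E = m\,n\,2^{-\mathrm{bit}},\qquad
  \mathrm{alignment\ score} = \max(0, -\log_{10} E).$$

The last quantity is the scale on which SSN tools express edge
thresholds; we adopt it with that conventional definition. Percent
identity is identical residue pairs divided by alignment length
*including gap columns* (the BLAST convention). Composition-based score
adjustment and low-complexity masking are not implemented; identities
from this kernel are comparable to BLAST to within about a percentage
point, not bit-exact.

Two numerical conventions matter for reproducibility:

* **Deterministic traceback.** Ties in the dynamic program resolve
  diagonal > up > left, and the traced cell is the first score maximum
  in row-major order.
* **Canonical orientation.** Co-optimal local alignments are not unique,
  and the tie-break above is not transposition-invariant. Each pair is
  therefore aligned with the lexicographically smaller sequence first
  and the result re-oriented, so `smith_waterman(a, b)` and
  `smith_waterman(b, a)` return the same score, identity and alignment
  length by construction.

All-vs-all alignment keeps one hit per unordered pair with
$E \le 10^{-5}$, the conventional SSN edge-inclusion expect score.

## SSNs, thresholds, and clusters

An SSN keeps an edge when the chosen metric (percent identity by
default; alignment score for parity with SSN web tools) passes the
threshold. Proteins with no passing edge remain as isolated nodes.
Clusters are **connected components** — the semantics of thresholded
SSNs in the EFI-EST tradition; no density-based clustering is applied.
Components of size ≥ 2 are numbered by strictly decreasing size with
ties broken by the lexicographically smallest member id; single-node
components are reported separately as singletons, and
`threshold_sweep()` reports both counts so users can decide whether to
fold singletons into their cluster census. Cluster ordinals are a
per-dataset convention; they are not comparable across datasets.

A cluster is labelled with a genus when ≥ 75 % of its nodes share it
(the genus being the first whitespace token of the organism string);
otherwise the two most populous genera are joined with `/`, ties
resolved alphabetically.

## Neighborhoods and 3GC detection

The neighborhood of a gene is the `window` ORFs on each side (default
± 3) in start-coordinate rank order — ORF rank, not base-pair distance,
matching how neighborhood sizes are quoted in this field. Neighborhoods
are strand-agnostic (real clusters mix strands), truncate at linear
contig ends, wrap around circular contigs without duplicating features,
and never cross contig boundaries.

The activity schema maps each activity to a family set:
aminotransferase {PF00202}; dehydrogenase {PF00107, PF08240, PF16912};
phosphatase {PF13419, PF00459, PF12710, PF07081}. "At least one of each
activity" is interpreted set-wise: any family of the set counts. The
phosphatase families split into the two classes observed in producers —
inositol phosphatase (PF00459) versus HAD hydrolase (the rest) — and a
neighborhood containing both classes is reported as `"both"` with a
warning rather than silently resolved. A feature annotated with families
from two activities counts toward both; the default schema's disjoint
sets make this rare.

`find_3gc()` emits **one record per focal gene** (not per triple) to
avoid combinatorial duplicates; when several candidates exist for an
activity the nearest by |ORF offset| wins, ties to the lower start
coordinate. Family annotations are consumed from the input GFF3
(`Dbxref=Pfam:` or a `pfam=` attribute); the package deliberately ships
no family models — profile search is an upstream step for the user's
annotation pipeline. Detection therefore operates on annotations
directly and is independent of sequence divergence; the network-based
view of the original workflow is recovered by intersecting detection
output with SSN membership. Producer tallies deduplicate at the genome
level (a genome with two clusters counts once) and hide genera under 5
hits from the main table while keeping the full listing.

## The consensus motif

`progressive_msa()` builds a guide tree by neighbor joining on pairwise
p-distances and merges profiles progressively under the same
substitution matrix and gap penalties as the pairwise kernel. It is
substitution-oriented: for inputs that diverged without indels the
alignment is provably gap-free, which is the regime the consensus
derivation targets. Column-for-column parity with Clustal is not
promised.

`derive_consensus()` takes the per-column plurality residue with gaps
excluded: uppercase at ≥ 90 % conservation, lowercase at ≥ 50 %, `X`
below that or on a plurality tie or an all-gap column. The case encodes
display information only; scanning is case-insensitive. The thresholds
are this package's own choice — consensus tools emit mixed-case output
without a universally fixed parameterisation — and affect only the
letter case, never match semantics.

The packaged screening pattern is the 30-mer
`SGNXFRXXXFPNXXXXXXXLXVPXPYCXRC` with 16 constrained positions, so a
uniform-random residue matches a constrained position with probability
1/20 and an exact hit occurs per offset with probability $20^{-16}$
(≈ 1.5 × 10⁻²¹) — effectively zero over any realistic proteome, which
is what makes the motif usable as a detector. The scanner replaces the
original BLAST-against-NR step, which is not reproducible offline; its
`mismatch_budget` (default 0; 2 is a reasonable screening leniency) is
the tunable analog of a permissive E-value cutoff.
`screen_and_validate()` reports precision as in-3GC hit proteins over
mapped hit proteins, reports organism-level counts alongside
protein-level ones (a screen's hit count can be quoted either per
protein or per organism, so both are given), leaves precision
undefined — not zero — when there are no hits,
and excludes unmapped hits from the denominator with a warning.

## Phylogenetic comparison

"Without correction" distances are raw p-distances: mismatches over
columns where neither sequence is gapped; a pair with no comparable
columns is an error naming the pair. Neighbor joining is the Saitou–Nei
algorithm with a deterministic tie-break (the pair whose sorted label
pair is lexicographically smallest joins first), so runs are exactly
reproducible; additive matrices are recovered exactly. Negative branch
lengths — a known NJ artefact on non-additive inputs — are clamped to
zero and flagged via the tree's `"clamped"` attribute.
Robinson–Foulds counts bipartitions present in exactly one tree,
normalised by $2(n-3)$; taxonomy trees are consumed as user-supplied
Newick. Discordance is quantified, not explained: no explicit
horizontal-transfer events are inferred.

## The synthetic-data generator

`generate_dataset()` is the testing ground for every stage, and its
defaults encode the study conditions the pipeline targets:

* Positive genomes carry one planted 3GC whose members are mutated
  copies of four fixed synthetic length-400 seed enzymes (one per
  activity, one phosphatase seed per class). Real seed-enzyme sequences
  are not bundled; the seeds are committed, clearly labelled synthetic
  fixtures, and the aminotransferase seed carries one exact motif
  instantiation at positions 145–174.
* `mutate_protein()` substitutes exactly `round((1 − identity) · L)`
  positions without replacement — no indels — so realised ungapped
  identity matches the target within 1/L and identity ladders are exact.
* Both observed gene orders (`A-P-D`, `A-D-P`) and both phosphatase
  classes are planted by default, recycled across positive genomes.
  Members are consecutive by default (`window_spacing = 2`, the minimum
  that fits three genes; a value below 2 is rejected).
* Decoy genomes come in three kinds: *two-gene* (one activity omitted),
  *scattered* (all three activities present but separated by
  `window_spacing + 3` ORFs — 5 by default, safely outside the ± 3
  detection window), and *none*.
* Background ORFs get random lengths (200–450 aa), random family labels
  from a disjoint dummy space (`PF9xxxx`) so schema collisions cannot
  occur, intergenic gaps uniform on 50–500 bp, and random strands —
  the detector must be strand-agnostic because real neighborhoods mix
  strands.
* Motif instantiations (wildcards filled with random residues) can be
  planted into planted aminotransferases (`motif_plants`) and into
  non-cluster decoy proteins (`motif_decoy_plants`) to exercise the
  precision bookkeeping in both directions.

`make_protein_families()` plants genus-like subfamilies for the
threshold-sweep analysis: members of one family at ~80 % pairwise
identity, different families at ~58 %. Those defaults put within-family
edges above, and cross-family edges below, the stringent 70 % threshold
while both exceed the permissive 40 % one — so the three families merge
into one cluster at 40 % and split into exactly three at 70 %,
reproducing the qualitative subfamily-separation behaviour seen in real
aminotransferase SSNs. Note that local-alignment percent identity runs
a few points above the nominal substitution identity (the optimal local
alignment trims weakly matching ends), so nominal targets adjacent to a
threshold (e.g. 0.35 against a 40 % cutoff) can straddle it; tests and
demonstrations keep nominal identities clear of the thresholds they
exercise.

What the generator does *not* emulate: indels and domain rearrangements,
codon-level sequence (contigs are coordinate frames only, no nucleotide
sequence is simulated), compositional bias, annotation errors (families
are always correct), paralog interference, and assembly fragmentation.
Passing on synthetic data therefore demonstrates the pipeline's logic —
windows, thresholds, statistics, bookkeeping — not robustness to
annotation noise in real genomes, where detection quality is bounded by
the quality of the input family annotations.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; internal draws save
and restore the caller's RNG state. The test suite and
`scripts/acceptance.R` work at deliberately modest sizes — 500
brute-force alignment checks at length ≤ 30, 50–60 synthetic genomes,
24-protein SSNs, 10⁶ scanned motif offsets, 100 neighbor-joining trials
at ≤ 12 taxa — chosen so the full suite runs in a couple of minutes on
one core while still exercising every code path against an independent
oracle. `run_full()` writes a manifest (package version, parameters,
seed, input checksum) sufficient to reproduce any run, and its
plain-file stage handoffs (TSV, GraphML, FASTA, GFF3, Newick) keep each
stage individually testable and replaceable from R.

## Known limitations

* The alignment kernel is exact but quadratic: it is meant for candidate
  sets (tens to a few hundred proteins), not database-scale search.
* Identities and E-values approximate BLAST without composition-based
  statistics; published identity tables reproduce only to about a
  percentage point.
* The progressive MSA has no iterative refinement; with substantial
  indel divergence a dedicated aligner should be used and imported via
  `read_msa()`.
* Cluster ordinals and singleton counts depend on the input set;
  published counts from database snapshots are not recoverable.
* Co-occurrence is implemented as a reporting threshold on cluster
  family fractions, one of two plausible readings of the convention in
  neighborhood tools (the other gates edge drawing in the hub-node
  network, a visualisation this package does not produce).
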