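---
title: "Genome architecture of LRR-RLP gene families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome architecture of LRR-RLP gene families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlparch)
```

## The problem

Leucine-rich-repeat receptor-like proteins (LRR-RLPs) are plant cell-surface
receptors: an extracellular block of leucine-rich repeats, a single
transmembrane span, and a short cytoplasmic tail with no kinase domain.  In
several plant genomes these receptor genes sit in tandem-duplication
clusters, and the clusters are enriched in small genes encoding proteins of
unknown function (SPUFs), some of them secreted.  Because a secreted small
protein sitting next to a receptor gene is a natural candidate ligand for
that receptor, the genomic architecture itself — who sits next to whom, who
is co-expressed with whom, whose promoters share conserved elements — is
evidence worth quantifying.

`rlparch` implements that quantification as a reproducible pipeline:
receptor identification from protein sequence alone, distance-based cluster
and super-cluster calling, vicinity-gene association, SPUF classification
and neighbourhood enrichment, a C3-D domain phylogeny with a clade/locus
concordance score, wounded vs non-wounded expression comparison, and
promoter conserved-block detection.  A seeded synthetic-genome generator
plants every structure the pipeline is supposed to find, so each stage is
validated against known ground truth.

## Receptor annotation

A protein is called an LRR-RLP from its sequence alone, using the canonical
domain series A-G:

* **A — signal peptide.** A rule-based heuristic stands in for a full
  secretion predictor: the first 35 residues must contain at least one K/R
  at positions 2-6 and a hydrophobic window of ≥ 6 residues with mean
  Kyte-Doolittle hydropathy above 1.5; the cleavage site is placed after
  the first small residue (A/G/S/C) following that core, clamped to
  positions 15-35.  This is deliberately a heuristic: the pipeline only
  needs a binary secreted/anchored flag, and the rule is transparent and
  dependency-free.  Its thresholds are exposed as arguments.
* **C1/C2/C3 — LRR blocks and island.** Repeats are found by scanning a
  24-column position-weight matrix built from the extracytoplasmic plant
  LRR consensus `LxxLxxLxLxxNxLSGxIPxxLGx` against a background amino-acid
  composition.  A window scoring ≥ 10 bits (log2 odds) is accepted and the
  scan advances by one repeat length, so repeats never overlap.  The PWM is
  shipped as a plain TSV (`inst/extdata/lrr_pwm.tsv`) and can be replaced.
  A PWM scan was chosen over an HMM because it is deterministic,
  desk-scale, and fully inspectable.  The largest inter-repeat gap of at
  least 15 residues becomes the C2 island, splitting the repeats into C1
  and C3; with no such gap all repeats are C1.
* **F — transmembrane span.** The highest-scoring 19-residue
  Kyte-Doolittle window in the C-terminal 40% of the protein, reported if
  its mean is ≥ 1.6.  Repeats overlapping the TM window are discarded as
  hydrophobic-run artefacts.
* **Verdict.** A protein is an LRR-RLP iff it has more than 15 detected
  repeats (strictly more — a protein with exactly 15 fails), a signal
  peptide, a TM span, and a cytoplasmic tail shorter than 30 residues.
  The tail bound is what separates an RLP from a receptor-like kinase.
  B, C2 and E are annotated but not required: there is no per-domain test
  for them that is independent of the features already required.  Whether
  a boundary count of exactly 15 should pass is genuinely ambiguous; the
  strict reading was chosen and the bound is a parameter (`min_lrr`).

The E domain (acidic juxtamembrane stretch) defaults to length 0 and is
folded into D; `e_len` carves it out when a fixed-length convention is
wanted.

## Cluster and super-cluster calling

A cluster is at least two receptor genes chained on one chromosome with
consecutive boundary gaps (next start − previous end) of **at most 50 kb**;
a super-cluster is at least two clusters whose span gaps are **strictly
below 2 Mb**.  Two deliberate readings are embedded here:

* "Within a 50 kb stretch" is interpreted as a bound on consecutive gaps
  (single linkage), not a cap on total cluster span — observed clusters of
  up to seven members are impossible under a hard 50 kb span cap.
* The 50 kb bound is inclusive (a stretch includes its endpoint); the 2 Mb
  super-cluster bound is exclusive ("less than").

Chaining is computed against the running maximum end of the current chain,
which makes it exactly equivalent to the transitive closure of the pairwise
gap relation even when spans nest or overlap; the test suite verifies this
equivalence against an O(n²) union-find oracle on random layouts.

Association uses a 25 kb window: a gene is associated with a receptor iff
its span overlaps the receptor's span padded by 25 kb on both sides
(any-overlap of half-open intervals, measured from gene boundaries, not
midpoints).  Receptors are never counted as associated genes.  Per-receptor
windows can be overridden (some loci are inspected with a wider vicinity).
Both the deduplicated union count and the per-receptor mean ± SD are
reported: the two are not mutually derivable, because neighbouring
receptors share associated genes.

## SPUF classification and enrichment

A SPUF is a protein strictly shorter than 200 aa whose gene carries no
informative description (the whitelist `""`, `"unknown"`, `"hypothetical
protein"`, `"expressed protein"` is case-insensitive,
whitespace-normalised, and configurable — annotation pipelines differ in
how they spell "no annotation") and no domain-library hit.  Secretion is
the signal-peptide heuristic above.

Homology uses Smith-Waterman local alignment (BLOSUM62, affine gaps
11/1).  A pair is called homologous when the alignment score divided by the
shorter sequence length reaches 1.0; this length-normalised cut emulates a
database E-value threshold at desk scale without Karlin-Altschul
calibration, which is documented as an approximation.  Paralog families are
connected components of the resulting graph.  Searches against another
species' proteome use the same rule against a user-supplied FASTA, so no
network database is needed.

Enrichment reports three percentages — SPUFs among receptor-associated
genes, SPUFs among all non-receptor genes, and SPUFs in the gene content of
the largest cluster units with receptors excluded — plus a permutation
test that is an *addition* beyond the raw percentages: receptor anchors are
relabelled uniformly among all gene positions, the associated-SPUF
percentage is recomputed, and p = (1 + #{perm ≥ obs}) / (1 + n_perm).  Ties
counted in "≥" make the p-value conservative (super-uniform).  One caveat
is documented rather than hidden: exchangeability between the observed and
permuted statistics is exact only when the observed anchors are themselves
an unstructured draw over gene positions.  Real receptor anchors are
clustered, which changes the variance of the observed percentage relative
to scattered permuted anchors; the null-calibration test therefore
randomises both anchor and SPUF labels, and p-values on strongly clustered
anchors should be read as approximate.

## Phylogeny and clade/locus concordance

Only the conserved C3 and D domains are used for tree building — they play
the role of an already-curated alignment block, so no further column
filtering is applied.  Distances are 1 − identity/100 from global
alignments (identity = matches / alignment columns, end gaps excluded).
The tree is canonical Saitou-Nei neighbor joining with the Q-criterion,
ties broken by the smallest (i, j) index pair, and closed-form resolution
of the final three nodes; on additive matrices it reproduces the input
metric exactly (verified to 1e-9 on random additive instances, and
cross-checked for topology against an independent NJ implementation).
Negative branch lengths, possible on non-additive input, are clamped to
zero.  NJ was chosen over likelihood methods because it is deterministic
and dependency-free, which is sufficient for the clade-versus-locus
question; no support values are computed.

Concordance cuts the tree into k clades by removing the k − 1 longest
internal branches and reports the adjusted Rand index against a genomic
labelling (cluster id for clustered receptors, chromosome otherwise).  The
clade count is exposed as a parameter (default 4) rather than inferred: in
practice the right k emerges from the tree, not from theory.

One property of duplicated ("twin") chromosomes deserves a note.  The
generator can copy a whole cluster to a twin chromosome with per-gene
mutation at a target identity (e.g. 96%).  Each twin gene is then *closer*
to its own source paralog than cluster members are to each other, so tree
clades follow descent, not location: a clade cut can never separate the
twin cluster from its source, and the location-label ARI saturates around
0.6 by construction.  The concordance tests therefore assert a high
location ARI on the no-twin layout and a descent-label (founder-family)
ARI of ~1 in the twin scenario — which is the signal such a duplication
actually creates.

## Expression comparison

Each treatment mean is the equal-weight average over its condition columns
(six by default).  A gene is expressed if either mean exceeds the
background threshold; the threshold is not printed anywhere authoritative,
so it defaults to 200 intensity units, is configurable, and is echoed in
output.  Categories are a step function of the larger mean: ≤ 4,000
low/medium, ≤ 10,000 higher, above that very high.  Fold change is
(mean_wounded + pseudocount)/(mean_nonwounded + pseudocount) with
pseudocount 1.0 to stabilise ratios at low intensity; induction bands are
≥ 5 "strong" and [1.5, 5) "slight", chosen so that the qualitative labels
"slightly (<2-fold)" and "strongly (~10-fold) induced" are reproduced on
planted data, and both bands are configurable.  Treatments are paired by
column order and no between-array normalisation is performed.  The
co-expression screen emits every (receptor, SPUF) pair within a cluster
where both genes are above background, with a Pearson correlation across
the paired condition columns when at least four conditions exist.

## Promoter conserved blocks

Promoters are the 1 kb upstream of the translation start, strand-aware and
truncated with a warning at chromosome edges; offsets are reported relative
to the translation start (−1 is the base immediately upstream) because TSS
annotations are not assumed.  Block detection is a banded, alignment-free
scan: co-linear promoter elements do not need gapped alignment, so for each
diagonal shift within ±50 bp, 100-bp windows at 10-bp steps are compared
position-by-position.  Windows at or above 85% identity on the same shift
are merged, and each merged extent is refined to base resolution with a
maximal-scoring-segment pass whose match/mismatch weights put the boundary
criterion halfway between the identity threshold and the ~25% identity of
unrelated DNA — so block edges are set where the identity profile decays
toward background, not at whichever 10-bp grid line a window happened to
cross.  Refined blocks shorter than 200 bp are discarded and identity is
recomputed over the refined extent, so reported identity is never below
the threshold.  Defaults (85%, 200 bp) are deliberately permissive of a
~300 bp, ~90% target; all are flags.

## The synthetic genome

`make_genome()` plants, by default: three chromosomes (~9 Mb total), four
receptor clusters of 4/3/5/2 members at 10-20 kb intra-cluster gaps (the
two chromosome-1 clusters ~1.7 Mb apart, forming one super-cluster), one
singleton receptor, one SPUF per intra-cluster gap plus an annotated filler
gene in two gaps per cluster, ~45 scattered SPUFs and ~220 scattered
annotated filler genes (~300 genes total, SPUFs ~20% of non-receptor
genes), receptor proteins with 18-28 repeats at 15% per-position repeat
noise, cluster members derived from a per-cluster founder at 8% divergence
(tandem-duplication emulation, which doubles as the planted paralog
families), a designated "RISP-like" secreted SPUF with a 10-fold planted
wounding induction next to a highly expressed, slightly induced (1.8-fold)
receptor, and a 300-bp, 90%-identity conserved block between those two
genes' promoters at offsets −1000…−700.  Expression matrices are
log-normal (baseline median 500, so the 4,000/10,000 category bounds are
meaningful) with a shared per-condition factor for the designated
co-induced cluster; the factor multiplies both treatments of a condition
equally, which creates correlated profiles without biasing fold-change
estimates.  Every artifact draws from its own RNG stream forked from the
master seed, so adding genes does not perturb expression draws, and
identical seeds give byte-identical output.

What the generator does **not** emulate: codon-level gene structure and
introns, sequencing noise, probe-level microarray artefacts, non-uniform
intergenic composition, and selection pressure (mutations fall uniformly,
so a duplicated receptor can lose its signal peptide — under the default
noise roughly one receptor in twenty is missed for exactly that reason,
while the noiseless limit is recovered exactly).  Passing tests on this
generator therefore demonstrate correctness of the *computations*, not
performance on real annotation pipelines, whose "no annotation" spellings,
gene-model errors and probe effects are additional failure modes.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: ~300-gene genomes,
50 random layouts for the cluster oracle, 30 for the association oracle,
100 additive matrices (n = 6-10) for NJ, 100 seeds for fold-change
recovery, 50 planted plus 100 null promoter pairs, and 200 null runs at
200 permutations each for p-value calibration.  Ties in NJ's Q-criterion
are broken deterministically; permutation p-values are reported with the
add-one correction; fold changes use pseudocounts; degenerate inputs
(empty cluster lists, zero receptors, promoters shorter than the scan
window, genes at chromosome edges) return empty results or warnings rather
than errors wherever a downstream stage can continue.

## Known limitations

* The signal-peptide and TM heuristics are hydropathy rules, not trained
  predictors; they are calibrated to the generator's constructs and to
  obvious negatives, and will disagree with modern predictors on real
  borderline sequences.
* The length-normalised Smith-Waterman cut is not an E-value; family
  membership near the threshold will differ from database searches.
* The permutation test treats gene positions as exchangeable units and
  ignores gene length and local gene density beyond what the association
  window captures.
* Clade cutting by longest internal branches is a heuristic; for trees
  whose deepest splits are not the family boundaries, k must be chosen by
  inspection.
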