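# rlparch — genome architecture of LRR-RLP gene families

Plant genomes carry large families of **leucine-rich-repeat receptor-like
proteins (LRR-RLPs)**: cell-surface receptors with an extracellular LRR
block, a transmembrane span and a short cytoplasmic tail, but no kinase.
Their genes often sit in tandem-duplication clusters, interspersed with
genes for **small proteins of unknown function (SPUFs)** — short (< 200 aa),
unannotated, often secreted.  A secreted SPUF sitting next to a receptor
gene, co-expressed with it and sharing promoter elements, is a natural
candidate **endogenous peptide ligand** for that receptor.

`rlparch` turns this genome-architecture argument into a tested pipeline
for anyone analysing a receptor family in an annotated genome:

1. **Receptor annotation** — calls LRR-RLPs from protein sequence alone:
   signal peptide (hydropathy heuristic), LRR repeats (24-column PWM scan
   of the plant consensus `LxxLxxLxLxxNxLSGxIPxxLGx`), transmembrane span
   (Kyte–Doolittle), segmentation into the canonical domains A–G.  The
   verdict requires **> 15 repeats** (strict), domains A and F, and a tail
   **< 30 aa**.
2. **Cluster architecture** — clusters are ≥ 2 receptor genes chained at
   consecutive gaps **≤ 50 kb**; super-clusters are ≥ 2 clusters separated
   by **< 2 Mb**; associated genes are everything overlapping a **25 kb**
   window around a receptor.
3. **SPUF analysis** — classification (< 200 aa, no annotation, no domain
   hit), secretion flags, Smith–Waterman paralog families (BLOSUM62, gaps
   11/1, length-normalised score ≥ 1), and neighbourhood enrichment with a
   permutation p-value, `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`.
4. **Phylogeny/locus concordance** — neighbor-joining tree from the
   conserved C3+D domain sequences (distance `1 − identity/100`), cut into
   k clades, scored by adjusted Rand index against genomic location.
5. **Expression under wounding** — per-treatment means over six
   conditions, categories at 4,000/10,000 intensity, fold change
   `FC = (mean_W + 1)/(mean_NW + 1)`, induction bands at 1.5 (slight) and
   5 (strong), plus a receptor/SPUF co-expression screen within clusters.
6. **Promoter conservation** — banded windowed-identity scan of promoter
   pairs with base-level boundary refinement (defaults: 100 bp windows,
   ≥ 85% identity, blocks ≥ 200 bp, offsets relative to the translation
   start).
7. **Synthetic genomes** — `make_genome()` / `make_expression()` plant all
   of the above structures with known ground truth behind a single seed,
   so every stage is validated end to end.

## Worked example

```r
library(rlparch)

gb  <- make_genome(seed = 7)                     # genome + planted truth
ex  <- make_expression(gb$truth, noise_sd = 0.2, seed = 7)
rep <- run_all(gb$genome, expr = ex, config = list(n_perm = 500, seed = 7))
```

The synthetic genome has 297 genes on 3 chromosomes; the pipeline prints /
returns, among other things:

```
receptors: 15 (14 clustered in 4 clusters, 93% of family)
associated genes: 24 (3.47 +/- 1.4 per receptor)
SPUF enrichment: 45.8% of associated genes vs 19.5% genome-wide (p = 0.003992, 500 permutations)
clade/locus concordance ARI: 0.91
RISP-like SPUF: FC = 9.3 (strong)
    gene_a    gene_b offset_a offset_b length identity
1 RLP_c4_1 SPUF_c4_1    -1000    -1000    300       90
```

Reading this: 14 of the 15 planted receptors were recovered under the
default sequence noise (one lost its signal peptide to simulated
divergence — the noiseless limit recovers all 15) and chained into the 4
planted clusters; SPUFs make up 45.8% of the genes in receptor
neighbourhoods against 19.5% genome-wide, and no random relabelling of the
receptor anchors among 500 reached the observed percentage; tree clades
match genomic clusters (ARI 0.91); the planted 10-fold wounding induction
of the RISP-like SPUF is estimated at 9.3-fold and called *strong*; and the
300-bp, 90%-identity block planted between the promoters of that SPUF and
its neighbouring receptor is recovered exactly, at offsets −1000…−700 from
both translation starts.

`run_all(..., outdir = "out/")` additionally writes TSV/BED/Newick/JSON
artifacts per stage, and `make_table1()` renders a two-genome comparison
table with percentages to one decimal place.

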