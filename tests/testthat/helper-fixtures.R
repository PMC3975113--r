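# Shared fixture builders and brute-force oracles.  All fixtures are
# generated in code; nothing is read from disk except files the tests
# write themselves.

# A bare gene table (no sequences) for interval-logic tests.
toy_genes <- function(ids, chrom, start, end, strand = "+") {
  data.frame(gene_id = ids, chrom = chrom, strand = strand,
             start = start, end = end, description = "",
             stringsAsFactors = FALSE)
}

toy_genome <- function(genes, chrom_len = NULL, proteins = NULL, genomic_seq = NULL) {
  if (is.null(chrom_len)) {
    chrom_len <- tapply(genes$end, genes$chrom, max) + 1000
    chrom_len <- stats::setNames(as.numeric(chrom_len), names(chrom_len))
  }
  new_genome(chrom_len, genes, proteins = proteins, genomic_seq = genomic_seq)
}

# Random receptor layout on a few chromosomes (may produce touching or
# overlapping spans; the oracles must agree anyway).
random_layout <- function(n_genes = 20, n_chrom = 2, chrom_len = 1e6,
                          gene_len_range = c(500, 5000)) {
  chrom <- sample(sprintf("chr%02d", seq_len(n_chrom)), n_genes, replace = TRUE)
  start <- vapply(chrom, function(cc) sample.int(chrom_len - gene_len_range[2] - 1, 1), 0L)
  len <- sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE)
  toy_genes(sprintf("g%03d", seq_len(n_genes)), chrom, start, start + len)
}

# O(n^2) transitive-closure oracle for cluster calling: edge iff same
# chromosome and boundary gap <= gap_max; clusters = components of size
# >= 2, as sets of gene ids.
brute_cluster_membership <- function(genes, gap_max) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (genes$chrom[i] != genes$chrom[j]) next
    gap <- max(genes$start[i], genes$start[j]) - min(genes$end[i], genes$end[j])
    if (gap <= gap_max) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(genes$gene_id, comp)
}

# sorted list of sorted member vectors, size >= 2 only
canon_members <- function(member_sets) {
  keep <- Filter(function(m) length(m) >= 2, unname(member_sets))
  keep <- lapply(keep, function(m) sort(unname(m)))
  keep[order(vapply(keep, `[`, "", 1))]
}

# All-pairs brute-force association oracle: gene associated iff its span
# overlaps any receptor's span padded by `window` (half-open intervals).
brute_associated <- function(genes, receptor_ids, window) {
  rec <- genes[genes$gene_id %in% receptor_ids, , drop = FALSE]
  oth <- genes[!genes$gene_id %in% receptor_ids, , drop = FALSE]
  hits <- character(0)
  for (i in seq_len(nrow(oth))) for (j in seq_len(nrow(rec))) {
    if (oth$chrom[i] != rec$chrom[j]) next
    if (oth$start[i] < rec$end[j] + window && oth$end[i] > rec$start[j] - window)
      hits <- c(hits, oth$gene_id[i])
  }
  sort(unique(hits))
}

# Random background protein of a given length.
random_protein <- function(len) {
  bg <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
          Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
          L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
          S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0653)
  paste(sample(names(bg), len, replace = TRUE, prob = bg / sum(bg)), collapse = "")
}

random_dna_str <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# Plant a conserved block (exact mismatch count) into two random promoters.
planted_promoter_pair <- function(prom_len = 1000, block_len = 300,
                                  identity = 90, at = 1) {
  pa <- random_dna_str(prom_len)
  pb <- random_dna_str(prom_len)
  block <- substr(pa, at, at + block_len - 1)
  v <- strsplit(block, "")[[1]]
  k <- round(block_len * (1 - identity / 100))
  idx <- sample.int(block_len, k)
  for (i in idx) {
    repl <- sample(c("A", "C", "G", "T"), 1)
    while (repl == v[i]) repl <- sample(c("A", "C", "G", "T"), 1)
    v[i] <- repl
  }
  substr(pb, at, at + block_len - 1) <- paste(v, collapse = "")
  list(a = pa, b = pb)
}

# Small, fast generator configuration (no chromosome sequence).
small_params <- function(...) {
  utils::modifyList(
    list(n_filler = 40, n_spuf_outside = 12, with_sequence = FALSE),
    list(...)
  )
}

# Minimal truth-like object for expression-only tests.
expression_truth <- function(n_genes = 60, inductions = c(gene_01 = 10),
                             baselines = NULL, coinduced = character(0)) {
  ids <- sprintf("gene_%02d", seq_len(n_genes))
  list(gene_ids = ids, inductions = inductions,
       baselines = baselines, coinduced = coinduced)
}
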