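# SPUF (small protein of unknown function) classification, secretion
# prediction, paralog family grouping and neighbourhood enrichment.
#
# A SPUF is a protein strictly shorter than 200 aa whose gene has no
# informative description and no domain-library hit.  Homology search is
# local Smith-Waterman (BLOSUM62, affine gaps 11/1) with a
# length-normalised score cut standing in for a database E-value
# threshold; the exact Karlin-Altschul calibration is deliberately out of
# scope.

SPUF_DESC_WHITELIST <- c("", "unknown", "hypothetical protein", "expressed protein")

#' Classify a gene as SPUF
#'
#' @param protein_length protein length in aa (`NA` for non-coding genes).
#' @param description functional description (`""` if none).
#' @param domain_hits character vector of domain-library hits.
#' @param len_max length bound in aa (strict `<`).
#' @param whitelist descriptions treated as "no annotation"
#'   (case-insensitive, whitespace-normalised).
#' @return Logical verdict.
#' @export
classify_spuf <- function(protein_length, description, domain_hits,
                          len_max = 200, whitelist = SPUF_DESC_WHITELIST) {
  !is.na(protein_length) && protein_length < len_max &&
    norm_desc(description) %in% norm_desc(whitelist) &&
    length(domain_hits) == 0
}

#' SPUF flags for a whole genome
#'
#' @param genome a `Genome`.
#' @param receptor_ids receptors are never SPUFs regardless of length.
#' @param ... passed to [classify_spuf()].
#' @return Named logical vector over all genes.
#' @export
spuf_flags <- function(genome, receptor_ids = character(0), ...) {
  g <- genome$genes
  fl <- vapply(seq_len(nrow(g)), function(i)
    classify_spuf(g$protein_length[i], g$description[i], g$domain_hits[[i]], ...),
    TRUE)
  fl[g$gene_id %in% receptor_ids] <- FALSE
  stats::setNames(fl, g$gene_id)
}

#' Predict secretion from the protein sequence
#'
#' Delegates to the signal-peptide heuristic of the receptor annotator:
#' a protein is predicted secreted iff a cleavable N-terminal signal
#' peptide is detected.
#'
#' @param seq amino-acid string.
#' @return Logical.
#' @export
predict_secreted <- function(seq) {
  !is.null(detect_signal_peptide(seq))
}

# Smith-Waterman score of query against a set of subjects.
sw_scores <- function(query, subjects) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects),
    Biostrings::AAString(query),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE
  )
  as.numeric(pa)
}

#' Find paralog families among query proteins
#'
#' Every pair of query proteins is aligned locally (Smith-Waterman,
#' BLOSUM62, affine gaps 11/1); a pair is paralogous iff the alignment
#' score divided by the shorter sequence length reaches `score_min`.
#' Families are the connected components of the paralogy graph.
#'
#' @param proteome named character vector of amino-acid sequences.
#' @param query_ids ids to analyse (must exist in `proteome`).
#' @param score_min length-normalised score threshold.
#' @return List: `n_paralogs` (named integer, direct paralog partners per
#'   query), `families` (list of id vectors, components of size >= 2),
#'   `family_id` (named vector, `NA` for singletons).
#' @export
find_paralogs <- function(proteome, query_ids = names(proteome), score_min = 1.0) {
  if (length(proteome) == 0) stopf("empty proteome")
  missing <- setdiff(query_ids, names(proteome))
  if (length(missing)) stopf("query id not in proteome: %s", missing[1])
  n <- length(query_ids)
  adj <- matrix(FALSE, n, n, dimnames = list(query_ids, query_ids))
  lens <- nchar(proteome[query_ids])
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    sc <- sw_scores(proteome[[query_ids[i]]], proteome[query_ids[js]])
    norm <- sc / pmin(lens[i], lens[js])
    adj[i, js] <- adj[js, i] <- norm >= score_min
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(gr)
  fam_id <- stats::setNames(comp$membership, query_ids)
  fam_sizes <- table(fam_id)
  fams <- lapply(names(fam_sizes)[fam_sizes >= 2], function(fid)
    query_ids[fam_id == as.integer(fid)])
  fam_out <- stats::setNames(rep(NA_character_, n), query_ids)
  for (k in seq_along(fams)) fam_out[fams[[k]]] <- sprintf("F%d", k)
  list(
    n_paralogs = stats::setNames(as.integer(rowSums(adj)), query_ids),
    families = fams,
    family_id = fam_out
  )
}

#' Count homologs of query proteins in another proteome
#'
#' Same score rule as [find_paralogs()], applied against an independent
#' (e.g. other-species) proteome.
#'
#' @param proteome_other named character vector of subject sequences.
#' @param queries named character vector of query sequences.
#' @param score_min length-normalised score threshold.
#' @return Named integer vector of homolog counts per query.
#' @export
count_homologs <- function(proteome_other, queries, score_min = 1.0) {
  if (length(proteome_other) == 0) stopf("empty proteome")
  vapply(names(queries), function(q) {
    sc <- sw_scores(queries[[q]], proteome_other)
    norm <- sc / pmin(nchar(queries[[q]]), nchar(proteome_other))
    sum(norm >= score_min)
  }, 0L)
}

#' Percent identity of a global pairwise alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps 11/1);
#' identity = matches / alignment columns, end gaps excluded, times 100.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  a <- aa_vec(as.character(Biostrings::alignedPattern(pa)))
  b <- aa_vec(as.character(Biostrings::alignedSubject(pa)))
  gap_a <- a == "-"; gap_b <- b == "-"
  if (all(gap_a | gap_b)) return(0)
  # trim end-gap columns: drop the leading/trailing run of columns where
  # either sequence has not started / has already ended
  first <- which(cumsum(!gap_a) > 0 & cumsum(!gap_b) > 0)[1]
  last <- length(a) + 1 - which(cumsum(rev(!gap_a)) > 0 & cumsum(rev(!gap_b)) > 0)[1]
  if (is.na(first) || is.na(last) || first > last) return(0)
  cols <- first:last
  100 * sum(a[cols] == b[cols] & a[cols] != "-") / length(cols)
}

#' Build SPUF records for a genome
#'
#' @param genome a `Genome` (proteins required for secretion and
#'   paralogy).
#' @param receptor_ids receptor gene ids.
#' @param proteome_other optional named character vector of other-species
#'   proteins for homolog counts.
#' @param score_min length-normalised homology score threshold.
#' @param ... passed to [classify_spuf()] via [spuf_flags()].
#' @return data.frame: `gene_id`, `protein_length`, `is_spuf`, `secreted`,
#'   `n_paralogs`, `n_homologs_other`, `family_id`.
#' @export
spuf_records <- function(genome, receptor_ids = character(0),
                         proteome_other = NULL, score_min = 1.0, ...) {
  fl <- spuf_flags(genome, receptor_ids, ...)
  ids <- names(fl)[fl]
  sec <- vapply(ids, function(id) {
    s <- genome$proteins[[id]]
    !is.null(s) && predict_secreted(s)
  }, TRUE)
  par <- if (length(ids) >= 2)
    find_paralogs(genome$proteins, ids, score_min = score_min)
  else list(n_paralogs = stats::setNames(integer(length(ids)), ids),
            family_id = stats::setNames(rep(NA_character_, length(ids)), ids))
  hom <- if (!is.null(proteome_other) && length(ids))
    count_homologs(proteome_other, genome$proteins[ids], score_min)
  else stats::setNames(rep(NA_integer_, length(ids)), ids)
  g <- genome$genes
  data.frame(
    gene_id = ids,
    protein_length = g$protein_length[match(ids, g$gene_id)],
    is_spuf = TRUE,
    secreted = unname(sec),
    n_paralogs = unname(par$n_paralogs[ids]),
    n_homologs_other = unname(hom[ids]),
    family_id = unname(par$family_id[ids]),
    row.names = NULL
  )
}

# Fast associated-gene set: ids of non-anchor genes overlapping any
# anchor's padded window.  Used by the permutation loop.
associated_union_fast <- function(chrom, start, end, anchor_idx, window) {
  hit <- rep(FALSE, length(start))
  for (i in anchor_idx) {
    hit <- hit | (chrom == chrom[i] & start < end[i] + window & end > start[i] - window)
  }
  hit[anchor_idx] <- FALSE
  hit
}

#' SPUF enrichment in receptor neighbourhoods
#'
#' Computes the percentage of SPUFs among receptor-associated genes, the
#' genome-wide SPUF percentage among non-receptor genes, and the SPUF
#' percentage of the gene content of the `top_k` largest cluster units
#' (receptors excluded).  A permutation test — an addition beyond the raw
#' percentages, flagged as such in the report — relabels the receptor
#' anchors uniformly among all gene positions and recomputes the
#' associated-SPUF percentage; p = (1 + #\{perm >= obs\}) / (1 + n_perm).
#'
#' @param genome a `Genome`.
#' @param receptor_ids receptor gene ids.
#' @param spufs named logical vector from [spuf_flags()].
#' @param clusters clusters from [call_clusters()] (for the top-unit
#'   percentage); may be `NULL`.
#' @param window association window (bp).
#' @param top_k number of largest clusters used for the cluster-content
#'   percentage.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return List of class `EnrichmentReport`: `pct_spuf_associated`,
#'   `pct_spuf_genome`, `pct_spuf_top_clusters_excl_receptors`, `p_value`,
#'   `n_perm`, `seed`, `n_associated`, `note`.
#' @export
enrichment <- function(genome, receptor_ids, spufs, clusters = NULL,
                       window = 25000, top_k = 9, n_perm = 1000, seed = 1) {
  g <- genome$genes
  is_rec <- g$gene_id %in% receptor_ids
  spuf_v <- unname(spufs[g$gene_id])
  pct_of <- function(hit) {
    n <- sum(hit)
    if (n == 0) { warnf("no associated genes"); return(0) }
    100 * sum(hit & spuf_v) / n
  }
  obs_hit <- associated_union_fast(g$chrom, g$start, g$end, which(is_rec), window)
  pct_assoc <- pct_of(obs_hit)
  pct_genome <- if (sum(!is_rec) > 0) 100 * sum(spuf_v & !is_rec) / sum(!is_rec) else 0
  pct_top <- NA_real_
  if (!is.null(clusters) && length(clusters)) {
    sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
    top <- clusters[order(sizes, decreasing = TRUE)][seq_len(min(top_k, length(clusters)))]
    top_members <- unlist(lapply(top, `[[`, "members"))
    hit_top <- associated_union_fast(g$chrom, g$start, g$end,
                                     which(g$gene_id %in% top_members), window)
    hit_top[is_rec] <- FALSE   # content counted without the receptors
    pct_top <- pct_of(hit_top)
  }
  n_anchor <- sum(is_rec)
  perm_pct <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    anchors <- sample.int(nrow(g), n_anchor)
    pct_of(associated_union_fast(g$chrom, g$start, g$end, anchors, window))
  }, 0))
  p <- (1 + sum(perm_pct >= pct_assoc)) / (1 + n_perm)
  structure(list(
    pct_spuf_associated = pct_assoc,
    pct_spuf_genome = pct_genome,
    pct_spuf_top_clusters_excl_receptors = pct_top,
    p_value = p,
    n_perm = n_perm,
    seed = seed,
    n_associated = sum(obs_hit),
    note = "permutation test is an addition beyond the descriptive percentages"
  ), class = "EnrichmentReport")
}

#' @export
print.EnrichmentReport <- function(x, ...) {
  cat(sprintf(
    "SPUF enrichment: %.1f%% of associated genes vs %.1f%% genome-wide (p = %.4g, %d permutations)\n",
    x$pct_spuf_associated, x$pct_spuf_genome, x$p_value, x$n_perm))
  invisible(x)
}

#' Tag truncated-LRR genes among a gene set
#'
#' Genes whose proteins carry 1-15 LRR repeats but are not called
#' receptors are reported as a separate "truncated LRR" class.
#'
#' @param genome a `Genome` with proteins.
#' @param gene_ids ids to scan.
#' @param receptor_ids ids already called as receptors (excluded).
#' @param profile,score_min see [scan_lrr_repeats()].
#' @return Character vector of truncated-LRR gene ids.
#' @export
tag_truncated_lrr <- function(genome, gene_ids, receptor_ids = character(0),
                              profile = default_lrr_profile(), score_min = 10) {
  ids <- setdiff(gene_ids, receptor_ids)
  keep <- vapply(ids, function(id) {
    s <- genome$proteins[[id]]
    if (is.null(s)) return(FALSE)
    nr <- length(scan_lrr_repeats(s, profile, score_min))
    nr >= 1 && nr <= 15
  }, TRUE)
  ids[keep]
}
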