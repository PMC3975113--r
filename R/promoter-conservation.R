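# Promoter extraction and conserved-block detection between promoter
# pairs.  Blocks are searched by a banded, alignment-free windowed
# identity scan: promoter elements shared between co-expressed genes are
# expected to be co-linear, so a small offset band replaces full local
# alignment.  Offsets are reported relative to the translation start
# (no TSS annotation is assumed): position -1 is the base immediately
# upstream of the start codon.

#' Extract the promoter sequence of a gene
#'
#' Strand-aware: for a + strand gene the `length` bases ending at the gene
#' start; for a - strand gene the reverse complement of the `length` bases
#' following the gene end.  Truncated with a warning at the chromosome
#' edge.
#'
#' @param genome a `Genome` with `genomic_seq`.
#' @param gene_id gene identifier.
#' @param length promoter length in bp.
#' @return Nucleotide string (possibly shorter than `length`).
#' @export
extract_promoter <- function(genome, gene_id, length = 1000) {
  if (is.null(genome$genomic_seq)) stopf("genome carries no nucleotide sequence")
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stopf("unknown gene: %s", gene_id)
  chrom_seq <- genome$genomic_seq[[g$chrom]]
  clen <- Biostrings::nchar(chrom_seq)
  if (g$strand == "+") {
    from0 <- g$start - length
    if (from0 < 0) {
      warnf("promoter of %s truncated at chromosome start", gene_id)
      from0 <- 0
    }
    if (g$start == 0) return("")
    as.character(Biostrings::subseq(chrom_seq, from0 + 1, g$start))
  } else {
    to0 <- g$end + length
    if (to0 > clen) {
      warnf("promoter of %s truncated at chromosome end", gene_id)
      to0 <- clen
    }
    if (to0 == g$end) return("")
    s <- Biostrings::subseq(chrom_seq, g$end + 1, to0)
    as.character(Biostrings::reverseComplement(s))
  }
}

# Maximal-scoring segment of the match profile between va[lo..hi] and
# vb[(lo+s)..(hi+s)].  The boundary criterion sits halfway between
# min_identity and the 25% identity expected of unrelated DNA: scoring a
# match +(100 - cut) and a mismatch -cut makes a segment positive iff its
# identity exceeds cut, so edges are trimmed where the profile decays
# toward background rather than at every local dip below min_identity.
# Returns c(start, end) in a-coordinates or NULL.
max_identity_segment <- function(va, vb, s, lo, hi, min_identity) {
  if (hi < lo) return(NULL)
  cut <- (min_identity + 25) / 2
  m <- va[lo:hi] == vb[(lo + s):(hi + s)]
  x <- ifelse(m, 100 - cut, -cut)
  cs <- cumsum(x)
  prev_min <- cummin(c(0, cs[-length(cs)]))
  gain <- cs - prev_min
  j <- which.max(gain)
  if (gain[j] <= 0) return(NULL)
  # segment start: position after the prefix minimum preceding j
  i <- which(c(0, cs)[seq_len(j)] == prev_min[j])[1]
  c(lo + i - 1, lo + j - 1)
}

#' Scan two promoters for shared conserved blocks
#'
#' For each diagonal shift within `band` bp, windows of `window` bp (step
#' `step`) are compared position-by-position; windows at or above
#' `min_identity` percent identity on the same shift are merged when they
#' overlap, each merged extent is refined to base resolution by a
#' maximal-scoring-segment pass (so block boundaries do not depend on the
#' window grid), blocks shorter than `min_block` are discarded, and the
#' identity of each surviving block is recomputed over its refined extent.
#' Overlapping blocks from different shifts are resolved greedily by
#' length x identity.
#'
#' @param prom_a,prom_b promoter nucleotide strings (position 1 =
#'   `-length(promoter)` relative to the translation start).
#' @param window window width (bp).
#' @param step window start step (bp).
#' @param min_identity minimum window/block percent identity.
#' @param min_block minimum merged block length (bp).
#' @param band maximum |offsetA - offsetB| considered (bp).
#' @return data.frame of class `ConservedBlocks`: `offset_a`, `offset_b`
#'   (bp relative to the translation starts, negative), `length`,
#'   `identity`.  Empty (with a warning) when a promoter is shorter than
#'   `window`.
#' @export
scan_conserved_blocks <- function(prom_a, prom_b, window = 100, step = 10,
                                  min_identity = 85, min_block = 200, band = 50) {
  empty <- data.frame(offset_a = numeric(0), offset_b = numeric(0),
                      length = numeric(0), identity = numeric(0))
  la <- nchar(prom_a); lb <- nchar(prom_b)
  if (la < window || lb < window) {
    warnf("promoter shorter than scan window (%d bp)", window)
    return(empty)
  }
  va <- aa_vec(prom_a); vb <- aa_vec(prom_b)
  blocks <- list()
  for (s in seq(-band, band, by = step)) {
    # compare va[i .. ] with vb[i + s .. ]
    i_min <- max(1, 1 - s)
    i_max <- min(la, lb - s)
    if (i_max - i_min + 1 < window) next
    starts <- seq(i_min, i_max - window + 1, by = step)
    ident <- vapply(starts, function(i)
      100 * sum(va[i:(i + window - 1)] == vb[(i + s):(i + s + window - 1)]) / window,
      0)
    ok <- ident >= min_identity
    if (!any(ok)) next
    # merge overlapping qualifying windows (same shift), then refine each
    # merged extent to base resolution with a maximal-scoring-segment pass
    # (match/mismatch weights chosen so a segment scores positive iff its
    # identity exceeds min_identity)
    runs <- split(starts[ok], cumsum(c(1, diff(starts[ok]) > window)))
    for (rn in runs) {
      lo <- max(i_min, min(rn) - window)
      hi <- min(i_max, max(rn) + 2 * window - 1)
      seg <- max_identity_segment(va, vb, s, lo, hi, min_identity)
      if (is.null(seg)) next
      len <- seg[2] - seg[1] + 1
      if (len < min_block) next
      id <- 100 * sum(va[seg[1]:seg[2]] == vb[(seg[1] + s):(seg[2] + s)]) / len
      if (id < min_identity) next
      blocks[[length(blocks) + 1]] <- data.frame(
        offset_a = seg[1] - 1 - la, offset_b = seg[1] + s - 1 - lb,
        length = len, identity = id
      )
    }
  }
  if (!length(blocks)) return(structure(empty, class = c("ConservedBlocks", "data.frame")))
  df <- do.call(rbind, blocks)
  # greedy non-overlap selection by length x identity
  df <- df[order(-(df$length * df$identity)), , drop = FALSE]
  kept <- df[0, ]
  for (r in seq_len(nrow(df))) {
    cand <- df[r, ]
    a0 <- cand$offset_a; a1 <- a0 + cand$length
    clash <- any(kept$offset_a < a1 & (kept$offset_a + kept$length) > a0)
    if (!clash) kept <- rbind(kept, cand)
  }
  kept <- kept[order(kept$offset_a), , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, class = c("ConservedBlocks", "data.frame"))
}
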