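# Domain-architecture annotation of candidate LRR-RLP proteins.
#
# An LRR-RLP is called from the protein sequence alone: a cleavable
# N-terminal signal peptide (domain A), a block of extracytoplasmic LRRs
# (C1), optionally interrupted by a non-LRR island (C2) separating it from
# a C-terminal LRR block (C3), an acidic linker (D), a single transmembrane
# span (F) and a short cytoplasmic tail (G) with no kinase.  The verdict
# requires more than `min_lrr` repeats (strict), A and F present and a tail
# shorter than `tail_max`.

# 24-residue extracytoplasmic plant LRR consensus; lower-case x = any
# residue (background).
LRR_CONSENSUS <- "LxxLxxLxLxxNxLSGxIPxxLGx"

#' Default LRR position-weight matrix
#'
#' 20 x 24 probability matrix over amino acids, one column per consensus
#' position.  Consensus positions put mass 0.7 on the consensus residue and
#' spread the rest proportionally to background; wildcard positions are the
#' background.  Shipped as a TSV under `extdata` so it can be swapped.
#'
#' @return Numeric matrix, rows = amino acids, columns = repeat positions.
#' @export
default_lrr_profile <- function() {
  path <- system.file("extdata", "lrr_pwm.tsv", package = "rlparch")
  if (nzchar(path)) return(read_lrr_profile(path))
  build_lrr_profile()
}

# Construct the default PWM from the consensus (used to generate the
# shipped TSV and as fallback when the package is loaded uninstalled).
build_lrr_profile <- function(consensus = LRR_CONSENSUS, match_prob = 0.7) {
  pos <- aa_vec(consensus)
  m <- vapply(pos, function(p) {
    if (p == "x") return(AA_BACKGROUND[AA20])
    pr <- AA_BACKGROUND[AA20] * (1 - match_prob) / (1 - AA_BACKGROUND[[p]])
    pr[p] <- match_prob
    pr / sum(pr)
  }, numeric(20))
  rownames(m) <- AA20
  colnames(m) <- seq_len(ncol(m))
  m
}

#' Read an LRR position-weight matrix from TSV
#'
#' @param path TSV with amino acids in the first column, one column per
#'   repeat position.
#' @return Numeric probability matrix (rows = amino acids).
#' @export
read_lrr_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(AA20 %in% rownames(m))) stopf("LRR profile lacks rows for all 20 amino acids")
  m[AA20, , drop = FALSE]
}

#' Scan a protein for tandem LRR repeats
#'
#' Greedy left-to-right scan: at each position the next `ncol(profile)`
#' residues are scored by log2 odds against the background; a window at or
#' above `score_min` is accepted as a repeat and the scan advances by the
#' repeat length (repeats never overlap), otherwise by one.
#'
#' @param seq amino-acid string.
#' @param profile position probability matrix (see [default_lrr_profile()]).
#' @param score_min minimum log2-odds score (bits) to accept a repeat.
#' @return List of 0-based half-open intervals `c(start, end)`, sorted.
#' @export
scan_lrr_repeats <- function(seq, profile = default_lrr_profile(), score_min = 10) {
  v <- aa_vec(seq)
  n <- length(v)
  w <- ncol(profile)
  if (n < w) return(list())
  lo <- log2(profile / AA_BACKGROUND[rownames(profile)])
  idx <- match(v, rownames(profile))
  # score of window starting at i: sum_j lo[idx[i+j-1], j]
  nw <- n - w + 1
  sc <- numeric(nw)
  for (j in seq_len(w)) {
    cj <- lo[, j][idx[j:(j + nw - 1)]]
    cj[is.na(cj)] <- 0
    sc <- sc + cj
  }
  out <- list()
  i <- 1
  while (i <= nw) {
    if (sc[i] >= score_min) {
      out[[length(out) + 1]] <- c(i - 1L, i - 1L + w)
      i <- i + w
    } else i <- i + 1
  }
  out
}

#' Detect a cleavable N-terminal signal peptide
#'
#' Rule-based stand-in for a full secretion predictor: the first 35
#' residues must contain at least one K/R at positions 2-6 (n-region
#' charge) and a hydrophobic core of >= 6 residues with mean Kyte-Doolittle
#' hydropathy > `kd_min`; the cleavage site is placed after the first small
#' residue (A/G/S/C) following the core, clamped to [15, 35].
#'
#' @param seq amino-acid string.
#' @param kd_min hydropathy threshold for the core window.
#' @return 0-based half-open interval `c(0, cleavage)` or `NULL`.
#' @export
detect_signal_peptide <- function(seq, kd_min = 1.5) {
  v <- aa_vec(seq)
  if (length(v) < 30) return(NULL)
  head35 <- v[1:min(35, length(v))]
  if (!any(head35[2:6] %in% c("K", "R"))) return(NULL)
  km <- kd_window_means(paste(head35, collapse = ""), 6)
  core <- which(km > kd_min)
  if (!length(core)) return(NULL)
  core_end <- core[1] + 6 - 1  # last residue (1-based) of the first core window
  after <- which(head35 %in% c("A", "G", "S", "C"))
  after <- after[after > core_end]
  if (!length(after)) return(NULL)
  c_pos <- min(max(after[1], 15L), 35L)
  c(0L, as.integer(c_pos))
}

#' Detect a C-terminal transmembrane span
#'
#' Highest-scoring Kyte-Doolittle window in the C-terminal 40% of the
#' sequence, reported iff its mean hydropathy reaches `kd_min`.
#'
#' @param seq amino-acid string.
#' @param window window width (aa).
#' @param kd_min mean hydropathy threshold.
#' @return 0-based half-open interval or `NULL`.
#' @export
detect_tm <- function(seq, window = 19, kd_min = 1.6) {
  n <- nchar(seq)
  if (n < window) return(NULL)
  km <- kd_window_means(seq, window)
  from <- max(1L, floor(0.6 * n) + 1L)       # window start within C-terminal 40%
  if (from > length(km)) return(NULL)
  km[seq_len(from - 1)] <- -Inf
  best <- unname(which.max(km))
  if (km[best] < kd_min) return(NULL)
  c(best - 1L, best - 1L + as.integer(window))
}

#' Segment a receptor protein into its canonical domains
#'
#' Domains are labelled A (signal peptide), B (pre-LRR spacer), C1 (LRR
#' block), C2 (non-LRR island), C3 (post-island LRR block), D (linker up to
#' the membrane), optionally E (acidic juxtamembrane stretch of `e_len`,
#' folded into D by default), F (transmembrane) and G (cytoplasmic tail).
#' C2/C3 are assigned at the largest inter-repeat gap of at least
#' `island_min` residues; with no such gap all repeats are C1.
#'
#' @param seq amino-acid string.
#' @param sp signal-peptide interval or `NULL`.
#' @param repeats list of LRR intervals from [scan_lrr_repeats()].
#' @param tm transmembrane interval or `NULL`.
#' @param island_min minimum island size (aa) separating C1 from C3.
#' @param e_len length of the E stretch carved off the end of D (aa).
#' @return Named list of 0-based half-open intervals; absent domains are
#'   omitted.
#' @export
segment_domains <- function(seq, sp, repeats, tm, island_min = 15, e_len = 0) {
  n <- nchar(seq)
  dom <- list()
  if (!is.null(sp)) dom$A <- c(0L, sp[2])
  if (length(repeats)) {
    first <- repeats[[1]][1]; last <- repeats[[length(repeats)]][2]
    b0 <- if (!is.null(sp)) sp[2] else 0L
    if (first > b0) dom$B <- c(b0, first)
    gaps <- if (length(repeats) > 1)
      vapply(2:length(repeats), function(i) as.numeric(repeats[[i]][1] - repeats[[i - 1]][2]), 0)
    else numeric(0)
    big <- which(gaps >= island_min)
    if (length(big)) {
      k <- big[which.max(gaps[big])]
      dom$C1 <- c(repeats[[1]][1], repeats[[k]][2])
      dom$C2 <- c(repeats[[k]][2], repeats[[k + 1]][1])
      dom$C3 <- c(repeats[[k + 1]][1], last)
    } else {
      dom$C1 <- c(first, last)
    }
    d_end <- if (!is.null(tm)) tm[1] - e_len else n
    if (d_end > last) dom$D <- c(last, as.integer(d_end))
    if (e_len > 0 && !is.null(tm)) dom$E <- c(as.integer(d_end), tm[1])
  } else if (!is.null(sp) || !is.null(tm)) {
    b0 <- if (!is.null(sp)) sp[2] else 0L
    b1 <- if (!is.null(tm)) tm[1] else n
    if (b1 > b0) dom$B <- c(b0, b1)
  }
  if (!is.null(tm)) {
    dom$F <- tm
    if (n > tm[2]) dom$G <- c(tm[2], n)
  }
  dom
}

#' Decide whether an annotation is an LRR-RLP
#'
#' True iff the repeat count strictly exceeds `min_lrr`, the signal peptide
#' (A) and transmembrane span (F) are present, and the cytoplasmic tail is
#' shorter than `tail_max` residues (the tail bound is what separates an
#' RLP from a kinase-bearing RLK).
#'
#' @param ann a `ReceptorAnnotation` from [annotate_receptor()].
#' @param min_lrr repeats must exceed this count (strict `>`).
#' @param tail_max maximum cytoplasmic tail length (aa, strict `<`).
#' @return Logical verdict.
#' @export
classify_receptor <- function(ann, min_lrr = 15, tail_max = 30) {
  length(ann$lrr_repeats) > min_lrr &&
    !is.null(ann$domains$A) &&
    !is.null(ann$domains$F) &&
    ann$cytoplasmic_tail_len < tail_max
}

#' Annotate one protein sequence
#'
#' Runs signal-peptide, LRR and transmembrane detection, segments the
#' canonical domains, extracts the concatenated C3+D sequence used for
#' phylogeny, and applies the receptor verdict.
#'
#' @param gene_id identifier carried through to the result.
#' @param seq amino-acid string.
#' @param profile LRR position-weight matrix.
#' @param score_min LRR score threshold (bits).
#' @param island_min,e_len see [segment_domains()].
#' @param min_lrr,tail_max see [classify_receptor()].
#' @return A `ReceptorAnnotation`: list with `gene_id`, `signal_peptide`,
#'   `lrr_repeats`, `island`, `domains`, `tm`, `cytoplasmic_tail_len`,
#'   `is_lrr_rlp`, `c3d_seq`.
#' @export
annotate_receptor <- function(gene_id, seq, profile = default_lrr_profile(),
                              score_min = 10, island_min = 15, e_len = 0,
                              min_lrr = 15, tail_max = 30) {
  sp <- detect_signal_peptide(seq)
  reps <- scan_lrr_repeats(seq, profile, score_min)
  tm <- detect_tm(seq)
  if (!is.null(tm) && length(reps)) {
    # repeats engulfed by the TM window are artefacts of hydrophobic runs
    reps <- Filter(function(r) r[2] <= tm[1], reps)
  }
  dom <- segment_domains(seq, sp, reps, tm, island_min, e_len)
  tail_len <- if (!is.null(dom$G)) iv_len(dom$G) else 0L
  c3d <- ""
  if (!is.null(dom$C3) && !is.null(dom$D)) {
    c3d <- paste0(substr(seq, dom$C3[1] + 1, dom$C3[2]),
                  substr(seq, dom$D[1] + 1, dom$D[2]))
  }
  ann <- list(
    gene_id = gene_id,
    signal_peptide = sp,
    lrr_repeats = reps,
    island = dom$C2,
    domains = dom,
    tm = tm,
    cytoplasmic_tail_len = tail_len,
    is_lrr_rlp = NA,
    c3d_seq = c3d
  )
  ann$is_lrr_rlp <- classify_receptor(ann, min_lrr = min_lrr, tail_max = tail_max)
  class(ann) <- "ReceptorAnnotation"
  ann
}

#' @export
print.ReceptorAnnotation <- function(x, ...) {
  cat(sprintf("ReceptorAnnotation %s: %d LRR repeat(s), domains {%s}, %s\n",
              x$gene_id, length(x$lrr_repeats),
              paste(names(x$domains), collapse = ","),
              if (isTRUE(x$is_lrr_rlp)) "LRR-RLP" else "not an LRR-RLP"))
  invisible(x)
}

#' Annotate every protein of a proteome
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param ... passed to [annotate_receptor()].
#' @return Named list of `ReceptorAnnotation`s.
#' @export
annotate_proteome <- function(proteins, ...) {
  stats::setNames(
    lapply(names(proteins), function(id) annotate_receptor(id, proteins[[id]], ...)),
    names(proteins)
  )
}

#' Tabulate receptor annotations
#'
#' @param anns list from [annotate_proteome()].
#' @return data.frame with one row per protein: `gene_id`, `lrr_count`,
#'   domain presence/intervals, `tail_len`, `is_lrr_rlp`.
#' @export
receptor_table <- function(anns) {
  fmt <- function(iv) if (is.null(iv)) "" else sprintf("%d-%d", iv[1], iv[2])
  data.frame(
    gene_id = vapply(anns, `[[`, "", "gene_id"),
    lrr_count = vapply(anns, function(a) length(a$lrr_repeats), 0L),
    signal_peptide = vapply(anns, function(a) fmt(a$signal_peptide), ""),
    island = vapply(anns, function(a) fmt(a$island), ""),
    tm = vapply(anns, function(a) fmt(a$tm), ""),
    tail_len = vapply(anns, function(a) as.integer(a$cytoplasmic_tail_len), 0L),
    is_lrr_rlp = vapply(anns, function(a) isTRUE(a$is_lrr_rlp), TRUE),
    row.names = NULL
  )
}

#' Extract C3+D sequences of called receptors
#'
#' @param anns list from [annotate_proteome()].
#' @param receptors_only keep only proteins with a positive receptor verdict.
#' @return Named character vector of C3+D amino-acid sequences (non-empty
#'   entries only).
#' @export
c3d_sequences <- function(anns, receptors_only = TRUE) {
  keep <- vapply(anns, function(a) nzchar(a$c3d_seq) && (!receptors_only || isTRUE(a$is_lrr_rlp)), TRUE)
  vapply(anns[keep], `[[`, "", "c3d_seq")
}
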