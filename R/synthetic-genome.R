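# Seeded synthetic-genome generator.  Plants every structure the analysis
# is meant to recover: receptor clusters and super-clusters at configurable
# gaps, interleaved SPUF genes (secreted or not), annotated filler genes,
# tandem-duplication paralog families (receptors of one cluster derive
# from a common founder), an optional twin-chromosome duplicated cluster,
# promoters with a planted conserved block, and expression matrices with
# planted inductions.  Everything is recorded in a SyntheticTruth object.

FILLER_DESCRIPTIONS <- c(
  "protein kinase family protein", "cytochrome P450", "pentatricopeptide repeat protein",
  "MYB transcription factor", "ABC transporter family protein", "glycosyl hydrolase",
  "ubiquitin ligase", "pectin methylesterase", "heat shock protein 70",
  "WD40 repeat protein", "chitinase", "protease inhibitor", "wound-responsive protein"
)
FILLER_DOMAINS <- c("PF00069", "PF00067", "PF01535", "PF00249", "PF00005",
                    "PF00232", "PF00632", "PF01095", "PF00012", "PF00400")

sample_bg <- function(n) sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One LRR repeat instance: wildcards drawn from background, consensus
# positions substituted with probability p_sub.
instantiate_lrr <- function(p_sub) {
  pos <- aa_vec(LRR_CONSENSUS)
  out <- character(length(pos))
  wild <- pos == "x"
  out[wild] <- sample_bg(sum(wild))
  fixed <- !wild
  sub <- fixed & (stats::runif(length(pos)) < p_sub)
  out[fixed & !sub] <- pos[fixed & !sub]
  out[sub] <- sample_bg(sum(sub))
  paste(out, collapse = "")
}

#' Generate a synthetic LRR-RLP protein sequence
#'
#' Builds, N to C: a cleavable signal peptide (Met, two basic residues, a
#' hydrophilic n-region, an 8-residue hydrophobic core and a small-residue
#' cleavage site; 20-28 aa in total), a cysteine-pair cap, `n_lrr` tandem
#' copies of the 24-aa plant LRR consensus with per-position substitution
#' probability `p_sub`, a 25-residue non-LRR island after repeat
#' `ceiling(0.75 * n_lrr)` (separating C1 from C3), a 20-aa acidic linker
#' (D), a 21-aa hydrophobic transmembrane stretch and a cytoplasmic tail
#' shorter than 30 aa.
#'
#' @param n_lrr number of LRR repeats (>= 1).
#' @param seed integer seed or `NULL`.
#' @param p_sub per-position substitution probability within repeats.
#' @param island_len length of the C2 island (aa).
#' @return Amino-acid string.
#' @export
make_receptor_protein <- function(n_lrr, seed = NULL, p_sub = 0.15, island_len = 25) {
  stopifnot(n_lrr >= 1)
  with_seed(seed, {
    f <- sample(8:16, 1)
    sp <- paste0(
      "M", paste(sample(c("K", "R"), 2, replace = TRUE), collapse = ""),
      paste(sample(c("N", "Q", "T", "P", "H", "E", "D"), f, replace = TRUE), collapse = ""),
      paste(sample(c("L", "I", "V", "F"), 8, replace = TRUE), collapse = ""),
      "A"
    )
    reps <- vapply(seq_len(n_lrr), function(i) instantiate_lrr(p_sub), "")
    island_after <- ceiling(0.75 * n_lrr)
    island <- paste(sample(c("N", "Q", "T", "S", "G", "P", "D", "E", "H", "K"),
                           island_len, replace = TRUE), collapse = "")
    lrr_block <- if (island_after >= n_lrr) {
      paste(reps, collapse = "")
    } else {
      paste0(paste(reps[seq_len(island_after)], collapse = ""), island,
             paste(reps[(island_after + 1):n_lrr], collapse = ""))
    }
    dlink <- paste(sample(c("D", "E", "S", "N"), 20, replace = TRUE,
                          prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    tm <- paste(sample(c("L", "I", "V", "F", "A"), 21, replace = TRUE,
                       prob = c(0.35, 0.25, 0.25, 0.1, 0.05)), collapse = "")
    t_len <- sample(8:20, 1)
    tail_seq <- paste(sample(c("K", "R", "S", "T", "N", "Q", "D", "E", "G"),
                             t_len, replace = TRUE), collapse = "")
    paste0(sp, "CC", lrr_block, dlink, tm, tail_seq)
  })
}

# Synthetic SPUF protein: short, and deterministically secreted or not.
# Non-secreted SPUFs keep their first 35 residues free of hydrophobic
# stretches so the signal-peptide heuristic cannot fire.
make_spuf_protein <- function(len, secreted) {
  if (secreted) {
    f <- sample(8:12, 1)
    sp <- paste0("M", paste(sample(c("K", "R"), 2, replace = TRUE), collapse = ""),
                 paste(sample(c("N", "Q", "T", "P", "H", "E", "D"), f, replace = TRUE), collapse = ""),
                 paste(sample(c("L", "I", "V", "F"), 8, replace = TRUE), collapse = ""), "A")
    body <- paste(sample_bg(max(10, len - nchar(sp))), collapse = "")
    paste0(sp, body)
  } else {
    head <- paste0("M", paste(sample(c("D", "E", "N", "Q", "S", "T", "G", "P", "H", "K", "R", "Y", "W"),
                                     34, replace = TRUE), collapse = ""))
    body <- paste(sample_bg(max(5, len - 35)), collapse = "")
    paste0(head, body)
  }
}

#' Mutate a protein sequence at a fixed per-residue rate
#'
#' Each position is replaced, with probability `rate`, by a different
#' residue drawn from the background composition; expected identity to the
#' input is `100 * (1 - rate)` percent.
#'
#' @param seq amino-acid string.
#' @param rate per-residue substitution probability.
#' @param seed integer seed or `NULL`.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(seq, rate, seed = NULL) {
  with_seed(seed, {
    v <- aa_vec(seq)
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) {
      repl <- sample(AA20, 1, prob = AA_BACKGROUND)
      while (repl == v[i]) repl <- sample(AA20, 1, prob = AA_BACKGROUND)
      v[i] <- repl
    }
    paste(v, collapse = "")
  })
}

# DNA mutation toward a target percent identity; `exact` plants the exact
# mismatch count instead of a binomial draw.
mutate_dna <- function(seq, identity, exact = FALSE) {
  v <- aa_vec(seq)
  rate <- (100 - identity) / 100
  hit <- if (exact) sample.int(length(v), round(length(v) * rate))
         else which(stats::runif(length(v)) < rate)
  for (i in hit) {
    repl <- sample(c("A", "C", "G", "T"), 1)
    while (repl == v[i]) repl <- sample(c("A", "C", "G", "T"), 1)
    v[i] <- repl
  }
  paste(v, collapse = "")
}

#' Default parameters of the synthetic genome
#'
#' Three chromosomes (~9 Mb), four planted receptor clusters of 4/3/5/2
#' members at 10-20 kb intra-cluster gaps, the two chromosome-1 clusters
#' ~1.7 Mb apart (one super-cluster), one singleton receptor, one SPUF and
#' (for two gaps per cluster) one annotated filler gene interleaved inside
#' every cluster gap, ~45 SPUF and ~220 annotated filler genes elsewhere
#' (~300 genes in total), cluster members derived from a per-cluster
#' founder protein at 8% divergence, and a 300-bp, 90%-identity conserved
#' block planted between the promoters of a designated SPUF ("RISP"-like)
#' and the singleton receptor.
#'
#' @return Named list of generator parameters.
#' @export
default_genome_params <- function() {
  list(
    chromosomes = c(chr01 = 3.4e6, chr02 = 3.4e6, chr03 = 2.2e6),
    clusters = list(
      list(chrom = "chr01", start = 400000, n_receptors = 4, gap = 10000),
      list(chrom = "chr01", start = 2200000, n_receptors = 3, gap = 15000),
      list(chrom = "chr02", start = 500000, n_receptors = 5, gap = 20000),
      list(chrom = "chr03", start = 300000, n_receptors = 2, gap = 10000)
    ),
    singletons = list(list(chrom = "chr02", start = 2900000)),
    receptor_gene_len = 3200,
    spuf_gene_len = 500,
    filler_gene_len = 1500,
    spuf_per_gap = 1,
    filler_gaps_per_cluster = 2,
    spuf_secreted_frac = 0.5,
    n_spuf_outside = 45,
    n_filler = 220,
    n_lrr_range = c(18, 28),
    p_sub = 0.15,
    within_cluster_divergence = 0.08,
    twin_chromosome = FALSE,
    twin_identity = 96,
    twin_source = 3,
    promoter_len = 1000,
    promoter_block = list(length = 300, identity = 90, offset = -1000),
    inductions = c(risp = 10, rlp9 = 1.8),
    coinduced_cluster = 1,
    with_sequence = TRUE
  )
}

# Place a gene interval, recording it in the occupancy environment.
.occupy <- function(env, chrom, start, end) {
  env$tab[[chrom]] <- rbind(env$tab[[chrom]], c(start, end))
}
.free <- function(env, chrom, start, end) {
  occ <- env$tab[[chrom]]
  is.null(occ) || !any(occ[, 1] < end & occ[, 2] > start)
}

#' Generate a synthetic genome with planted ground truth
#'
#' @param params parameter list; missing entries are filled from
#'   [default_genome_params()].
#' @param seed master integer seed; every internal stream is forked from it.
#' @return List with elements `genome` (a [new_genome()] `Genome` including
#'   proteins and, when `with_sequence`, chromosome DNA) and `truth` (a
#'   `SyntheticTruth` list: `receptor_ids`, `clusters`, `superclusters`,
#'   `spuf_ids`, `secreted_ids`, `paralog_families`, `conserved_block`,
#'   `inductions`, `coinduced`, `baselines`, `gene_ids`, `seed`).
#' @export
make_genome <- function(params = list(), seed = 1) {
  # non-recursive merge: a supplied cluster list replaces the default list
  # wholesale rather than being merged element-wise
  p <- default_genome_params()
  p[names(params)] <- params
  chroms <- p$chromosomes
  genes <- list()
  proteins <- list()
  occ <- new.env(); occ$tab <- list()
  truth_clusters <- list()
  paralog_families <- list()
  spuf_ids <- character(0); secreted_ids <- character(0)
  receptor_ids <- character(0)

  add_gene <- function(id, chrom, strand, start, len, desc = "", hits = character(0), plen = NA_integer_) {
    end <- start + len
    if (start < 0 || end > chroms[[chrom]])
      stopf("placement overflow: gene %s does not fit chromosome %s", id, chrom)
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = id, chrom = chrom, strand = strand, start = start, end = end,
      description = desc, stringsAsFactors = FALSE
    )
    genes[[length(genes)]]$domain_hits <<- list(hits)
    genes[[length(genes)]]$protein_length <<- plen
    .occupy(occ, chrom, start, end)
  }

  # --- planted clusters -------------------------------------------------
  spuf_counter <- 0
  with_seed(derive_seed(seed, 1), {
    for (ci in seq_along(p$clusters)) {
      cl <- p$clusters[[ci]]
      n_lrr <- sample(p$n_lrr_range[1]:p$n_lrr_range[2], 1)
      founder <- make_receptor_protein(n_lrr, p_sub = p$p_sub)
      members <- character(cl$n_receptors)
      pos <- cl$start
      for (m in seq_len(cl$n_receptors)) {
        id <- sprintf("RLP_c%d_%d", ci, m)
        members[m] <- id
        prot <- if (p$within_cluster_divergence > 0)
          mutate_protein(founder, p$within_cluster_divergence) else founder
        proteins[[id]] <- prot
        add_gene(id, cl$chrom, sample(c("+", "-"), 1), pos, p$receptor_gene_len,
                 desc = "", hits = character(0), plen = nchar(prot))
        if (m < cl$n_receptors) {
          gap_start <- pos + p$receptor_gene_len
          # interleave one SPUF per gap, plus a filler in the first
          # `filler_gaps_per_cluster` gaps
          spuf_counter <- spuf_counter + 1
          sid <- sprintf("SPUF_c%d_%d", ci, m)
          secreted <- stats::runif(1) < p$spuf_secreted_frac
          sp_prot <- make_spuf_protein(sample(80:180, 1), secreted)
          proteins[[sid]] <- sp_prot
          add_gene(sid, cl$chrom, sample(c("+", "-"), 1),
                   gap_start + round(cl$gap * 0.25), p$spuf_gene_len,
                   desc = "", hits = character(0), plen = nchar(sp_prot))
          spuf_ids <- c(spuf_ids, sid)
          if (secreted) secreted_ids <- c(secreted_ids, sid)
          if (m <= p$filler_gaps_per_cluster) {
            fid <- sprintf("GENE_c%d_%d", ci, m)
            fl <- sample(250:500, 1)
            fp <- paste(sample_bg(fl), collapse = "")
            proteins[[fid]] <- fp
            add_gene(fid, cl$chrom, sample(c("+", "-"), 1),
                     gap_start + round(cl$gap * 0.65), p$filler_gene_len,
                     desc = sample(FILLER_DESCRIPTIONS, 1),
                     hits = sample(FILLER_DOMAINS, sample(1:2, 1)),
                     plen = fl)
          }
          pos <- pos + p$receptor_gene_len + cl$gap
        }
      }
      receptor_ids <- c(receptor_ids, members)
      paralog_families[[length(paralog_families) + 1]] <- list(
        members = members,
        identity = 100 * (1 - p$within_cluster_divergence)
      )
      span_end <- cl$start + cl$n_receptors * p$receptor_gene_len +
        (cl$n_receptors - 1) * cl$gap
      truth_clusters[[ci]] <- list(
        cluster = ci, chrom = cl$chrom, members = members, gap = cl$gap,
        span = c(cl$start, span_end)
      )
    }
    # singleton receptors
    for (si in seq_along(p$singletons)) {
      s <- p$singletons[[si]]
      id <- sprintf("RLP_s%d", si)
      n_lrr <- sample(p$n_lrr_range[1]:p$n_lrr_range[2], 1)
      prot <- make_receptor_protein(n_lrr, p_sub = p$p_sub)
      proteins[[id]] <- prot
      add_gene(id, s$chrom, sample(c("+", "-"), 1), s$start, p$receptor_gene_len,
               plen = nchar(prot))
      receptor_ids <- c(receptor_ids, id)
    }
  })

  # --- twin-chromosome duplication -------------------------------------
  twin_ids <- character(0)
  if (isTRUE(p$twin_chromosome)) {
    src <- truth_clusters[[p$twin_source]]
    chroms <- c(chroms, chr_twin = unname(diff(src$span)) + 6e5)
    names(chroms)[length(chroms)] <- "chr_twin"
    with_seed(derive_seed(seed, 2), {
      shift <- 3e5 - src$span[1]
      src_rows <- do.call(rbind, genes)
      src_rows <- src_rows[src_rows$chrom == src$chrom &
                             src_rows$start >= src$span[1] &
                             src_rows$end <= src$span[2] + 1, , drop = FALSE]
      tw_members <- character(0)
      for (r in seq_len(nrow(src_rows))) {
        g <- src_rows[r, ]
        tid <- paste0(g$gene_id, "_t")
        prot <- mutate_protein(proteins[[g$gene_id]], (100 - p$twin_identity) / 100)
        proteins[[tid]] <- prot
        add_gene(tid, "chr_twin", g$strand, g$start + shift, g$end - g$start,
                 desc = g$description, hits = g$domain_hits[[1]], plen = nchar(prot))
        if (g$gene_id %in% receptor_ids) {
          receptor_ids <- c(receptor_ids, tid)
          tw_members <- c(tw_members, tid)
          paralog_families[[length(paralog_families) + 1]] <- list(
            members = c(g$gene_id, tid), identity = p$twin_identity
          )
        } else if (g$gene_id %in% spuf_ids) {
          spuf_ids <- c(spuf_ids, tid)
          if (g$gene_id %in% secreted_ids) secreted_ids <- c(secreted_ids, tid)
        }
      }
      tci <- length(truth_clusters) + 1
      truth_clusters[[tci]] <- list(
        cluster = tci, chrom = "chr_twin", members = tw_members,
        gap = p$clusters[[p$twin_source]]$gap,
        span = c(3e5, 3e5 + unname(diff(src$span)))
      )
      twin_ids <- tw_members
    })
  }

  # --- scattered SPUF and filler genes ---------------------------------
  with_seed(derive_seed(seed, 3), {
    cluster_spans <- lapply(truth_clusters, function(tc) c(tc$chrom, tc$span))
    place_random <- function(id, len, desc, hits, plen) {
      for (try in 1:500) {
        chrom <- sample(names(chroms), 1, prob = chroms / sum(chroms))
        start <- sample.int(chroms[[chrom]] - len - 2000, 1) + 1000
        in_cluster <- any(vapply(truth_clusters, function(tc)
          tc$chrom == chrom && start < tc$span[2] && (start + len) > tc$span[1], TRUE))
        if (!in_cluster && .free(occ, chrom, start, start + len)) {
          add_gene(id, chrom, sample(c("+", "-"), 1), start, len, desc, hits, plen)
          return(invisible(NULL))
        }
      }
      stopf("placement overflow: could not place gene %s", id)
    }
    for (i in seq_len(p$n_spuf_outside)) {
      id <- sprintf("SPUF_o%03d", i)
      secreted <- stats::runif(1) < p$spuf_secreted_frac
      prot <- make_spuf_protein(sample(80:180, 1), secreted)
      proteins[[id]] <- prot
      place_random(id, p$spuf_gene_len, "", character(0), nchar(prot))
      spuf_ids <- c(spuf_ids, id)
      if (secreted) secreted_ids <- c(secreted_ids, id)
    }
    for (i in seq_len(p$n_filler)) {
      id <- sprintf("GENE_f%03d", i)
      fl <- sample(250:500, 1)
      proteins[[id]] <- paste(sample_bg(fl), collapse = "")
      place_random(id, p$filler_gene_len,
                   sample(FILLER_DESCRIPTIONS, 1),
                   sample(FILLER_DOMAINS, sample(1:2, 1)), fl)
    }
  })

  gene_df <- do.call(rbind, genes)

  # --- chromosome sequence + planted promoter block --------------------
  genomic_seq <- NULL
  block_truth <- NULL
  if (isTRUE(p$with_sequence)) {
    seqs <- lapply(seq_along(chroms), function(i)
      with_seed(derive_seed(seed, 10 + i), random_dna(chroms[[i]])))
    names(seqs) <- names(chroms)
    genomic_seq <- Biostrings::DNAStringSet(unlist(seqs))
    # conserved block between the "RISP"-like SPUF (first SPUF of the last
    # planted cluster) and its associated receptor
    risp_id <- sprintf("SPUF_c%d_1", length(p$clusters))
    rlp9_id <- sprintf("RLP_c%d_1", length(p$clusters))
    if (all(c(risp_id, rlp9_id) %in% gene_df$gene_id)) {
      bl <- p$promoter_block
      genomic_seq <- with_seed(derive_seed(seed, 30), {
        block <- random_dna(bl$length)
        gs <- plant_promoter_block(genomic_seq, gene_df, risp_id, block,
                                   bl$offset, p$promoter_len)
        block_b <- mutate_dna(block, bl$identity, exact = TRUE)
        plant_promoter_block(gs, gene_df, rlp9_id, block_b, bl$offset, p$promoter_len)
      })
      block_truth <- list(gene_a = risp_id, gene_b = rlp9_id,
                          offset = bl$offset, length = bl$length,
                          identity = bl$identity)
    }
  }

  genome <- new_genome(chroms, gene_df, proteins = unlist(proteins),
                       genomic_seq = genomic_seq)

  # planted super-clusters: consecutive planted clusters on one chromosome
  # whose span gap is below 2 Mb
  sc <- list()
  by_chr <- split(seq_along(truth_clusters),
                  vapply(truth_clusters, `[[`, "", "chrom"))
  for (idx in by_chr) {
    idx <- idx[order(vapply(truth_clusters[idx], function(tc) tc$span[1], 0))]
    run <- idx[1]
    for (j in seq_along(idx)[-1]) {
      gap <- truth_clusters[[idx[j]]]$span[1] - truth_clusters[[idx[j - 1]]]$span[2]
      if (gap < 2e6) run <- c(run, idx[j])
      else {
        if (length(run) >= 2) sc[[length(sc) + 1]] <- run
        run <- idx[j]
      }
    }
    if (length(run) >= 2) sc[[length(sc) + 1]] <- run
  }

  risp_id <- sprintf("SPUF_c%d_1", length(p$clusters))
  risp_rlp_id <- sprintf("RLP_c%d_1", length(p$clusters))
  inductions <- stats::setNames(
    c(p$inductions[["risp"]], p$inductions[["rlp9"]]),
    c(risp_id, risp_rlp_id)
  )
  inductions <- inductions[names(inductions) %in% gene_df$gene_id]
  coind <- truth_clusters[[p$coinduced_cluster]]$members
  coind_spufs <- grep(sprintf("^SPUF_c%d_", p$coinduced_cluster), gene_df$gene_id, value = TRUE)
  coinduced <- c(coind, coind_spufs)
  baselines <- stats::setNames(
    c(rep(5000, length(coind)), rep(3000, length(coind_spufs)), 15000, 1200, 4500),
    c(coind, coind_spufs, sprintf("SPUF_o%03d", 1), risp_id, risp_rlp_id)
  )
  baselines <- baselines[names(baselines) %in% gene_df$gene_id]

  truth <- list(
    receptor_ids = receptor_ids,
    clusters = truth_clusters,
    superclusters = sc,
    spuf_ids = spuf_ids,
    secreted_ids = secreted_ids,
    paralog_families = paralog_families,
    conserved_block = block_truth,
    inductions = inductions,
    coinduced = coinduced,
    baselines = baselines,
    gene_ids = genome$genes$gene_id,
    seed = seed,
    params = p
  )
  class(truth) <- "SyntheticTruth"
  list(genome = genome, truth = truth)
}

# Overwrite the promoter region [offset, offset + nchar(block)) of a gene
# (offsets relative to the translation start, e.g. -1000) with `block`,
# strand-aware.
plant_promoter_block <- function(genomic_seq, gene_df, gene_id, block,
                                 offset, promoter_len) {
  g <- gene_df[gene_df$gene_id == gene_id, ]
  len <- nchar(block)
  if (g$strand == "+") {
    at0 <- g$start + offset            # 0-based chromosome position
    value <- block
  } else {
    # promoter runs away from the gene end on the reverse strand; promoter
    # index i (0 = -promoter_len) maps to chromosome position
    # end + promoter_len - 1 - i
    at0 <- g$end + (-offset) - len
    value <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(block)))
  }
  if (at0 < 0) stopf("conserved block does not fit upstream of %s", gene_id)
  genomic_seq[[g$chrom]] <- Biostrings::replaceAt(
    genomic_seq[[g$chrom]],
    IRanges::IRanges(at0 + 1, at0 + len),
    Biostrings::DNAString(value)
  )
  genomic_seq
}

#' Generate paired expression matrices with planted inductions
#'
#' Baseline intensities are log-normal (median `exp(baseline_meanlog)`),
#' shared between treatments; the wounded-treatment mean of each planted
#' induced gene is multiplied by its fold change.  Columns are paired: a
#' shared per-condition factor (applied to both treatments of the
#' designated co-induced genes) creates correlated profiles without biasing
#' the fold-change estimate.
#'
#' @param truth `SyntheticTruth` from [make_genome()].
#' @param n_cond conditions per treatment.
#' @param noise_sd standard deviation of the per-cell log-normal noise.
#' @param seed integer seed.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param cond_sd standard deviation of the shared condition factor of
#'   co-induced genes.
#' @return List with matrices `nonwounded` and `wounded` (genes x
#'   conditions).
#' @export
make_expression <- function(truth, n_cond = 6, noise_sd = 0.2, seed = 1,
                            baseline_meanlog = log(500), baseline_sdlog = 1,
                            cond_sd = 0.5) {
  ids <- truth$gene_ids
  n <- length(ids)
  with_seed(derive_seed(seed, 41), {
    base <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    names(base) <- ids
    ov <- truth$baselines
    if (length(ov)) base[names(ov)] <- ov
    fc <- rep(1, n); names(fc) <- ids
    if (length(truth$inductions)) fc[names(truth$inductions)] <- truth$inductions
    shared <- stats::rnorm(n_cond, 0, cond_sd)
    coin <- ids %in% truth$coinduced
    mk <- function(mult) {
      m <- matrix(0, n, n_cond, dimnames = list(ids, paste0("cond_", seq_len(n_cond))))
      for (cc in seq_len(n_cond)) {
        s <- ifelse(coin, exp(shared[cc]), 1)
        eps <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else 1
        m[, cc] <- base * mult * s * eps
      }
      m
    }
    list(nonwounded = mk(1), wounded = mk(fc))
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits GFF3, protein FASTA, genomic FASTA (when present), an annotation
#' TSV (`gene_id`, `description`, `domain_hits`, `protein_length`), the two
#' expression TSVs and the ground truth as JSON.
#'
#' @param genome `Genome` from [make_genome()].
#' @param truth `SyntheticTruth`.
#' @param expr list from [make_expression()], or `NULL`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_bundle <- function(genome, truth, expr = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(genome, file.path(outdir, "genome.gff3"))
  write_fasta(genome$proteins, file.path(outdir, "proteins.fasta"), type = "protein")
  if (!is.null(genome$genomic_seq))
    Biostrings::writeXStringSet(genome$genomic_seq, file.path(outdir, "genome.fasta"))
  ann <- data.frame(
    gene_id = genome$genes$gene_id,
    description = genome$genes$description,
    domain_hits = vapply(genome$genes$domain_hits, paste, "", collapse = ","),
    protein_length = genome$genes$protein_length
  )
  utils::write.table(ann, file.path(outdir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(expr)) {
    write_expression(expr$nonwounded, file.path(outdir, "expression_nonwounded.tsv"))
    write_expression(expr$wounded, file.path(outdir, "expression_wounded.tsv"))
  }
  tr <- truth
  class(tr) <- NULL
  tr$params <- NULL
  jsonlite::write_json(tr, file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
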