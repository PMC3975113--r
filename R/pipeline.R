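# End-to-end orchestration: annotate -> cluster -> associate ->
# SPUF/enrichment -> phylogeny -> expression -> promoters, with one
# config object carrying every threshold (serialized into the report for
# provenance) and per-stage gene counts for auditability.

#' Default pipeline configuration
#'
#' Every numeric threshold of the analysis in one list: cluster gap 50 kb,
#' super-cluster gap 2 Mb, association window 25 kb, SPUF length bound
#' 200 aa, receptor repeat bound (> 15 LRRs), expression category bounds
#' 4,000 / 10,000, induction bands 1.5 / 5, background 200, promoter scan
#' parameters, permutation count and seed.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    cluster_gap_max = 50000,
    sc_gap_max = 2e6,
    window = 25000,
    spuf_len_max = 200,
    min_lrr = 15,
    tail_max = 30,
    lrr_score_min = 10,
    island_min = 15,
    homology_score_min = 1.0,
    top_k = 9,
    n_clades = 4,
    background = 200,
    pseudocount = 1,
    induction_bands = c(1.5, 5),
    cat_bounds = c(4000, 10000),
    promoter_len = 1000,
    promoter_window = 100,
    promoter_step = 10,
    promoter_min_identity = 85,
    promoter_min_block = 200,
    promoter_band = 50,
    n_perm = 1000,
    seed = 1
  )
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; any stage failure aborts with the stage
#' name.  Expression and promoter stages are skipped (and flagged in the
#' report) when their inputs are absent.
#'
#' @param genome a `Genome` with proteins (and, for the promoter stage,
#'   chromosome sequence).
#' @param expr optional list with matrices `nonwounded` and `wounded`.
#' @param config configuration list; missing entries filled from
#'   [default_config()].
#' @param outdir optional output directory for TSV/BED/Newick/JSON
#'   artifacts.
#' @return A report list: `config`, per-stage results (`receptors`,
#'   `architecture`, `association`, `spuf`, `enrichment`, `phylo`,
#'   `expression`, `promoter`), and `skipped` (character vector of stages
#'   not run).
#' @export
run_all <- function(genome, expr = NULL, config = list(), outdir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  skipped <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  anns <- stage("annotate", annotate_proteome(
    genome$proteins, score_min = cfg$lrr_score_min, island_min = cfg$island_min,
    min_lrr = cfg$min_lrr, tail_max = cfg$tail_max))
  rec_tab <- receptor_table(anns)
  receptor_ids <- rec_tab$gene_id[rec_tab$is_lrr_rlp]

  called <- stage("cluster", call_clusters(
    genome$genes[genome$genes$gene_id %in% receptor_ids, , drop = FALSE],
    cluster_gap_max = cfg$cluster_gap_max))
  scs <- stage("cluster", call_superclusters(called$clusters, sc_gap_max = cfg$sc_gap_max))
  arch <- summarize_architecture(called, scs, receptor_ids, k = cfg$top_k)

  assoc <- stage("associate", collect_associated(genome, receptor_ids, window = cfg$window))

  spufs <- stage("spuf", spuf_flags(genome, receptor_ids, len_max = cfg$spuf_len_max))
  spuf_tab <- stage("spuf", spuf_records(genome, receptor_ids,
                                         score_min = cfg$homology_score_min,
                                         len_max = cfg$spuf_len_max))
  enr <- stage("enrich", enrichment(genome, receptor_ids, spufs,
                                    clusters = called$clusters, window = cfg$window,
                                    top_k = cfg$top_k, n_perm = cfg$n_perm,
                                    seed = cfg$seed))
  truncated <- stage("spuf", tag_truncated_lrr(genome, assoc$union, receptor_ids,
                                               score_min = cfg$lrr_score_min))

  phylo <- NULL
  c3d <- c3d_sequences(anns)
  if (length(c3d) >= 3) {
    dm <- stage("phylo", build_distance_matrix(c3d))
    tree <- stage("phylo", neighbor_joining(dm))
    loc <- cluster_labels(called, genome)
    conc <- stage("phylo", clade_locus_concordance(tree, loc[names(c3d)], k = cfg$n_clades))
    phylo <- list(tree = tree, distance_matrix = dm, concordance = conc)
  } else skipped <- c(skipped, "phylo")

  expression <- NULL; pairs <- NULL
  if (!is.null(expr)) {
    expression <- stage("expression", summarize_expression(
      expr$nonwounded, expr$wounded, background = cfg$background,
      pseudocount = cfg$pseudocount, bands = cfg$induction_bands,
      cat_bounds = cfg$cat_bounds))
    pairs <- stage("expression", coexpressed_pairs(
      called$clusters, assoc, expression, names(spufs)[spufs],
      background = cfg$background, mat_nw = expr$nonwounded, mat_w = expr$wounded))
  } else skipped <- c(skipped, "expression")

  promoter <- NULL
  if (!is.null(genome$genomic_seq) && !is.null(pairs) && nrow(pairs)) {
    promoter <- stage("promoter", {
      out <- list()
      for (r in seq_len(nrow(pairs))) {
        pa <- extract_promoter(genome, pairs$receptor_id[r], cfg$promoter_len)
        pb <- extract_promoter(genome, pairs$spuf_id[r], cfg$promoter_len)
        bl <- scan_conserved_blocks(pa, pb,
                                    window = cfg$promoter_window, step = cfg$promoter_step,
                                    min_identity = cfg$promoter_min_identity,
                                    min_block = cfg$promoter_min_block,
                                    band = cfg$promoter_band)
        if (nrow(bl)) {
          bl$gene_a <- pairs$receptor_id[r]; bl$gene_b <- pairs$spuf_id[r]
          out[[length(out) + 1]] <- bl
        }
      }
      if (length(out)) do.call(rbind, out) else NULL
    })
  } else if (is.null(genome$genomic_seq)) skipped <- c(skipped, "promoter")

  report <- list(
    config = cfg,
    receptors = rec_tab,
    receptor_ids = receptor_ids,
    architecture = arch,
    clusters = called,
    superclusters = scs,
    association = assoc,
    spuf = spuf_tab,
    truncated_lrr = truncated,
    enrichment = enr,
    phylo = phylo,
    expression = expression,
    coexpressed = pairs,
    promoter = promoter,
    skipped = skipped
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Location label per receptor: cluster id when clustered, otherwise the
# chromosome.
cluster_labels <- function(called, genome) {
  g <- genome$genes
  lab <- stats::setNames(paste0("chr:", g$chrom), g$gene_id)
  for (cl in called$clusters) lab[cl$members] <- cl$cluster_id
  lab
}

# Write the machine-readable pieces of a pipeline report.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$receptors, file.path(outdir, "receptors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(report$clusters$clusters, file.path(outdir, "clusters.bed"))
  write_bed(report$superclusters, file.path(outdir, "superclusters.bed"))
  utils::write.table(report$spuf, file.path(outdir, "spuf_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$phylo))
    write_newick(report$phylo$tree, file.path(outdir, "c3d_tree.nwk"))
  if (!is.null(report$expression))
    utils::write.table(report$expression, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- pipeline_summary(report)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Compact numeric summary of a pipeline report
#'
#' Mirrors the structure of a two-genome receptor/SPUF comparison table:
#' family size, clustered count and cluster count, associated-gene count
#' with per-receptor mean and SD, SPUF counts and percentages, secreted
#' SPUFs, and the paralog-count histogram.
#'
#' @param report list from [run_all()].
#' @return Named list of scalars (plus the paralog histogram).
#' @export
pipeline_summary <- function(report) {
  arch <- report$architecture
  per_counts <- vapply(report$association$per_receptor, nrow, 0L)
  spuf_ids <- report$spuf$gene_id
  assoc <- report$association$union
  n_assoc_spuf <- length(intersect(assoc, spuf_ids))
  npar <- report$spuf$n_paralogs
  list(
    n_receptors = arch$n_receptors,
    n_clustered = arch$n_clustered,
    n_clusters = arch$n_clusters,
    pct_clustered = arch$pct_clustered,
    pct_family_top = arch$pct_family_top,
    n_associated = length(assoc),
    assoc_per_receptor_mean = if (length(per_counts)) mean(per_counts) else 0,
    assoc_per_receptor_sd = if (length(per_counts) > 1) stats::sd(per_counts) else 0,
    n_spuf = length(spuf_ids),
    n_spuf_associated = n_assoc_spuf,
    pct_spuf_associated = report$enrichment$pct_spuf_associated,
    pct_spuf_genome = report$enrichment$pct_spuf_genome,
    enrichment_p = report$enrichment$p_value,
    n_secreted = sum(report$spuf$secreted),
    n_no_paralog = sum(npar == 0),
    n_one_or_two_paralogs = sum(npar %in% 1:2),
    concordance_ari = if (!is.null(report$phylo)) report$phylo$concordance$ari else NA_real_
  )
}

#' Render a two-genome comparison table
#'
#' Formats the family/SPUF summary rows of two genomes side by side, with
#' percentages to one decimal place; counts of zero receptors render as
#' dashes rather than dividing by zero.
#'
#' @param summary_self,summary_other lists from [pipeline_summary()] (or
#'   any list with compatible fields).
#' @param labels column labels.
#' @return data.frame with one row per statistic and one column per
#'   genome.
#' @export
make_table1 <- function(summary_self, summary_other,
                        labels = c("genome_A", "genome_B")) {
  fmt <- function(s) {
    no_rec <- (s$n_receptors %||% 0) == 0
    c(
      "LRR-RLP genes" = as.character(s$n_receptors %||% 0),
      "SPUF genes" = as.character(s$n_spuf %||% 0),
      "LRR-RLP-associated genes [avg. per LRR-RLP gene]" =
        if (no_rec) "-" else sprintf("%d [%.2f +/- %.1f]", s$n_associated,
                                     s$assoc_per_receptor_mean, s$assoc_per_receptor_sd),
      "% of SPUF genes among LRR-RLP-associated genes" =
        if (no_rec) "-" else pct1(s$n_spuf_associated, s$n_associated),
      "% of SPUF genes in the whole predicted proteome" =
        sprintf("~%.0f", s$pct_spuf_genome %||% 0),
      "LRR-RLP genes clustered [no. of clusters]" =
        if (no_rec) "-" else sprintf("%d [%d]", s$n_clustered, s$n_clusters),
      "SPUFs predicted secreted" = as.character(s$n_secreted %||% 0),
      "SPUFs with no paralog" = as.character(s$n_no_paralog %||% 0),
      "SPUFs with 1 or 2 paralogs" = as.character(s$n_one_or_two_paralogs %||% 0)
    )
  }
  a <- fmt(summary_self); b <- fmt(summary_other)
  df <- data.frame(statistic = names(a), a = unname(a), b = unname(b),
                   stringsAsFactors = FALSE)
  names(df)[2:3] <- labels
  df
}
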