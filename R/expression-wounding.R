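# Wounded vs non-wounded expression comparison: per-gene treatment means
# (equal-weight average over the conditions of each treatment), expression
# categories, fold change and induction calls; plus the receptor/SPUF
# co-expression screen within clusters.

#' Summarize expression across two treatments
#'
#' Means are taken over the columns of each matrix.  A gene is `expressed`
#' iff either treatment mean exceeds `background`.  The category is a step
#' function of the larger treatment mean: `below_background`, `low_medium`
#' (<= `cat_bounds[1]`), `higher` (<= `cat_bounds[2]`) or `very_high`.
#' Fold change is `(mean_wounded + pseudocount) / (mean_nonwounded +
#' pseudocount)`; induction is `strong` at FC >= `bands[2]`, `slight` at
#' FC in `[bands[1], bands[2])`, else `none`.
#'
#' @param mat_nw,mat_w non-wounded / wounded matrices (same genes; same
#'   number of condition columns).
#' @param background intensity threshold for "expressed".
#' @param pseudocount added to both means before the ratio.
#' @param bands numeric `c(slight, strong)` fold-change cutoffs.
#' @param cat_bounds numeric `c(low_medium_max, higher_max)` intensities.
#' @return data.frame: `gene_id`, `mean_nonwounded`, `mean_wounded`,
#'   `expressed`, `category`, `fold_change`, `induction`.
#' @export
summarize_expression <- function(mat_nw, mat_w, background = 200, pseudocount = 1,
                                 bands = c(1.5, 5), cat_bounds = c(4000, 10000)) {
  if (ncol(mat_nw) != ncol(mat_w))
    stopf("condition count mismatch: %d vs %d columns", ncol(mat_nw), ncol(mat_w))
  ids <- rownames(mat_nw)
  if (!setequal(ids, rownames(mat_w))) stopf("gene sets of the two matrices differ")
  mat_w <- mat_w[ids, , drop = FALSE]
  m_nw <- rowMeans(mat_nw)
  m_w <- rowMeans(mat_w)
  mx <- pmax(m_nw, m_w)
  expressed <- mx > background
  category <- ifelse(!expressed, "below_background",
              ifelse(mx <= cat_bounds[1], "low_medium",
              ifelse(mx <= cat_bounds[2], "higher", "very_high")))
  fc <- (m_w + pseudocount) / (m_nw + pseudocount)
  induction <- ifelse(fc >= bands[2], "strong",
               ifelse(fc >= bands[1], "slight", "none"))
  data.frame(
    gene_id = ids,
    mean_nonwounded = unname(m_nw),
    mean_wounded = unname(m_w),
    expressed = unname(expressed),
    category = unname(category),
    fold_change = unname(fc),
    induction = unname(induction),
    row.names = NULL
  )
}

#' Regression of wounded on non-wounded treatment means
#'
#' Ordinary least squares of `mean_wounded` on `mean_nonwounded` over a
#' gene set.
#'
#' @param results data.frame from [summarize_expression()].
#' @param gene_ids optional subset of genes.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
regression_wounded_vs_nonwounded <- function(results, gene_ids = NULL) {
  df <- results
  if (!is.null(gene_ids)) df <- df[df$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(df) < 2) stopf("regression needs at least 2 genes")
  fit <- stats::lm(mean_wounded ~ mean_nonwounded, data = df)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared)
}

#' Co-expressed receptor/SPUF pairs within clusters
#'
#' For each cluster, every (receptor, SPUF) pair in which both genes are
#' expressed above `background` is emitted.  SPUFs are taken from the
#' association lists of the cluster's receptors.  When expression matrices
#' with at least 4 conditions are supplied, the Pearson correlation of the
#' two genes across the paired condition columns (both treatments
#' concatenated) is attached.
#'
#' @param clusters clusters from [call_clusters()].
#' @param association result of [collect_associated()].
#' @param results data.frame from [summarize_expression()].
#' @param spuf_ids character vector of SPUF gene ids.
#' @param background expression threshold.
#' @param mat_nw,mat_w optional expression matrices for the correlation.
#' @return data.frame: `cluster_id`, `receptor_id`, `spuf_id`,
#'   `mean_receptor`, `mean_spuf`, `correlation` (`NA` without matrices).
#' @export
coexpressed_pairs <- function(clusters, association, results, spuf_ids,
                              background = 200, mat_nw = NULL, mat_w = NULL) {
  mean_max <- stats::setNames(pmax(results$mean_nonwounded, results$mean_wounded),
                              results$gene_id)
  profile <- NULL
  if (!is.null(mat_nw) && !is.null(mat_w) && ncol(mat_nw) + ncol(mat_w) >= 4) {
    profile <- cbind(mat_nw, mat_w[rownames(mat_nw), , drop = FALSE])
  }
  rows <- list()
  for (cl in clusters) {
    for (rid in cl$members) {
      if (is.na(mean_max[rid]) || mean_max[rid] <= background) next
      assoc <- association$per_receptor[[rid]]
      if (is.null(assoc)) next
      for (sid in intersect(assoc$gene_id, spuf_ids)) {
        if (is.na(mean_max[sid]) || mean_max[sid] <= background) next
        corr <- NA_real_
        if (!is.null(profile) && all(c(rid, sid) %in% rownames(profile)) &&
            stats::sd(profile[rid, ]) > 0 && stats::sd(profile[sid, ]) > 0)
          corr <- stats::cor(profile[rid, ], profile[sid, ])
        rows[[length(rows) + 1]] <- data.frame(
          cluster_id = cl$cluster_id, receptor_id = rid, spuf_id = sid,
          mean_receptor = unname(mean_max[rid]), mean_spuf = unname(mean_max[sid]),
          correlation = corr, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(0), receptor_id = character(0),
                      spuf_id = character(0), mean_receptor = numeric(0),
                      mean_spuf = numeric(0), correlation = numeric(0)))
  unique(do.call(rbind, rows))
}
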