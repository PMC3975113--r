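# Cluster / super-cluster calling and vicinity-gene association.
#
# A cluster is >= 2 receptor genes chained on one chromosome at
# consecutive boundary gaps (next start - previous end) of at most
# `cluster_gap_max` (the 50 kb stretch includes its bound); a
# super-cluster is >= 2 clusters whose span gaps are strictly below
# `sc_gap_max` (2 Mb, exclusive).  Note the chaining interpretation: the
# 50 kb rule bounds consecutive gaps, not the total span — observed
# clusters of up to seven members are impossible under a hard span cap.

#' Call receptor gene clusters by distance chaining
#'
#' @param receptor_genes data.frame of receptor gene models (subset of
#'   `genome$genes`); order is irrelevant.
#' @param cluster_gap_max maximum consecutive boundary gap in bp
#'   (inclusive).
#' @return List with `clusters` (each a list `cluster_id`, `chrom`,
#'   `members`, `span`) and `singletons` (character vector of receptor ids
#'   in no cluster).
#' @export
call_clusters <- function(receptor_genes, cluster_gap_max = 50000) {
  g <- receptor_genes[order(receptor_genes$chrom, receptor_genes$start), , drop = FALSE]
  clusters <- list(); singles <- character(0)
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, , drop = FALSE]
    n <- nrow(gc)
    if (n == 1) { singles <- c(singles, gc$gene_id); next }
    # gap to the running chain end, so nested/overlapping spans chain
    # exactly like the transitive closure of the pairwise gap relation
    gaps <- gc$start[-1] - cummax(gc$end)[-n]
    brk <- c(0, which(gaps > cluster_gap_max), n)
    for (k in seq_len(length(brk) - 1)) {
      idx <- (brk[k] + 1):brk[k + 1]
      if (length(idx) >= 2) {
        clusters[[length(clusters) + 1]] <- list(
          chrom = chrom,
          members = gc$gene_id[idx],
          span = c(min(gc$start[idx]), max(gc$end[idx]))
        )
      } else singles <- c(singles, gc$gene_id[idx])
    }
  }
  # canonical ids in (chrom, start) order
  if (length(clusters)) {
    ord <- order(vapply(clusters, `[[`, "", "chrom"),
                 vapply(clusters, function(cl) cl$span[1], 0))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- sprintf("C%d", i)
  }
  list(clusters = clusters, singletons = singles)
}

#' Call super-clusters of receptor clusters
#'
#' @param clusters list of clusters from [call_clusters()].
#' @param sc_gap_max maximum span gap in bp (strict `<`).
#' @return List of super-clusters, each a list `sc_id`, `chrom`,
#'   `member_clusters` (cluster ids), `span`.
#' @export
call_superclusters <- function(clusters, sc_gap_max = 2e6) {
  if (length(clusters) < 2) return(list())
  chroms <- vapply(clusters, `[[`, "", "chrom")
  out <- list()
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    idx <- idx[order(vapply(clusters[idx], function(cl) cl$span[1], 0))]
    run <- idx[1]
    flush <- function(run) {
      if (length(run) >= 2) {
        spans <- vapply(clusters[run], `[[`, numeric(2), "span")
        out[[length(out) + 1]] <<- list(
          chrom = chrom,
          member_clusters = vapply(clusters[run], `[[`, "", "cluster_id"),
          span = c(min(spans[1, ]), max(spans[2, ]))
        )
      }
    }
    chain_end <- clusters[[idx[1]]]$span[2]
    for (j in seq_along(idx)[-1]) {
      gap <- clusters[[idx[j]]]$span[1] - chain_end
      if (gap < sc_gap_max) run <- c(run, idx[j]) else { flush(run); run <- idx[j] }
      chain_end <- max(chain_end, clusters[[idx[j]]]$span[2])
      if (gap >= sc_gap_max) chain_end <- clusters[[idx[j]]]$span[2]
    }
    flush(run)
  }
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "chrom"),
                 vapply(out, function(s) s$span[1], 0))
    out <- out[ord]
    for (i in seq_along(out)) out[[i]]$sc_id <- sprintf("SC%d", i)
  }
  out
}

#' Collect genes associated with receptor neighbourhoods
#'
#' A gene is associated with a receptor iff its span overlaps the
#' receptor's span padded by `window` bp on both sides (any overlap of
#' half-open intervals).  Receptors are never counted as associated genes
#' of any receptor.  Per-locus window overrides are supported (a named
#' vector), mirroring analyses where a wider vicinity is inspected for a
#' specific super-cluster.
#'
#' @param genome a `Genome`.
#' @param receptor_ids character vector of receptor gene ids.
#' @param window padding in bp (>= 0).
#' @param overrides optional named numeric vector of per-receptor windows.
#' @return List with `per_receptor` (named list of data.frames `gene_id`,
#'   `distance`; signed bp distance, negative upstream of the receptor
#'   start, 0 when overlapping) and `union` (sorted unique associated
#'   gene ids).
#' @export
collect_associated <- function(genome, receptor_ids, window = 25000, overrides = NULL) {
  if (window < 0) stopf("association window must be >= 0")
  g <- genome$genes
  rec <- g[g$gene_id %in% receptor_ids, , drop = FALSE]
  oth <- g[!g$gene_id %in% receptor_ids, , drop = FALSE]
  per <- vector("list", nrow(rec))
  names(per) <- rec$gene_id
  for (i in seq_len(nrow(rec))) {
    w <- if (!is.null(overrides) && rec$gene_id[i] %in% names(overrides))
      overrides[[rec$gene_id[i]]] else window
    lo <- rec$start[i] - w
    hi <- rec$end[i] + w
    hit <- oth$chrom == rec$chrom[i] & oth$start < hi & oth$end > lo
    hits <- oth[hit, , drop = FALSE]
    dist <- ifelse(hits$end <= rec$start[i], hits$end - rec$start[i],
                   ifelse(hits$start >= rec$end[i], hits$start - rec$end[i], 0))
    per[[i]] <- data.frame(gene_id = hits$gene_id, distance = dist,
                           stringsAsFactors = FALSE)
  }
  list(per_receptor = per,
       union = sort(unique(unlist(lapply(per, `[[`, "gene_id")))))
}

#' Summarize the genomic architecture of a receptor family
#'
#' @param called result of [call_clusters()].
#' @param superclusters result of [call_superclusters()].
#' @param receptor_ids all receptor gene ids.
#' @param k number of largest cluster/super-cluster units for the
#'   top-unit percentage (clusters belonging to one super-cluster count as
#'   a single unit).
#' @return List: `n_receptors`, `n_clustered`, `n_clusters`,
#'   `pct_clustered`, `cluster_sizes`, `supercluster_sizes`,
#'   `n_top_units`, `n_receptors_top`, `pct_family_top` (integer percent).
#' @export
summarize_architecture <- function(called, superclusters, receptor_ids, k = 9) {
  clusters <- called$clusters
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  n_rec <- length(receptor_ids)
  n_clustered <- sum(sizes)
  # units: super-clusters absorb their member clusters
  in_sc <- unlist(lapply(superclusters, `[[`, "member_clusters"))
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  unit_sizes <- c(
    vapply(superclusters, function(s) sum(sizes[ids %in% s$member_clusters]), 0L),
    sizes[!ids %in% in_sc]
  )
  unit_sizes <- sort(unit_sizes, decreasing = TRUE)
  top <- utils::head(unit_sizes, k)
  list(
    n_receptors = n_rec,
    n_clustered = n_clustered,
    n_clusters = length(clusters),
    pct_clustered = pct_int(n_clustered, n_rec),
    cluster_sizes = sizes,
    supercluster_sizes = vapply(superclusters, function(s)
      sum(sizes[ids %in% s$member_clusters]), 0L),
    n_top_units = length(top),
    n_receptors_top = sum(top),
    pct_family_top = pct_int(sum(top), n_rec)
  )
}
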