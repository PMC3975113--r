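# Phylogeny from the conserved C3-D receptor domains and
# phylogeny/genome-location concordance.
#
# Distances are 1 - identity/100 over global alignments of the C3+D
# sequences; the tree is built by canonical neighbor joining (the
# conserved C3-D region plays the role of an already-curated alignment
# block, so no further column filtering is applied).

#' Pairwise distance matrix from C3-D sequences
#'
#' @param c3d_seqs named character vector of C3+D amino-acid sequences.
#' @return Symmetric numeric matrix with zero diagonal; entries
#'   `1 - identity/100` from [pairwise_identity()].
#' @export
build_distance_matrix <- function(c3d_seqs) {
  n <- length(c3d_seqs)
  ids <- names(c3d_seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(c3d_seqs[[i]], c3d_seqs[[j]]) / 100
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: at each step the pair minimising
#' Q(i, j) = (n - 2) d(i, j) - R_i - R_j is joined (ties broken by the
#' smallest (i, j) index pair in the current matrix order), branch lengths
#' follow the standard formulas, and the final three nodes are resolved in
#' closed form.  Negative branch lengths (possible on non-additive input)
#' are clamped to zero.
#'
#' @param d symmetric distance matrix with row/column names (n >= 3).
#' @return An unrooted [ape::phylo] tree whose leaves are the matrix ids.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stopf("neighbor joining needs at least 3 taxa, got %d", n)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) stopf("distance matrix must be symmetric")
  labs <- rownames(d)     # newick fragment per active node
  bl <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest (i, j), i < j, among argmins
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_lab <- sprintf("(%s:%s,%s:%s)", labs[i], bl(li), labs[j], bl(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labs <- c(labs[keep], new_lab)
    rownames(d2) <- colnames(d2) <- seq_len(m - 1)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 labs[1], bl(la), labs[2], bl(lb), labs[3], bl(lc))
  ape::read.tree(text = nwk)
}

#' Concordance between phylogenetic clades and genomic location
#'
#' Cuts the tree into `k` clades by removing the `k - 1` longest internal
#' branches and returns the adjusted Rand index between clade membership
#' and a genomic-location labelling (cluster id or chromosome) of the
#' leaves.
#'
#' @param tree an [ape::phylo] tree.
#' @param gene_locations named character vector, leaf id -> location label.
#' @param k number of clades.
#' @return List: `ari` (adjusted Rand index, in `[-1, 1]`), `clades`
#'   (named vector of clade indices per leaf).
#' @export
clade_locus_concordance <- function(tree, gene_locations, k = 4) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  lens <- tree$edge.length
  internal <- which(edges[, 2] > ntip)
  ncut <- min(k - 1, length(internal))
  cut <- internal[order(lens[internal], decreasing = TRUE)][seq_len(ncut)]
  keep <- setdiff(seq_len(nrow(edges)), cut)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[keep, 1]),
               to = as.character(edges[keep, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(max(edges))))
  )
  comp <- igraph::components(gr)$membership
  clades <- comp[as.character(seq_len(ntip))]
  names(clades) <- tree$tip.label
  common <- intersect(names(clades), names(gene_locations))
  ari <- mclust::adjustedRandIndex(clades[common], gene_locations[common])
  list(ari = ari, clades = clades)
}
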