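test_that("distance matrix is symmetric, zero-diagonal and separates planted families", {
  withr::with_seed(71, {
    f1 <- random_protein(120); f2 <- random_protein(120)
    seqs <- c(a1 = mutate_protein(f1, 0.05), a2 = mutate_protein(f1, 0.05),
              b1 = mutate_protein(f2, 0.05), b2 = mutate_protein(f2, 0.05))
    d <- build_distance_matrix(seqs)
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    within <- c(d["a1", "a2"], d["b1", "b2"])
    between <- c(d["a1", "b1"], d["a1", "b2"], d["a2", "b1"], d["a2", "b2"])
    expect_lt(max(within), min(between))
    expect_equal(build_distance_matrix(c(x = "MKLV", y = "MKLV"))["x", "y"], 0)
  })
})

test_that("neighbor joining recovers the worked 4-taxon additive example exactly", {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  # A-B form a cherry and path lengths reproduce the metric exactly
  cm <- stats::cophenetic(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cm, d, tolerance = 1e-12)
  mrca_ab <- ape::getMRCA(ape::root(tree, "D"), c("A", "B"))
  desc <- ape::extract.clade(ape::root(tree, "D"), mrca_ab)$tip.label
  expect_setequal(desc, c("A", "B"))
})

test_that("3 taxa resolve as a star with closed-form branch lengths; n < 3 errors", {
  d <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- neighbor_joining(d)
  expect_equal(length(tree$tip.label), 3)
  cm <- stats::cophenetic(tree)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(cm, d, tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on random additive matrices and agrees with an independent NJ", {
  skip_if_not_installed("phangorn")
  withr::with_seed(81, {
    for (rep in 1:20) {
      n <- sample(6:10, 1)
      ref <- ape::rtree(n)
      dm <- stats::cophenetic(ref)
      tree <- neighbor_joining(dm)
      cm <- stats::cophenetic(tree)[rownames(dm), colnames(dm)]
      expect_lt(max(abs(cm - dm)), 1e-9)
      # independent implementation recovers the same unrooted topology
      ref_nj <- ape::nj(dm)
      expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(ref_nj)), 0)
    }
  })
})

test_that("NJ topology is invariant under taxon-order permutation", {
  skip_if_not_installed("phangorn")
  withr::with_seed(91, {
    dm <- stats::cophenetic(ape::rtree(8))
    t1 <- neighbor_joining(dm)
    perm <- sample(nrow(dm))
    t2 <- neighbor_joining(dm[perm, perm])
    expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
  })
})

test_that("clade/locus concordance: perfect clades give ARI 1, random labels give ~0", {
  withr::with_seed(17, {
    f <- replicate(4, random_protein(100))
    seqs <- stats::setNames(
      unlist(lapply(1:4, function(i) replicate(3, mutate_protein(f[i], 0.04)))),
      sprintf("g%02d", 1:12))
    tree <- neighbor_joining(build_distance_matrix(seqs))
    loc <- stats::setNames(rep(paste0("L", 1:4), each = 3), names(seqs))
    conc <- clade_locus_concordance(tree, loc, k = 4)
    expect_equal(conc$ari, 1)
    expect_equal(length(unique(conc$clades)), 4)
    # random labels: ARI concentrates near zero
    aris <- vapply(1:100, function(s) {
      clade_locus_concordance(tree, stats::setNames(sample(loc), names(loc)), k = 4)$ari
    }, 0)
    expect_lt(abs(mean(aris)), 0.1)
  })
})

test_that("twin-chromosome scenario: clades follow descent; default layout follows loci", {
  gb <- make_genome(list(twin_chromosome = TRUE, n_filler = 30,
                         n_spuf_outside = 10, with_sequence = FALSE), seed = 11)
  g <- gb$genome
  anns <- annotate_proteome(g$proteins)
  c3d <- c3d_sequences(anns)
  tree <- neighbor_joining(build_distance_matrix(c3d))
  # founder-family labels: twins inherit the family of their source cluster
  fam <- stats::setNames(rep(NA_character_, length(gb$truth$receptor_ids)),
                         gb$truth$receptor_ids)
  for (pf in seq_along(gb$truth$paralog_families)) {
    mem <- gb$truth$paralog_families[[pf]]$members
    root_fam <- sub("_t$", "", mem[1])
    fam[mem] <- sub("_[0-9]+$", "", root_fam)
  }
  fam[is.na(fam)] <- names(fam)[is.na(fam)]
  conc <- clade_locus_concordance(tree, fam[names(c3d)], k = 5)
  expect_gte(conc$ari, 0.8)
  # no-twin default: clades align with genomic clusters
  gb2 <- make_genome(small_params(), seed = 7)
  anns2 <- annotate_proteome(gb2$genome$proteins)
  c3d2 <- c3d_sequences(anns2)
  rec2 <- gb2$genome$genes[gb2$genome$genes$gene_id %in% gb2$truth$receptor_ids, ]
  cc2 <- call_clusters(rec2)
  loc2 <- stats::setNames(rep("single", length(gb2$truth$receptor_ids)),
                          gb2$truth$receptor_ids)
  for (cl in cc2$clusters) loc2[cl$members] <- cl$cluster_id
  conc2 <- clade_locus_concordance(neighbor_joining(build_distance_matrix(c3d2)),
                                   loc2[names(c3d2)], k = 4)
  expect_gte(conc2$ari, 0.8)
})
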