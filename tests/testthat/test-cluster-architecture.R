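test_that("cluster gap boundary is inclusive at 50 kb", {
  # three receptors with boundary gaps 10 kb and 49 kb: one cluster of 3
  g <- toy_genes(c("r1", "r2", "r3"), "c1",
                 c(0, 11000, 61000), c(1000, 12000, 62000))
  cc <- call_clusters(g)  # gaps: 10000, 49000
  expect_equal(length(cc$clusters), 1)
  expect_equal(cc$clusters[[1]]$members, c("r1", "r2", "r3"))
  # gap of exactly 50 kb still chains; 51 kb does not
  g2 <- toy_genes(c("r1", "r2", "r3"), "c1",
                  c(0, 51000, 113000), c(1000, 52000, 114000))
  cc2 <- call_clusters(g2)  # gaps: 50000, 61000
  expect_equal(length(cc2$clusters), 1)
  expect_equal(cc2$clusters[[1]]$members, c("r1", "r2"))
  expect_equal(cc2$singletons, "r3")
})

test_that("super-cluster gap is strictly below 2 Mb", {
  mk_cl <- function(id, start, end) list(cluster_id = id, chrom = "c1",
                                         members = c("a", "b"), span = c(start, end))
  near <- list(mk_cl("C1", 0, 100000), mk_cl("C2", 1600000, 1700000))
  expect_equal(length(call_superclusters(near)), 1)
  exact <- list(mk_cl("C1", 0, 100000), mk_cl("C2", 2100000, 2200000))
  expect_equal(length(call_superclusters(exact)), 0)   # gap exactly 2 Mb
  just_in <- list(mk_cl("C1", 0, 100000), mk_cl("C2", 2099999, 2200000))
  expect_equal(length(call_superclusters(just_in)), 1)
})

test_that("cluster calling equals the brute-force transitive closure on random layouts", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      lay <- random_layout(n_genes = sample(5:25, 1), n_chrom = sample(1:3, 1))
      cc <- call_clusters(lay, cluster_gap_max = 50000)
      got <- canon_members(lapply(cc$clusters, `[[`, "members"))
      want <- canon_members(brute_cluster_membership(lay, 50000))
      expect_equal(got, want, info = paste("layout", rep))
      # partition property: every receptor in exactly one cluster or singleton
      all_ids <- c(unlist(lapply(cc$clusters, `[[`, "members")), cc$singletons)
      expect_setequal(all_ids, lay$gene_id)
      expect_equal(anyDuplicated(all_ids), 0)
    }
  })
})

test_that("cluster calling is invariant to input order", {
  withr::with_seed(7, {
    lay <- random_layout(n_genes = 15)
    a <- call_clusters(lay)
    b <- call_clusters(lay[sample(nrow(lay)), ])
    expect_equal(a, b)
  })
})

test_that("association window boundaries behave to the base pair", {
  # receptor at [100000, 101000); window 25 kb
  genes <- toy_genes(c("rec", "g_in", "g_out", "g_touch"), "c1",
                     c(100000, 74500, 74000, 126000),
                     c(101000, 75001, 74999, 127000))
  gn <- toy_genome(genes)
  # g_in ends 24999 bp before the receptor start -> overlaps padded window
  # g_out ends exactly 25001 bp before -> no overlap
  # g_touch starts exactly at receptor end + 25000 -> half-open, excluded
  assoc <- collect_associated(gn, "rec", window = 25000)
  expect_setequal(assoc$union, "g_in")
  assoc2 <- collect_associated(gn, "rec", window = 25002)
  expect_setequal(assoc2$union, c("g_in", "g_out", "g_touch"))
  expect_error(collect_associated(gn, "rec", window = -1), "window")
})

test_that("association equals the all-pairs brute-force overlap on random layouts", {
  withr::with_seed(202, {
    for (rep in 1:30) {
      lay <- random_layout(n_genes = sample(10:30, 1), n_chrom = 2)
      rec_ids <- sample(lay$gene_id, sample(2:4, 1))
      gn <- toy_genome(lay)
      got <- collect_associated(gn, rec_ids, window = 25000)
      expect_equal(got$union, brute_associated(lay, rec_ids, 25000))
      # receptors never appear in association lists
      expect_false(any(rec_ids %in% got$union))
      # per-receptor lists with multiplicity cover at least the union
      expect_gte(sum(vapply(got$per_receptor, nrow, 0L)), length(got$union))
    }
  })
})

test_that("signed distances are zero on overlap, negative upstream, positive downstream", {
  genes <- toy_genes(c("rec", "up", "down", "ov"), "c1",
                     c(50000, 40000, 62000, 50500),
                     c(51000, 41000, 63000, 52000))
  assoc <- collect_associated(toy_genome(genes), "rec", window = 25000)
  d <- assoc$per_receptor$rec
  expect_equal(d$distance[d$gene_id == "up"], 41000 - 50000)
  expect_equal(d$distance[d$gene_id == "down"], 62000 - 51000)
  expect_equal(d$distance[d$gene_id == "ov"], 0)
})

test_that("architecture summary counts members and top units correctly", {
  gb <- make_genome(small_params(), seed = 12)
  rec <- gb$genome$genes[gb$genome$genes$gene_id %in% gb$truth$receptor_ids, ]
  cc <- call_clusters(rec)
  scs <- call_superclusters(cc$clusters)
  s <- summarize_architecture(cc, scs, gb$truth$receptor_ids, k = 9)
  truth_sizes <- sort(vapply(gb$truth$clusters, function(tc) length(tc$members), 0L))
  expect_equal(sort(s$cluster_sizes), truth_sizes)
  expect_equal(s$n_clustered, sum(truth_sizes))
  expect_equal(s$n_receptors, length(gb$truth$receptor_ids))
  expect_equal(s$pct_clustered, round(100 * sum(truth_sizes) / s$n_receptors))
  # zero clusters: percentages are 0, no division error
  empty <- summarize_architecture(list(clusters = list(), singletons = "r1"),
                                  list(), "r1", k = 9)
  expect_equal(empty$pct_clustered, 0)
  expect_equal(empty$pct_family_top, 0)
})
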