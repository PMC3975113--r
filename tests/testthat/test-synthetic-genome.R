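test_that("receptor proteins carry the constructed repeat count", {
  p0 <- make_receptor_protein(17, seed = 11, p_sub = 0)
  expect_equal(length(scan_lrr_repeats(p0)), 17)
  # receptor verdict holds for most noisy constructions
  ok <- vapply(1:20, function(s)
    annotate_receptor("x", make_receptor_protein(17, seed = s))$is_lrr_rlp, TRUE)
  expect_gte(sum(ok), 19)
})

test_that("planted layouts appear in the truth as specified", {
  one <- make_genome(small_params(
    chromosomes = c(chrA = 2e5),
    clusters = list(list(chrom = "chrA", start = 10000, n_receptors = 4, gap = 10000)),
    singletons = list(), n_filler = 5, n_spuf_outside = 2
  ), seed = 2)
  expect_equal(length(one$truth$clusters), 1)
  expect_equal(length(one$truth$clusters[[1]]$members), 4)
  expect_equal(length(one$truth$superclusters), 0)
  # two clusters 1.5 Mb apart form one planted super-cluster
  two <- make_genome(small_params(
    chromosomes = c(chrA = 4e6),
    clusters = list(
      list(chrom = "chrA", start = 100000, n_receptors = 3, gap = 10000),
      list(chrom = "chrA", start = 1650000, n_receptors = 3, gap = 10000)
    ),
    singletons = list(), n_filler = 5, n_spuf_outside = 2
  ), seed = 2)
  expect_equal(length(two$truth$superclusters), 1)
  expect_equal(two$truth$superclusters[[1]], c(1, 2))
})

test_that("generation is deterministic given the seed", {
  a <- make_genome(small_params(), seed = 9)
  b <- make_genome(small_params(), seed = 9)
  expect_identical(a$genome$genes, b$genome$genes)
  expect_identical(a$genome$proteins, b$genome$proteins)
  expect_identical(a$truth[names(a$truth) != "params"], b$truth[names(b$truth) != "params"])
  c <- make_genome(small_params(), seed = 10)
  expect_false(identical(a$genome$genes, c$genome$genes))
})

test_that("planted intra-cluster gaps are exact and ids exist in the genome", {
  gb <- make_genome(small_params(), seed = 4)
  g <- gb$genome$genes
  for (tc in gb$truth$clusters) {
    rows <- g[match(tc$members, g$gene_id), ]
    expect_false(anyNA(rows$start))
    gaps <- rows$start[-1] - rows$end[-nrow(rows)]
    expect_true(all(gaps == tc$gap))
  }
  expect_true(all(gb$truth$spuf_ids %in% g$gene_id))
  expect_true(all(gb$truth$secreted_ids %in% gb$truth$spuf_ids))
})

test_that("overfull layouts raise a placement error", {
  expect_error(make_genome(small_params(
    chromosomes = c(chrA = 40000),
    clusters = list(list(chrom = "chrA", start = 10000, n_receptors = 6, gap = 10000)),
    singletons = list(), n_filler = 0, n_spuf_outside = 0
  ), seed = 1), "placement overflow|does not fit")
})

test_that("expression fold changes reproduce the planted induction", {
  tr <- expression_truth(n_genes = 50, inductions = c(gene_01 = 10))
  ex0 <- make_expression(tr, noise_sd = 0, seed = 5)
  res0 <- summarize_expression(ex0$nonwounded, ex0$wounded, pseudocount = 0)
  expect_equal(res0$fold_change[res0$gene_id == "gene_01"], 10)
  expect_true(all(res0$fold_change[res0$gene_id != "gene_01"] == 1))
  # FC invariance under a global scale factor (pseudocount -> 0)
  resk <- summarize_expression(ex0$nonwounded * 7, ex0$wounded * 7, pseudocount = 0)
  expect_equal(resk$fold_change, res0$fold_change)
})

test_that("noisy fold-change estimates are unbiased and nulls stay quiet", {
  tr <- expression_truth(n_genes = 40, inductions = c(gene_01 = 10))
  fcs <- vapply(1:60, function(s) {
    ex <- make_expression(tr, noise_sd = 0.2, seed = s)
    mean(ex$wounded["gene_01", ]) / mean(ex$nonwounded["gene_01", ])
  }, 0)
  expect_gte(mean(fcs), 9)
  expect_lte(mean(fcs), 11)
  ex <- make_expression(expression_truth(n_genes = 200, inductions = NULL),
                        noise_sd = 0.1, seed = 77)
  lfc <- log2(rowMeans(ex$wounded) / rowMeans(ex$nonwounded))
  expect_gte(mean(abs(lfc) < 0.5), 0.95)
})

test_that("the synthetic bundle round-trips through its files", {
  gb <- make_genome(small_params(n_filler = 8, n_spuf_outside = 3), seed = 6)
  ex <- make_expression(gb$truth, seed = 6)
  outdir <- withr::local_tempdir()
  write_synthetic_bundle(gb$genome, gb$truth, ex, outdir)
  g2 <- read_gff3(file.path(outdir, "genome.gff3"))
  expect_equal(g2$genes, gb$genome$genes)
  prot <- read_fasta(file.path(outdir, "proteins.fasta"))
  expect_identical(prot[names(gb$genome$proteins)], gb$genome$proteins)
  expect_equal(read_expression(file.path(outdir, "expression_wounded.tsv")),
               ex$wounded)
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"))
  expect_setequal(unlist(truth$spuf_ids), gb$truth$spuf_ids)
})
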