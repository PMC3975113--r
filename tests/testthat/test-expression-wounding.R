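mk_mat <- function(means, n_cond = 6, prefix = "c") {
  m <- matrix(rep(means, n_cond), length(means), n_cond,
              dimnames = list(names(means), paste0(prefix, seq_len(n_cond))))
  m
}

test_that("categories, fold change and induction bands follow the step rules", {
  nw <- mk_mat(c(g_bg = 100, g_low = 500, g_hi = 5000, g_vhi = 12000, g_risp = 500))
  w <- mk_mat(c(g_bg = 100, g_low = 500, g_hi = 5000, g_vhi = 12000, g_risp = 5000))
  res <- summarize_expression(nw, w, background = 200, pseudocount = 0)
  expect_equal(res$category[match(c("g_bg", "g_low", "g_hi", "g_vhi"), res$gene_id)],
               c("below_background", "low_medium", "higher", "very_high"))
  expect_equal(res$expressed[res$gene_id == "g_bg"], FALSE)
  # planted ~10-fold induction is called strong
  risp <- res[res$gene_id == "g_risp", ]
  expect_equal(risp$fold_change, 10)
  expect_equal(risp$induction, "strong")
  # identical matrices: FC 1, induction none
  same <- summarize_expression(nw, nw, pseudocount = 0)
  expect_true(all(same$fold_change == 1))
  expect_true(all(same$induction == "none"))
  # 1.8-fold sits in the slight band; boundaries 1.5 and 5 are inclusive below
  w2 <- mk_mat(c(g = 1800)); nw2 <- mk_mat(c(g = 1000))
  expect_equal(summarize_expression(nw2, w2, pseudocount = 0)$induction, "slight")
  expect_equal(summarize_expression(mk_mat(c(g = 1000)), mk_mat(c(g = 1500)),
                                    pseudocount = 0)$induction, "slight")
  expect_equal(summarize_expression(mk_mat(c(g = 1000)), mk_mat(c(g = 5000)),
                                    pseudocount = 0)$induction, "strong")
  expect_error(summarize_expression(nw, w[, 1:3]), "mismatch")
})

test_that("category is a monotone step function of the larger mean", {
  means <- seq(50, 15000, by = 475)
  res <- summarize_expression(mk_mat(stats::setNames(means, paste0("g", seq_along(means)))),
                              mk_mat(stats::setNames(means, paste0("g", seq_along(means)))),
                              pseudocount = 0)
  lev <- c(below_background = 0, low_medium = 1, higher = 2, very_high = 3)
  expect_true(all(diff(lev[res$category]) >= 0))
})

test_that("OLS regression matches the closed-form fit on a fixed 10-point set", {
  x <- c(120, 340, 560, 800, 1500, 2300, 3100, 4200, 5100, 6400)
  y <- c(180, 300, 700, 850, 1400, 2600, 3000, 4600, 5000, 6900)
  res <- data.frame(gene_id = paste0("g", 1:10), mean_nonwounded = x, mean_wounded = y)
  fit <- regression_wounded_vs_nonwounded(res)
  # closed form from raw sums
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx; intercept <- mean(y) - slope * mean(x)
  r2 <- (sxy / sqrt(sxx * sum((y - mean(y))^2)))^2
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  # y = x exactly -> slope 1, r2 1; constant y -> slope 0
  res2 <- data.frame(gene_id = paste0("g", 1:10), mean_nonwounded = x, mean_wounded = x)
  fit2 <- regression_wounded_vs_nonwounded(res2)
  expect_equal(fit2$slope, 1); expect_equal(fit2$r_squared, 1)
  res3 <- data.frame(gene_id = paste0("g", 1:10), mean_nonwounded = x,
                     mean_wounded = rep(7, 10))
  expect_equal(regression_wounded_vs_nonwounded(res3)$slope, 0)
})

test_that("co-expressed receptor/SPUF pairs require both genes above background", {
  gb <- make_genome(small_params(), seed = 7)
  tr <- gb$truth
  ex <- make_expression(tr, noise_sd = 0, seed = 7)
  res <- summarize_expression(ex$nonwounded, ex$wounded)
  rec <- gb$genome$genes[gb$genome$genes$gene_id %in% tr$receptor_ids, ]
  cc <- call_clusters(rec)
  assoc <- collect_associated(gb$genome, tr$receptor_ids)
  pairs <- coexpressed_pairs(cc$clusters, assoc, res, tr$spuf_ids,
                             mat_nw = ex$nonwounded, mat_w = ex$wounded)
  # the co-induced cluster contributes pairs; every pair is above background
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$mean_receptor > 200 & pairs$mean_spuf > 200))
  expect_true(all(pairs$receptor_id %in% tr$receptor_ids))
  expect_true(all(pairs$spuf_id %in% tr$spuf_ids))
  # silencing the SPUF partner removes its pairs
  res_off <- res
  res_off$mean_nonwounded[res_off$gene_id %in% tr$spuf_ids] <- 0
  res_off$mean_wounded[res_off$gene_id %in% tr$spuf_ids] <- 0
  expect_equal(nrow(coexpressed_pairs(cc$clusters, assoc, res_off, tr$spuf_ids)), 0)
})

test_that("planted co-induced pairs are strongly correlated across conditions", {
  gb <- make_genome(small_params(), seed = 7)
  tr <- gb$truth
  pair <- c(tr$coinduced[1], grep("^SPUF_", tr$coinduced, value = TRUE)[1])
  cors <- vapply(1:60, function(s) {
    ex <- make_expression(tr, noise_sd = 0.1, seed = s)
    prof <- cbind(ex$nonwounded, ex$wounded)
    stats::cor(prof[pair[1], ], prof[pair[2], ])
  }, 0)
  expect_gte(mean(cors >= 0.8), 0.9)
})
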