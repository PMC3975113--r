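test_that("noiseless generator receptors are fully segmented and called", {
  p <- make_receptor_protein(17, seed = 1, p_sub = 0)
  ann <- annotate_receptor("g1", p)
  expect_equal(length(ann$lrr_repeats), 17)
  expect_false(is.null(ann$signal_peptide))
  expect_lte(ann$signal_peptide[2], 28)
  expect_false(is.null(ann$tm))
  expect_true(all(c("A", "B", "C1", "C2", "C3", "D", "F", "G") %in% names(ann$domains)))
  expect_true(ann$is_lrr_rlp)
  # C3+D is a contiguous substring pair of the input
  c3 <- ann$domains$C3; d <- ann$domains$D
  expect_equal(ann$c3d_seq,
               paste0(substr(p, c3[1] + 1, c3[2]), substr(p, d[1] + 1, d[2])))
})

test_that("domain intervals tile the sequence without overlap across seeds", {
  for (s in 1:25) {
    p <- make_receptor_protein(sample(16:26, 1), seed = s, p_sub = 0)
    ann <- annotate_receptor(paste0("g", s), p)
    iv <- do.call(rbind, ann$domains)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    expect_true(all(iv[-1, 1] == iv[-nrow(iv), 2]), info = paste("seed", s))
    expect_equal(iv[1, 1], 0, ignore_attr = TRUE)
    expect_equal(unname(iv[nrow(iv), 2]), nchar(p))
  }
})

test_that("signal-peptide heuristic: found on generator constructs, absent without a core", {
  expect_null(detect_signal_peptide(paste(rep("D", 50), collapse = "")))
  expect_null(detect_signal_peptide("MKAL"))  # below length 30: absent, no error
  found <- vapply(1:100, function(s) {
    p <- make_receptor_protein(16, seed = s)
    !is.null(detect_signal_peptide(p))
  }, TRUE)
  expect_gte(mean(found), 0.95)
})

test_that("LRR scan: exact copies all found, noisy copies mostly found, null almost never fires", {
  consensus_inst <- function() {
    # consensus with wildcards drawn from background
    v <- strsplit("LxxLxxLxLxxNxLSGxIPxxLGx", "")[[1]]
    v[v == "x"] <- strsplit(random_protein(sum(v == "x")), "")[[1]]
    paste(v, collapse = "")
  }
  withr::with_seed(42, {
    seq17 <- paste(replicate(17, consensus_inst()), collapse = "")
    reps <- scan_lrr_repeats(seq17)
    expect_equal(length(reps), 17)
    expect_equal(reps[[1]], c(0, 24), ignore_attr = TRUE)
    # noisy copies: >= 16/17 detected in >= 90% of seeds
    hits <- vapply(1:40, function(s) {
      p <- make_receptor_protein(17, seed = s, p_sub = 0.15)
      ann <- annotate_receptor("x", p)
      length(ann$lrr_repeats)
    }, 0L)
    expect_gte(mean(hits >= 16), 0.9)
    # null: <= 1 spurious repeat in >= 95% of random proteins
    fp <- vapply(1:100, function(s) length(scan_lrr_repeats(random_protein(500))), 0L)
    expect_gte(mean(fp <= 1), 0.95)
  })
})

test_that("TM detection matches a brute-force window mean and respects its threshold", {
  p <- make_receptor_protein(17, seed = 5, p_sub = 0)
  tm <- detect_tm(p)
  expect_false(is.null(tm))
  # brute force over every window in the C-terminal 40%
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  v <- kd[strsplit(p, "")[[1]]]
  n <- length(v); w <- 19
  from <- floor(0.6 * n) + 1
  means <- vapply(from:(n - w + 1), function(i) mean(v[i:(i + w - 1)]), 0)
  best <- which.max(means) + from - 1
  expect_equal(tm[1], best - 1)
  expect_gte(means[best - from + 1], 1.6)
  expect_null(detect_tm(paste(rep("E", 200), collapse = "")))
})

test_that("receptor verdict applies the strict >15 LRR rule and the tail bound", {
  expect_false(annotate_receptor("low", make_receptor_protein(5, seed = 2, p_sub = 0))$is_lrr_rlp)
  p15 <- make_receptor_protein(15, seed = 3, p_sub = 0)
  ann15 <- annotate_receptor("b15", p15)
  expect_equal(length(ann15$lrr_repeats), 15)
  expect_false(ann15$is_lrr_rlp)   # boundary: exactly 15 is not "more than 15"
  p16 <- make_receptor_protein(16, seed = 3, p_sub = 0)
  expect_true(annotate_receptor("b16", p16)$is_lrr_rlp)
  # kinase-sized tail disqualifies
  long_tail <- paste0(make_receptor_protein(17, seed = 4, p_sub = 0), random_protein(300))
  ann_lt <- annotate_receptor("lt", long_tail)
  expect_false(ann_lt$is_lrr_rlp)
  # verdict is monotone in detected repeat count (other domains equal)
  mk <- function(n) {
    a <- annotate_receptor("m", make_receptor_protein(n, seed = 9, p_sub = 0))
    c(length(a$lrr_repeats), a$is_lrr_rlp)
  }
  res <- vapply(14:18, mk, c(0, 0))
  expect_true(all(diff(res[1, ]) >= 0))
  expect_true(all(res[2, ][res[1, ] > 15] == 1))
  expect_true(all(res[2, ][res[1, ] <= 15] == 0))
})

test_that("shipped PWM file matches the in-code construction", {
  shipped <- default_lrr_profile()
  expect_equal(dim(shipped), c(20, 24))
  expect_equal(colnames(shipped), as.character(1:24))
  built <- rlparch:::build_lrr_profile()
  expect_equal(unname(shipped), unname(built), tolerance = 1e-4)
})
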