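test_that("average reference removes the instantaneous across-channel mean", {
  rec <- ieeg_record(matrix(c(1, 2, 3), nrow = 3, ncol = 50), fs = 10)
  out <- average_reference(rec)
  expect_equal(out$samples, matrix(c(-1, 0, 1), nrow = 3, ncol = 50))

  v <- rnorm(100)
  same <- ieeg_record(matrix(v, nrow = 4, ncol = 100, byrow = TRUE), fs = 10)
  expect_equal(max(abs(average_reference(same)$samples)), 0)

  set.seed(5)
  r <- ieeg_record(matrix(rnorm(400), nrow = 4), fs = 10)
  expect_lt(max(abs(colMeans(average_reference(r)$samples))), 1e-12)

  expect_error(average_reference(ieeg_record(matrix(0, 1, 100), fs = 10)),
               "at least 2 channels")
})

test_that("block partitioning drops the trailing partial block and demands fully valid samples", {
  rec <- ieeg_record(matrix(0, 2, 600 * 400), fs = 400)
  expect_equal(nrow(partition_blocks(rec, 60)), 10L)

  rec2 <- ieeg_record(matrix(0, 2, 630 * 400), fs = 400)
  b <- partition_blocks(rec2, 60)
  expect_equal(nrow(b), 10L)
  expect_equal(b$block_start_s, seq(0, 540, by = 60))

  valid <- rep(TRUE, 600 * 400)
  valid[2 * 60 * 400 + 77] <- FALSE  # one sample inside block 3
  rec3 <- ieeg_record(matrix(0, 2, 600 * 400), fs = 400, valid_mask = valid)
  b3 <- partition_blocks(rec3, 60)
  expect_identical(b3$valid, c(TRUE, TRUE, FALSE, rep(TRUE, 7)))
})

test_that("band powers match closed-form sinusoid variances", {
  fs <- 400; n <- 60 * fs
  t <- (0:(n - 1)) / fs
  expect_equal(unname(compute_pib(numeric(n), fs)), rep(0, 6))

  # unit 10 Hz sinusoid: all power in alpha, equal to its variance 1/2
  p <- compute_pib(sin(2 * pi * 10 * t), fs)
  expect_gt(p[["alpha"]] / sum(p), 0.99)
  expect_equal(p[["alpha"]], 0.5, tolerance = 1e-9)

  # one bin-aligned sinusoid per band: PIB_b = amplitude_b^2 / 2 exactly
  amp <- c(3, 2, 1.5, 1, 0.8, 0.5)
  freqs <- c(2, 6, 10, 20, 50, 100)
  x <- drop(vapply(freqs, function(f) sin(2 * pi * f * t), numeric(n)) %*% amp)
  p6 <- compute_pib(x, fs)
  expect_equal(unname(p6), amp^2 / 2, tolerance = 1e-9)
})

test_that("white-noise band powers are proportional to bandwidth and conserve variance", {
  fs <- 400; n <- 60 * fs
  set.seed(7)
  props <- replicate(8, {
    p <- compute_pib(rnorm(n), fs)
    p / sum(p)
  })
  bw <- with(band_definitions(), hi_hz - lo_hz) / 179.9
  expect_equal(rowMeans(props), bw, tolerance = 0.02, ignore_attr = TRUE)

  # Parseval: total band power never exceeds block variance, and equals the
  # 0.1-180 Hz bin sum computed independently
  x <- rnorm(n)
  p <- compute_pib(x, fs)
  xc <- x - mean(x)
  bins <- Mod(fft(xc))^2 / n^2
  f <- (seq_len(n %/% 2)) * fs / n
  fold <- c(rep(2, n %/% 2 - 1), 1)
  binsum <- sum((bins[2:(n %/% 2 + 1)] * fold)[f >= 0.1 & f < 180])
  expect_equal(sum(p), binsum, tolerance = 1e-9)
  expect_lte(sum(p), sum(xc^2) / n + 1e-12)

  # mean removal: constant offsets do not change any band power
  expect_equal(compute_pib(x + 1e4, fs), p, tolerance = 1e-6)
})

test_that("invalid blocks are refused by compute_pib", {
  x <- rnorm(1000); x[5] <- NA
  expect_error(compute_pib(x, 400), "invalid")
})

test_that("extract_features yields a channels-x-bands matrix consistent with compute_pib", {
  set.seed(9)
  n_s <- 10 * 60 * 400
  rec <- ieeg_record(matrix(rnorm(4 * n_s, sd = 20), nrow = 4), fs = 400)
  cfg <- run_config()
  fm <- extract_features(rec, cfg)
  expect_equal(dim(fm$X), c(10L, 24L))
  expect_equal(colnames(fm$X)[1:7],
               c(paste0("ch1_", band_definitions()$name), "ch2_delta"))

  # vectorized path agrees with the per-block reference implementation
  ref <- average_reference(rec)
  blk <- ref$samples[3, (2 * 60 * 400 + 1):(3 * 60 * 400)]
  expect_equal(unname(fm$X[3, 13:18]), unname(compute_pib(blk, 400)),
               tolerance = 1e-10)

  # invalid blocks carry NA rows and are flagged
  valid <- rep(TRUE, n_s); valid[1:(60 * 400)] <- FALSE
  valid[(5 * 60 * 400) + 1] <- FALSE
  rec2 <- ieeg_record(rec$samples, fs = 400, valid_mask = valid)
  fm2 <- extract_features(rec2, cfg)
  expect_equal(sum(fm2$valid), 8L)
  expect_true(all(is.na(fm2$X[1, ])))
  expect_true(all(!is.na(fm2$X[fm2$valid, ])))
})

test_that("a 16-channel record yields the canonical 96-feature vector", {
  set.seed(10)
  rec <- ieeg_record(matrix(rnorm(16 * 2 * 60 * 100), nrow = 16), fs = 100)
  fm <- extract_features(rec, run_config())
  expect_equal(ncol(fm$X), 96L)
  expect_equal(nrow(fm$X), 2L)
})

test_that("doubling one channel changes its own powers fourfold up to the reference shift", {
  set.seed(12)
  n_s <- 4 * 60 * 200
  base <- matrix(rnorm(8 * n_s, sd = 10), nrow = 8)
  rec1 <- ieeg_record(base, fs = 200)
  mod <- base; mod[2, ] <- 2 * mod[2, ]
  rec2 <- ieeg_record(mod, fs = 200)
  f1 <- extract_features(rec1, run_config())
  f2 <- extract_features(rec2, run_config())
  # oracle: recompute from the average-referenced signals directly
  r2 <- average_reference(rec2)
  blk <- r2$samples[2, 1:(60 * 200)]
  expect_equal(unname(f2$X[1, 7:12]),
               unname(suppressWarnings(compute_pib(blk, 200))),
               tolerance = 1e-10)
  # with 8 independent channels the reference shift is small: ratio near 4
  ratio <- f2$X[, 7:12] / f1$X[, 7:12]
  expect_true(all(ratio > 2.5 & ratio < 6))
})

test_that("feature tables round trip through the long CSV format", {
  fm <- make_fm(6, n_ch = 2, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  fm$label <- c("interictal", "preictal", NA, "interictal", "preictal",
                "ictal_excluded")
  fm$fold <- c(1L, 1L, NA, 2L, 2L, 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, path)
  back <- read_feature_table(path, block_len = 60)
  vb <- which(fm$valid)
  expect_equal(back$block_start_s, fm$block_start_s[vb])
  expect_equal(back$X, fm$X[vb, ], tolerance = 1e-12)
  expect_equal(back$label, fm$label[vb])
  expect_equal(back$fold, fm$fold[vb])
})
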