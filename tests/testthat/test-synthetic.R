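test_that("seizure-time simulation is seed-deterministic and respects the rate", {
  sp <- sim_params(duration_s = 30 * 86400, lead_rate = 0.3, seed = 51)
  a <- simulate_seizure_times(sp)
  b <- simulate_seizure_times(sp)
  expect_identical(a, b)

  expect_equal(nrow(simulate_seizure_times(
    sim_params(duration_s = 10 * 86400, lead_rate = 0, seed = 1))), 0L)
})

test_that("total seizure counts match the cluster-process expectation", {
  # E[count] ~= lead_rate * days * mean cluster size, up to edge truncation
  sp <- sim_params(duration_s = 30 * 86400, lead_rate = 0.5,
                   cluster_size_mean = 3, intra_gap_median_s = 1800)
  set.seed(52)
  counts <- replicate(200, nrow(simulate_seizure_times(sp)))
  expected <- 0.5 * 30 * 3
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.05 * expected)
})

test_that("the default regime reproduces a months-long clustered record", {
  # ~5 clusters over 197 days with mean size 5.4 -> counts centered near 27
  set.seed(53)
  counts <- replicate(150, nrow(simulate_seizure_times(sim_params())))
  expect_lt(abs(mean(counts) - 27), 5)
  expect_gt(sd(counts), 5)  # clustering makes counts overdispersed vs Poisson
})

test_that("feature-level simulation honors the null and the stated effect size", {
  # effect = 1 everywhere: pre-ictal and inter-ictal blocks identically
  # distributed (no rejection excess at alpha = 0.01)
  set.seed(54)
  rejections <- 0L
  for (s in 1:10) {
    sp <- sim_params(duration_s = 3000 * 60, n_channels = 1L, lead_rate = 3,
                     cluster_size_mean = 2, gap_fraction = 0, seed = s)
    catalog <- simulate_seizure_times(sp)
    fm <- simulate_pib_features(3000, catalog, sp)
    pre <- fm$label == "preictal"
    int <- fm$label == "interictal"
    if (sum(pre, na.rm = TRUE) < 30) next
    p <- t.test(log10(fm$X[which(pre), 3]), log10(fm$X[which(int), 3]))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)

  # effect = 4 on one band shifts that log-mean by log10(4) within CI
  sp <- sim_params(duration_s = 5000 * 60, n_channels = 2L, lead_rate = 4,
                   cluster_size_mean = 2, gap_fraction = 0,
                   effect = c(ch1_alpha = 4), seed = 55)
  catalog <- simulate_seizure_times(sp)
  fm <- simulate_pib_features(5000, catalog, sp)
  pre <- which(fm$label == "preictal")
  int <- which(fm$label == "interictal")
  d <- mean(log10(fm$X[pre, "ch1_alpha"])) - mean(log10(fm$X[int, "ch1_alpha"]))
  se <- 0.4 * sqrt(1 / length(pre) + 1 / length(int))
  expect_lt(abs(d - log10(4)), 4 * se)
  # untouched features stay centered
  d2 <- mean(log10(fm$X[pre, "ch2_beta"])) - mean(log10(fm$X[int, "ch2_beta"]))
  expect_lt(abs(d2), 4 * se)
})

test_that("feature-level simulation validates inputs and handles empties", {
  expect_equal(nrow(simulate_pib_features(0, seizure_catalog(),
                                          sim_params(n_channels = 2L))$X), 0L)
  expect_error(simulate_pib_features(
    10, seizure_catalog(),
    sim_params(n_channels = 1L, effect = c(ch9_alpha = 2))),
    "not among simulated features")
})

test_that("invalid-gap placement hits the requested fraction as runs", {
  sp <- sim_params(duration_s = 5000 * 60, n_channels = 1L,
                   gap_fraction = 0.2, seed = 56)
  fm <- simulate_pib_features(5000, seizure_catalog(), sp)
  expect_lt(abs(mean(!fm$valid) - 0.2), 0.01)
  runs <- rle(fm$valid)
  expect_lt(sum(!runs$values), 100)  # gaps come as runs, not scattered blocks
})

test_that("raw synthesis produces the configured spectra, gaps, and pre-ictal gain", {
  # white noise (alpha = 0, no oscillations): band power ~ bandwidth
  sp <- sim_params(duration_s = 600, n_channels = 2L, fs = 200,
                   noise_alpha = 0, gap_fraction = 0, seed = 57)
  rec <- simulate_raw_ieeg(seizure_catalog(), sp)
  fm <- extract_features(rec, run_config())
  props <- colMeans(fm$X[, 1:6]) / sum(colMeans(fm$X[, 1:6]))
  bw <- with(band_definitions(), pmin(hi_hz, 100) - lo_hz)
  bw <- pmax(bw, 0) / sum(pmax(bw, 0))
  expect_equal(unname(props), bw, tolerance = 0.05)

  # gap fraction lands where asked
  sp2 <- sim_params(duration_s = 1200, n_channels = 2L, fs = 100,
                    gap_fraction = 0.2, gap_mean_len_s = 30, seed = 58)
  rec2 <- simulate_raw_ieeg(seizure_catalog(), sp2)
  expect_lt(abs(mean(!rec2$valid_mask) - 0.2), 0.01)

  # effect 4 on alpha scales the 10 Hz oscillation power ~4x pre-ictally
  osc <- data.frame(channel = c(1, 2), freq_hz = c(10, 10), amplitude = c(40, 40))
  sp3 <- sim_params(duration_s = 1800, n_channels = 2L, fs = 200,
                    noise_sd = 10, oscillations = osc, gap_fraction = 0,
                    preictal_len_s = 600, effect = c(ch1_alpha = 4),
                    seed = 59)
  cat3 <- seizure_catalog(1500, 1560)
  rec3 <- simulate_raw_ieeg(cat3, sp3)
  # oracle: per-channel band power on the raw signal, block by block
  blocks <- partition_blocks(rec3, 60)
  pib_ch <- function(ch) t(vapply(seq_len(nrow(blocks)), function(k) {
    idx <- blocks$first_sample[k]:(blocks$first_sample[k] + 60 * 200 - 1)
    suppressWarnings(compute_pib(rec3$samples[ch, idx], 200))
  }, numeric(6)))
  lab <- brute_labels(blocks$block_start_s, 60, cat3, 600)
  pre <- lab == "preictal"; int <- lab == "interictal"
  p1 <- pib_ch(1); p2 <- pib_ch(2)
  ratio <- mean(p1[pre, "alpha"]) / mean(p1[int, "alpha"])
  expect_lt(abs(ratio - 4), 0.8)
  ratio2 <- mean(p2[pre, "alpha"]) / mean(p2[int, "alpha"])
  expect_lt(abs(ratio2 - 1), 0.3)

  # memory budget guard advises the feature-level path
  expect_error(simulate_raw_ieeg(seizure_catalog(),
                                 sim_params(duration_s = 86400 * 30)),
               "simulate_pib_features")
})

test_that("identical seeds give bit-identical features", {
  sp <- sim_params(duration_s = 500 * 60, n_channels = 2L, seed = 60)
  cat1 <- simulate_seizure_times(sp)
  f1 <- simulate_pib_features(500, cat1, sp)
  f2 <- simulate_pib_features(500, cat1, sp)
  expect_identical(f1$X, f2$X)
  expect_identical(f1$valid, f2$valid)
})
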