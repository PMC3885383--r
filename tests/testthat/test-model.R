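test_that("the penalized fit matches glm at negligible penalty", {
  set.seed(31)
  X <- matrix(rnorm(400 * 3), 400, 3)
  y <- rbinom(400, 1, plogis(drop(X %*% c(1, -0.7, 0.2))))
  fit <- fit_logistic(X, y, ridge = 0)
  ref <- stats::glm.fit(cbind(1, X), y, family = binomial())
  expect_true(fit$converged)
  expect_lt(max(abs(c(fit$intercept, fit$coef) - ref$coefficients)), 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
})

test_that("a 2x2 balanced design recovers the closed-form log odds ratio", {
  x <- rep(c(0, 1), each = 100)
  y <- c(rep(c(1, 0), c(40, 60)), rep(c(1, 0), c(70, 30)))
  fit <- fit_logistic(matrix(x), y, ridge = 1e-10)
  expect_equal(fit$coef, log((70 / 30) / (40 / 60)), tolerance = 1e-4)
  expect_equal(fit$intercept, log(40 / 60), tolerance = 1e-4)
})

test_that("degenerate classifier inputs are refused and risks stay in [0,1]", {
  X <- matrix(rnorm(50), 50, 1)
  expect_error(fit_logistic(X, rep(1, 50)), "single class")
  Xb <- X; Xb[3] <- Inf
  expect_error(fit_logistic(Xb, rep(c(0, 1), 25)), "non-finite")
  # separable 1-D data: risks monotone in the feature, within [0,1]
  xs <- seq(-2, 2, length.out = 60)
  ys <- as.numeric(xs > 0)
  f <- fit_logistic(matrix(xs), ys, ridge = 1e-4)
  r <- predict(f, matrix(xs))
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("rank-based AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (i in 1:5) {
    y <- rbinom(200, 1, 0.3)
    s <- rnorm(200) + y
    expect_equal(pibcast:::auc_rank(s, y),
                 as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
  }
})

test_that("forward selection finds the informative feature first", {
  set.seed(33)
  hits <- 0L
  for (i in 1:30) {
    n <- 600
    X <- matrix(rnorm(n * 8), n, 8)
    pos <- sort(sample(n, 120))
    y <- rep(0, n); y[pos] <- 1
    X[pos, 4] <- X[pos, 4] + 1.2
    sel <- forward_select(X, y, k = 2, n_inner = 3)
    if (sel[1] == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 27L)
})

test_that("forward selection honors k, ties, and bounds", {
  set.seed(34)
  X <- matrix(rnorm(300 * 5), 300, 5)
  pos <- sort(sample(300, 80)); y <- rep(0, 300); y[pos] <- 1
  X[pos, 2] <- X[pos, 2] + 2
  X[, 4] <- X[, 2]  # duplicated informative column
  expect_identical(forward_select(X, y, 0, n_inner = 3), integer(0))
  sel <- forward_select(X, y, 2, n_inner = 3)
  expect_equal(sel[1], 2L)  # tie broken to the lower column index
  expect_error(forward_select(X, y, 9, n_inner = 3), "more features")
})

test_that("out-of-fold risks discriminate under an effect and not under the null", {
  mk <- function(seed, effect) {
    sp <- sim_params(duration_s = 4000 * 60, n_channels = 2L, lead_rate = 2,
                     cluster_size_mean = 2, gap_fraction = 0,
                     effect = effect, seed = seed)
    catalog <- simulate_seizure_times(sp)
    fm <- simulate_pib_features(4000, catalog, sp)
    fm <- make_folds(fm, 10L)
    cfg <- run_config(n_features = 2L, n_inner_folds = 3L)
    suppressWarnings(cross_val_risk(fm, cfg))
  }
  # average per-fold AUC: pooling out-of-fold scores across folds is biased
  # when training class balance varies by fold, so discrimination is
  # assessed within each held-out fold and averaged
  fold_auc <- function(r) {
    a <- vapply(split(seq_len(nrow(r)), r$fold), function(i) {
      y <- r$label[i] == "preictal"
      if (length(unique(y)) < 2L || anyNA(r$risk[i])) return(NA_real_)
      pibcast:::auc_rank(r$risk[i], y)
    }, 0)
    mean(a, na.rm = TRUE)
  }
  aucs_null <- vapply(1:3, function(s) fold_auc(mk(s, NULL)), 0)
  expect_true(all(abs(aucs_null - 0.5) < 0.15))
  aucs_eff <- vapply(4:6, function(s)
    fold_auc(mk(s, c(ch1_alpha = 8, ch2_beta = 8))), 0)
  expect_true(all(aucs_eff > 0.9))
})

test_that("no test-fold information leaks into selection, scaling, or weights", {
  sp <- sim_params(duration_s = 1500 * 60, n_channels = 2L, lead_rate = 3,
                   cluster_size_mean = 2, gap_fraction = 0,
                   effect = c(ch1_alpha = 6), seed = 41)
  catalog <- simulate_seizure_times(sp)
  fm <- simulate_pib_features(1500, catalog, sp)
  fm <- make_folds(fm, 5L)
  cfg <- run_config(n_folds = 5L, n_features = 2L, n_inner_folds = 3L)
  r1 <- suppressWarnings(cross_val_risk(fm, cfg))
  m1 <- attr(r1, "models")

  # perturb the features of every fold-3 block (test rows for fold 3)
  fm2 <- fm
  rows3 <- which(fm2$fold == 3L)
  fm2$X[rows3, ] <- fm2$X[rows3, ] * 10
  r2 <- suppressWarnings(cross_val_risk(fm2, cfg))
  m2 <- attr(r2, "models")
  expect_identical(m1[["3"]]$selected, m2[["3"]]$selected)
  expect_equal(m1[["3"]]$coef, m2[["3"]]$coef)
  expect_equal(m1[["3"]]$center, m2[["3"]]$center)

  # shuffling test-fold labels (among scored rows) changes no risk values
  fm3 <- fm
  rows3pi <- rows3[fm3$label[rows3] %in% c("preictal", "interictal")]
  set.seed(99)
  fm3$label[rows3pi] <- sample(fm3$label[rows3pi])
  r3 <- suppressWarnings(cross_val_risk(fm3, cfg))
  expect_equal(r3$risk[r3$fold == 3L], r1$risk[r1$fold == 3L])

  # determinism: identical inputs give identical selections and risks
  r4 <- suppressWarnings(cross_val_risk(fm, cfg))
  expect_identical(r4$risk, r1$risk)
  expect_identical(attr(r4, "models")[["2"]]$selected, m1[["2"]]$selected)
})

test_that("risks are invariant to affine rescaling of raw features", {
  sp <- sim_params(duration_s = 1200 * 60, n_channels = 2L, lead_rate = 3,
                   cluster_size_mean = 2, gap_fraction = 0,
                   effect = c(ch1_alpha = 6), seed = 42)
  catalog <- simulate_seizure_times(sp)
  fm <- simulate_pib_features(1200, catalog, sp)
  fm <- make_folds(fm, 4L)
  cfg <- run_config(n_folds = 4L, n_features = 2L, n_inner_folds = 3L)
  r1 <- suppressWarnings(cross_val_risk(fm, cfg))
  fm2 <- fm
  fm2$X <- fm2$X * 37  # constant power rescaling (log-shift per feature)
  r2 <- suppressWarnings(cross_val_risk(fm2, cfg))
  expect_equal(r2$risk, r1$risk, tolerance = 1e-6)
})

test_that("model artifacts serialize to JSON", {
  sp <- sim_params(duration_s = 800 * 60, n_channels = 1L, lead_rate = 4,
                   cluster_size_mean = 2, gap_fraction = 0,
                   effect = c(ch1_theta = 6), seed = 43)
  catalog <- simulate_seizure_times(sp)
  fm <- simulate_pib_features(800, catalog, sp)
  fm <- make_folds(fm, 4L)
  cfg <- run_config(n_folds = 4L, n_features = 1L, n_inner_folds = 2L)
  r <- suppressWarnings(cross_val_risk(fm, cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(length(back), 4L)
  expect_equal(back[["2"]]$selected, attr(r, "models")[["2"]]$selected)
})
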