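# Shared fixture builders and brute-force oracles. All fixtures are built
# in code; no data files are read.

feat_names <- function(n_ch) {
  as.vector(t(outer(seq_len(n_ch), band_definitions()$name,
                    function(i, b) paste0("ch", i, "_", b))))
}

# Plain feature matrix with lognormal PIB values on a 60 s grid.
make_fm <- function(n_blocks, n_ch = 2L, block_len = 60, seed = 1,
                    valid = NULL) {
  set.seed(seed)
  cn <- feat_names(n_ch)
  X <- matrix(10^rnorm(n_blocks * length(cn), mean = 1.5, sd = 0.4),
              n_blocks, length(cn), dimnames = list(NULL, cn))
  if (is.null(valid)) valid <- rep(TRUE, n_blocks)
  X[!valid, ] <- NA_real_
  pib_features((seq_len(n_blocks) - 1L) * block_len, X, valid = valid,
               block_len = block_len)
}

# Minute-grid brute force: is each minute of [0, span) inside a warning
# built from supra-threshold 60 s blocks with the given persistence?
brute_warning_mask <- function(block_start_s, risk, theta, persistence, span) {
  minutes <- seq(0, span - 60, by = 60)
  mask <- rep(FALSE, length(minutes))
  for (s in block_start_s[!is.na(risk) & risk > theta]) {
    hit <- minutes >= s & minutes < min(s + persistence, span)
    mask <- mask | hit
  }
  mask
}

# Pairwise brute-force forecast scoring (reference for score_forecasts).
brute_score <- function(warnings, onsets, horizon, consider = NULL) {
  if (is.null(consider)) consider <- seq_along(onsets)
  tp <- vapply(onsets, function(t) {
    any(warnings$start_s <= t - horizon & t < warnings$end_s)
  }, TRUE)
  fp <- 0L
  for (i in seq_len(nrow(warnings))) {
    if (!any(onsets >= warnings$start_s[i] & onsets < warnings$end_s[i]))
      fp <- fp + 1L
  }
  list(n_tp = sum(tp[consider]), n_fp = fp)
}

# Brute-force block labeling (reference for label_blocks).
brute_labels <- function(block_start_s, block_len, catalog, preictal_len) {
  vapply(block_start_s, function(b) {
    ictal <- any(b < catalog$offset_s & b + block_len > catalog$onset_s)
    if (ictal) return("ictal_excluded")
    pre <- any(b >= catalog$onset_s - preictal_len & b < catalog$onset_s)
    if (pre) "preictal" else "interictal"
  }, "")
}
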