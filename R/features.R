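#' Standard frequency-band definitions
#'
#' The six canonical bands used for power-in-band features: delta 0.1-4 Hz,
#' theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz, low gamma 30-70 Hz and high
#' gamma 70-180 Hz. Bands are half-open `[lo, hi)`, so a shared edge (4, 8,
#' 12, 30, 70 Hz) belongs to the upper band; frequency-bin assignment over
#' [0.1, 180) Hz is exhaustive and exclusive.
#'
#' @return data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma_low", "gamma_high"),
    lo_hz = c(0.1, 4, 8, 12, 30, 70),
    hi_hz = c(4, 8, 12, 30, 70, 180))
}

#' Power-in-band feature matrix
#'
#' Per-block feature container: one row per non-overlapping block, one
#' column per (channel, band) power-in-band value in uV^2. Columns are
#' channel-major, band-minor (`ch1_delta ... ch1_gamma_high, ch2_delta, ...`).
#' Invalid blocks carry `NA` features. `label` and `fold` columns are filled
#' by [label_blocks()] and [make_folds()].
#'
#' @param block_start_s numeric vector of block start times (s).
#' @param X numeric matrix, blocks x features, non-negative where valid.
#' @param valid logical vector, one entry per block.
#' @param block_len block length (s).
#' @param label optional character vector of block labels.
#' @param fold optional integer vector of fold ids.
#' @return An object of class `pib_features`.
#' @export
pib_features <- function(block_start_s, X, valid = NULL, block_len = 60,
                         label = NULL, fold = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = length(block_start_s))
  stopifnot(length(block_start_s) == nrow(X))
  if (is.null(valid)) valid <- rep(TRUE, nrow(X))
  stopifnot(length(valid) == nrow(X))
  if (any(X[valid, ] < 0, na.rm = TRUE)) stop("PIB values must be non-negative")
  structure(list(block_start_s = as.numeric(block_start_s),
                 X = X, valid = as.logical(valid),
                 block_len = as.numeric(block_len),
                 label = label, fold = fold),
            class = "pib_features")
}

#' @export
print.pib_features <- function(x, ...) {
  cat(sprintf("<pib_features> %d block(s) x %d feature(s), %d valid, block_len %g s\n",
              nrow(x$X), ncol(x$X), sum(x$valid), x$block_len))
  if (!is.null(x$label)) {
    tb <- table(x$label, useNA = "no")
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Re-reference a record to the common average
#'
#' Subtracts the instantaneous across-channel mean from every channel.
#' The validity mask is unchanged.
#'
#' @param record an [ieeg_record()] with at least 2 channels.
#' @return The re-referenced `ieeg_record`.
#' @export
average_reference <- function(record) {
  stopifnot(inherits(record, "ieeg_record"))
  if (nrow(record$samples) < 2L)
    stop("average reference requires at least 2 channels")
  record$samples <- sweep(record$samples, 2L, colMeans(record$samples))
  record
}

#' Partition a record into non-overlapping blocks
#'
#' Consecutive half-open windows `[k*block_len, (k+1)*block_len)` from the
#' record start; the trailing partial block is dropped. A block is valid
#' only if every one of its samples is valid.
#'
#' @param record an [ieeg_record()].
#' @param block_len block length in seconds; `block_len * fs` must be a
#'   whole number of samples.
#' @return data frame with columns `block_start_s`, `first_sample`
#'   (1-based index), and `valid`.
#' @export
partition_blocks <- function(record, block_len = 60) {
  stopifnot(inherits(record, "ieeg_record"), block_len > 0)
  bs <- block_len * record$fs
  if (abs(bs - round(bs)) > 1e-6)
    stop("block_len * fs must be an integer sample count")
  bs <- as.integer(round(bs))
  n_blocks <- ncol(record$samples) %/% bs
  if (n_blocks == 0L) stop("record shorter than one block")
  first <- (seq_len(n_blocks) - 1L) * bs + 1L
  valid_counts <- vapply(seq_len(n_blocks), function(k)
    sum(record$valid_mask[first[k]:(first[k] + bs - 1L)]), 0L)
  data.frame(block_start_s = (seq_len(n_blocks) - 1L) * block_len,
             first_sample = first,
             valid = valid_counts == bs)
}

# Map positive-frequency bins of an N-point DFT at rate fs to band indices
# (0 = discarded). Returns list(freqs, band, fold_factor).
band_bins <- function(n, fs, bands) {
  kmax <- n %/% 2L
  k <- seq_len(kmax)
  f <- k * fs / n
  # one-sided periodogram: double all bins except Nyquist (even n)
  fold <- rep(2, kmax)
  if (n %% 2L == 0L) fold[kmax] <- 1
  band <- rep(0L, kmax)
  for (b in seq_len(nrow(bands)))
    band[f >= bands$lo_hz[b] & f < bands$hi_hz[b]] <- b
  list(k = k, f = f, band = band, fold = fold)
}

#' Power-in-band features of one signal block
#'
#' Discrete Fourier transform of the mean-removed block; the periodogram
#' power at each positive-frequency bin is assigned to the band whose
#' half-open `[lo, hi)` range contains the bin frequency, and summed per
#' band. Powers are normalized so that the sum over all bins equals the
#' block's (population) variance in uV^2 (Parseval); the DC bin and bins
#' outside every band contribute to no feature.
#'
#' @param x numeric vector: one fully valid block of one channel.
#' @param fs sampling rate (Hz).
#' @param bands band definition data frame (see [band_definitions()]).
#' @return Named numeric vector of per-band powers (uV^2).
#' @export
compute_pib <- function(x, fs, bands = band_definitions()) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (anyNA(x)) stop("block contains invalid samples; caller must skip it")
  if (any(bands$hi_hz > fs / 2))
    warning("band(s) extend above the Nyquist frequency and are clipped")
  n <- length(x)
  bb <- band_bins(n, fs, bands)
  p <- Mod(stats::fft(x - mean(x)))^2 / n^2
  pw <- p[bb$k + 1L] * bb$fold
  out <- vapply(seq_len(nrow(bands)), function(b) sum(pw[bb$band == b]), 0)
  names(out) <- bands$name
  out
}

#' Extract the full power-in-band feature matrix from a record
#'
#' Applies the common average reference, partitions the record into
#' non-overlapping blocks, and computes per-channel band powers for every
#' fully valid block, yielding `n_channels * n_bands` features per block
#' in channel-major, band-minor order. Invalid blocks carry `NA` rows.
#'
#' @param record an [ieeg_record()] (>= 2 channels).
#' @param config a [run_config()] supplying `block_len` and `bands`.
#' @return A [pib_features()] object.
#' @export
extract_features <- function(record, config = run_config()) {
  stopifnot(inherits(record, "ieeg_record"))
  rec <- average_reference(record)
  blocks <- partition_blocks(rec, config$block_len)
  if (!any(blocks$valid)) stop("record contains no fully valid block")
  bands <- config$bands
  n_blocks <- nrow(blocks)
  bs <- as.integer(round(config$block_len * rec$fs))
  n_ch <- nrow(rec$samples)
  bb <- band_bins(bs, rec$fs, bands)
  agg <- bb$band + 1L  # 1 = discarded bin bucket

  X <- matrix(NA_real_, n_blocks, n_ch * nrow(bands))
  vb <- which(blocks$valid)
  for (ch in seq_len(n_ch)) {
    # all valid blocks of one channel at once: columns are blocks
    m <- matrix(0, bs, length(vb))
    for (i in seq_along(vb))
      m[, i] <- rec$samples[ch, blocks$first_sample[vb[i]]:(blocks$first_sample[vb[i]] + bs - 1L)]
    m <- sweep(m, 2L, colMeans(m))
    p <- Mod(stats::mvfft(m))^2 / bs^2
    pw <- p[bb$k + 1L, , drop = FALSE] * bb$fold
    sums <- rowsum(pw, agg)  # one row per bucket present
    cols <- (ch - 1L) * nrow(bands) + seq_len(nrow(bands))
    for (b in seq_len(nrow(bands))) {
      r <- which(rownames(sums) == as.character(b + 1L))
      X[vb, cols[b]] <- if (length(r)) sums[r, ] else 0
    }
  }
  colnames(X) <- as.vector(t(outer(seq_len(n_ch), bands$name,
                                   function(i, b) paste0("ch", i, "_", b))))
  pib_features(blocks$block_start_s, X, valid = blocks$valid,
               block_len = config$block_len)
}

#' Write a feature table to CSV (long format)
#'
#' One row per (block, channel, band) with columns `block_start_s`,
#' `channel`, `band`, `pib`, `label`, `fold`. Invalid blocks are omitted.
#'
#' @param fm a [pib_features()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "pib_features"))
  cn <- colnames(fm$X)
  parts <- regmatches(cn, regexec("^ch([0-9]+)_(.+)$", cn))
  ch <- vapply(parts, function(p) as.integer(p[2L]), 0L)
  band <- vapply(parts, function(p) p[3L], "")
  vb <- which(fm$valid)
  long <- data.frame(
    block_start_s = rep(fm$block_start_s[vb], each = length(cn)),
    channel = rep(ch, length(vb)),
    band = rep(band, length(vb)),
    pib = as.vector(t(fm$X[vb, , drop = FALSE])),
    label = if (is.null(fm$label)) NA_character_ else
      rep(fm$label[vb], each = length(cn)),
    fold = if (is.null(fm$fold)) NA_integer_ else
      rep(fm$fold[vb], each = length(cn)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @param block_len block length in seconds (not stored in the table).
#' @return A [pib_features()] object (valid blocks only).
#' @export
read_feature_table <- function(path, block_len = 60) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("block_start_s", "channel", "band", "pib")
  stopifnot(all(req %in% names(long)))
  feat <- paste0("ch", long$channel, "_", long$band)
  starts <- sort(unique(long$block_start_s))
  cn <- unique(feat[order(long$channel, match(long$band, unique(long$band)))])
  X <- matrix(NA_real_, length(starts), length(cn),
              dimnames = list(NULL, cn))
  ri <- match(long$block_start_s, starts)
  ci <- match(feat, cn)
  X[cbind(ri, ci)] <- long$pib
  lab <- fold <- NULL
  if ("label" %in% names(long) && !all(is.na(long$label)))
    lab <- long$label[!duplicated(long$block_start_s)][order(unique(long$block_start_s))]
  if ("fold" %in% names(long) && !all(is.na(long$fold)))
    fold <- long$fold[!duplicated(long$block_start_s)][order(unique(long$block_start_s))]
  pib_features(starts, X, block_len = block_len, label = lab, fold = fold)
}
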