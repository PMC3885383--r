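# Minimal EDF (European Data Format) support. EDF stores an ASCII header
# followed by fixed-duration data records of little-endian 16-bit integers,
# one stretch per signal per record, linearly mapped between per-signal
# digital and physical calibration ranges. This implementation covers
# continuous uniform-rate recordings (the device regime targeted here):
# one common sampling rate across signals; EDF+ annotation channels are
# skipped on read.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, digits = 7L, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = 4L, format = "g")
  edf_pad(s, width)
}

#' Write an iEEG record to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's physical
#' range, using 1-second data records. The record duration must be a whole
#' number of seconds and the sampling rate a whole number of samples per
#' second.
#'
#' @param record an [ieeg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "ieeg_record"))
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer number of samples per second")
  n_rec <- floor(ncol(record$samples) / fs)
  if (n_rec * fs != ncol(record$samples))
    stop("write_edf requires a whole number of seconds of data")
  n_ch <- nrow(record$samples)
  dmin <- -32768; dmax <- 32767

  pmin <- apply(record$samples, 1L, min)
  pmax <- apply(record$samples, 1L, max)
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  # write-what-you-print: use the header's (rounded) calibration values for
  # quantization so read-back matches within one quantization step
  pmin_s <- vapply(pmin, edf_num, "")
  pmax_s <- vapply(pmax, edf_num, "")
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X X X X", 80L), edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (n_ch + 1L), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad("1", 8L), edf_pad(n_ch, 4L))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  fld(record$channel_ids, 16L)
  fld(rep("", n_ch), 80L)
  fld(rep("uV", n_ch), 8L)
  fld(pmin_s, 8L)
  fld(pmax_s, 8L)
  fld(rep(dmin, n_ch), 8L)
  fld(rep(dmax, n_ch), 8L)
  fld(rep("", n_ch), 80L)
  fld(rep(as.integer(fs), n_ch), 8L)
  fld(rep("", n_ch), 32L)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- round((record$samples - pmin) * scale + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  spr <- as.integer(fs)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an iEEG record
#'
#' Supports continuous EDF/EDF+ files in which every ordinary signal shares
#' one sampling rate; files with unequal per-signal rates are rejected as
#' unsupported. EDF+ annotation signals are skipped. All samples are marked
#' valid (this reader performs no artifact detection).
#'
#' @param path path to an EDF file.
#' @return An [ieeg_record()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- as.integer(rd(8L)); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  n_sig <- as.integer(rd(4L))
  if (is.na(n_sig) || n_sig < 1L) stop("not a valid EDF file: ", path)
  sig_fld <- function(w) vapply(seq_len(n_sig), function(i) rd(w), "")
  labels <- sig_fld(16L); sig_fld(80L); sig_fld(8L)
  pmin <- as.numeric(sig_fld(8L)); pmax <- as.numeric(sig_fld(8L))
  dmin <- as.numeric(sig_fld(8L)); dmax <- as.numeric(sig_fld(8L))
  sig_fld(80L)
  spr <- as.integer(sig_fld(8L))
  sig_fld(32L)

  is_annot <- grepl("EDF Annotations", labels, fixed = TRUE)
  sig <- which(!is_annot)
  if (length(sig) == 0L) stop("EDF file contains no signal channels: ", path)
  if (length(unique(spr[sig])) != 1L)
    stop("unsupported EDF: signals have unequal sampling rates")
  fs <- spr[sig][1L] / rec_dur

  out <- matrix(0, nrow = length(sig), ncol = n_rec * spr[sig][1L])
  rec_words <- sum(spr)
  offs <- cumsum(c(0L, spr))  # word offset of each signal within a record
  for (r in seq_len(n_rec)) {
    words <- readBin(con, "integer", n = rec_words, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(words) < rec_words)
      stop("EDF file truncated at data record ", r)
    for (k in seq_along(sig)) {
      j <- sig[k]
      seg <- words[(offs[j] + 1L):(offs[j] + spr[j])]
      out[k, ((r - 1L) * spr[j] + 1L):(r * spr[j])] <- seg
    }
  }
  gain <- (pmax[sig] - pmin[sig]) / (dmax[sig] - dmin[sig])
  out <- (out - dmin[sig]) * gain + pmin[sig]
  ieeg_record(out, fs = fs, channel_ids = labels[sig])
}

#' Write an iEEG record to the chunked binary container
#'
#' Stores samples as little-endian float32 frames (all channels per time
#' point) in `<path>.bin` with a JSON sidecar `<path>.json` holding channel
#' labels, sampling rate, start time, and invalid runs as half-open sample
#' ranges. Unlike EDF this holds months-long single sessions without
#' per-record bookkeeping or 16-bit quantization.
#'
#' @param record an [ieeg_record()].
#' @param path path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_ieeg_container <- function(record, path) {
  stopifnot(inherits(record, "ieeg_record"))
  inv <- rle(!record$valid_mask)
  ends <- cumsum(inv$lengths)
  starts <- ends - inv$lengths
  runs <- cbind(starts, ends)[inv$values, , drop = FALSE]  # 0-based half-open
  meta <- list(format = "pibcast-ieeg-v1",
               channel_ids = record$channel_ids,
               fs = record$fs, t0 = record$t0,
               n_samples = ncol(record$samples),
               dtype = "float32_le",
               invalid_runs = lapply(seq_len(nrow(runs)), function(i)
                 c(runs[[i, 1L]], runs[[i, 2L]])))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(record$samples), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an iEEG record from the chunked binary container
#' @param path path stem used in [write_ieeg_container()].
#' @return An [ieeg_record()].
#' @export
read_ieeg_container <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("container sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "pibcast-ieeg-v1"))
    stop("unrecognized container format in ", meta_path)
  n_ch <- length(meta$channel_ids)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_ch * meta$n_samples, size = 4L,
               endian = "little")
  if (length(x) != n_ch * meta$n_samples)
    stop("container data truncated: ", path, ".bin")
  valid <- rep(TRUE, meta$n_samples)
  if (length(meta$invalid_runs) > 0L) {
    runs <- meta$invalid_runs
    if (!is.matrix(runs)) runs <- do.call(rbind, lapply(runs, unlist))
    for (i in seq_len(nrow(runs)))
      valid[(runs[i, 1L] + 1L):runs[i, 2L]] <- FALSE
  }
  ieeg_record(matrix(x, nrow = n_ch), fs = meta$fs,
              channel_ids = meta$channel_ids, valid_mask = valid, t0 = meta$t0)
}
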