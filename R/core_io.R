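#' Multichannel iEEG record
#'
#' In-memory container for a continuous multichannel recording: a
#' channels-by-samples matrix (microvolts), sampling rate, a per-sample
#' validity mask shared across channels (dropouts, telemetry gaps), and the
#' absolute start time of the record. All block and event times in the
#' package are seconds from record start, with half-open intervals
#' `[start, end)` throughout.
#'
#' @param samples numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_ids character vector of channel labels; defaults to
#'   `ch1, ch2, ...`.
#' @param valid_mask logical vector, one entry per sample; `FALSE` marks
#'   invalid data. Defaults to all valid.
#' @param t0 absolute record start time in seconds (defines time 0).
#' @return An object of class `ieeg_record`.
#' @export
ieeg_record <- function(samples, fs, channel_ids = NULL, valid_mask = NULL,
                        t0 = 0) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1L, fs > 0)
  n_ch <- nrow(samples)
  n_s <- ncol(samples)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(n_ch))
  if (length(channel_ids) != n_ch)
    stop("channel_ids length must match the number of channels")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n_s)
  if (length(valid_mask) != n_s)
    stop("valid_mask must have one entry per sample")
  structure(list(channel_ids = as.character(channel_ids),
                 fs = as.numeric(fs),
                 samples = samples,
                 valid_mask = as.logical(valid_mask),
                 t0 = as.numeric(t0),
                 duration = n_s / fs),
            class = "ieeg_record")
}

#' @export
print.ieeg_record <- function(x, ...) {
  cat(sprintf(
    "<ieeg_record> %d channel(s), %.6g Hz, %.6g s (%d samples), %.1f%% valid\n",
    length(x$channel_ids), x$fs, x$duration, ncol(x$samples),
    100 * mean(x$valid_mask)))
  invisible(x)
}

#' Seizure catalog
#'
#' Ordered list of seizure events given as onset/offset seconds from record
#' start. Events must be non-overlapping and strictly ordered by onset.
#' The `lead` column (seizures preceded by at least `min_lead_gap` seconds
#' with no other onset) is filled by [find_lead_seizures()].
#'
#' @param onset_s,offset_s numeric vectors of event onsets and offsets (s).
#' @param lead optional logical vector of lead-seizure flags.
#' @return An object of class `seizure_catalog`: a data frame with columns
#'   `onset_s`, `offset_s`, `lead`, sorted by onset.
#' @export
seizure_catalog <- function(onset_s = numeric(), offset_s = numeric(),
                            lead = NULL) {
  stopifnot(length(onset_s) == length(offset_s))
  if (is.null(lead)) lead <- rep(NA, length(onset_s))
  bad <- which(offset_s <= onset_s)
  if (length(bad) > 0L)
    stop(sprintf("event %d: offset_s (%.6g) must exceed onset_s (%.6g)",
                 bad[1L], offset_s[bad[1L]], onset_s[bad[1L]]))
  if (any(onset_s < 0)) stop("onsets must be >= 0 (seconds from record start)")
  o <- order(onset_s)
  onset_s <- onset_s[o]; offset_s <- offset_s[o]; lead <- lead[o]
  if (length(onset_s) > 1L) {
    ov <- which(onset_s[-1L] < offset_s[-length(offset_s)])
    if (length(ov) > 0L)
      stop(sprintf("events %d and %d overlap", ov[1L], ov[1L] + 1L))
  }
  structure(data.frame(onset_s = as.numeric(onset_s),
                       offset_s = as.numeric(offset_s),
                       lead = as.logical(lead)),
            class = c("seizure_catalog", "data.frame"))
}

#' Read a seizure catalog from CSV
#'
#' The CSV must have header columns `onset_s` and `offset_s` (seconds from
#' record start); an optional `lead` column is preserved. Rows are sorted by
#' onset; malformed rows are rejected with their row number.
#'
#' @param path path to the CSV file.
#' @return A [seizure_catalog()].
#' @export
read_seizure_catalog <- function(path) {
  if (!file.exists(path)) stop("seizure catalog not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "offset_s")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("catalog is missing required column(s): ", paste(miss, collapse = ", "))
  for (cl in req) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (anyNA(v))
      stop(sprintf("catalog row %d: non-numeric or missing %s",
                   which(is.na(v))[1L], cl))
    df[[cl]] <- v
  }
  bad <- which(df$offset_s <= df$onset_s)
  if (length(bad) > 0L)
    stop(sprintf("catalog row %d: offset_s must exceed onset_s", bad[1L]))
  lead <- if ("lead" %in% names(df)) as.logical(df$lead) else NULL
  seizure_catalog(df$onset_s, df$offset_s, lead)
}

#' Write a seizure catalog to CSV
#' @param catalog a [seizure_catalog()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_seizure_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' Cohort summary statistics
#'
#' Per-subject recording durations and seizure counts summarized as exact
#' integer totals plus means and sample standard deviations (n - 1
#' denominator). With a single subject the standard deviation is reported
#' as `NA` (undefined), not 0.
#'
#' @param per_subject data frame with columns `duration_days`, `n_seizures`,
#'   `n_lead` (one row per subject); a `subject_id` column is optional.
#' @return An object of class `cohort_summary` with elements `per_subject`,
#'   `totals`, `means` and `stds`.
#' @export
summarize_cohort <- function(per_subject) {
  req <- c("duration_days", "n_seizures", "n_lead")
  stopifnot(is.data.frame(per_subject), all(req %in% names(per_subject)),
            nrow(per_subject) >= 1L)
  m <- as.matrix(per_subject[req])
  n <- nrow(m)
  stds <- if (n >= 2L) apply(m, 2L, stats::sd) else
    stats::setNames(rep(NA_real_, 3L), req)
  structure(list(per_subject = per_subject,
                 totals = colSums(m),
                 means = colMeans(m),
                 stds = stds,
                 n_subjects = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subject(s)\n", x$n_subjects))
  for (cl in names(x$totals)) {
    sd_txt <- if (is.na(x$stds[[cl]])) "NA" else sprintf("%.1f", x$stds[[cl]])
    cat(sprintf("  %-14s total %g, mean %.1f +/- %s\n",
                cl, x$totals[[cl]], x$means[[cl]], sd_txt))
  }
  invisible(x)
}

#' Analysis run configuration
#'
#' Bundles every tunable of the forecasting pipeline with its default:
#' the six frequency bands, 60 s feature blocks, a 90 min pre-ictal
#' labeling window, 90 min warning persistence, 5 min forecast horizon,
#' 4 h lead-seizure gap, the target time-in-warning grid, 10 contiguous
#' cross-validation folds, and 10 forward-selected features.
#'
#' @param bands data frame of band definitions (see [band_definitions()]).
#' @param block_len feature block length in seconds.
#' @param preictal_len pre-ictal labeling window before each onset (s).
#' @param persistence warning persistence: minimum warning duration (s).
#' @param horizon forecast horizon: a warning must begin at least this many
#'   seconds before onset to count as a valid forecast (s).
#' @param min_lead_gap minimum seizure-free gap defining a lead seizure (s).
#' @param tiw_grid target proportions of record time in warning, each in (0,1).
#' @param n_folds number of contiguous cross-validation folds.
#' @param n_features number of PIB features chosen by forward selection.
#' @param n_inner_folds contiguous inner folds used by the selection criterion.
#' @param ridge small ridge penalty on classifier weights (numerical guard).
#' @param n_mc Monte-Carlo draws for the chance-predictor p-value.
#' @param seed master seed; all pipeline randomness derives from it.
#' @param analysis_window optional `c(start_s, end_s)` restricting the
#'   analyzed portion of the record (e.g. to skip post-surgical segments);
#'   `NULL` analyzes the whole record.
#' @param ictal_as_interictal if `TRUE`, blocks overlapping a seizure are
#'   labeled inter-ictal instead of being excluded.
#' @param lead_analysis if `TRUE` (default), [run_pipeline()] also scores and
#'   tests the lead-seizure subset; disable to halve the Monte-Carlo cost.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(bands = band_definitions(),
                       block_len = 60,
                       preictal_len = 5400,
                       persistence = 5400,
                       horizon = 300,
                       min_lead_gap = 14400,
                       tiw_grid = c(0.1, 0.15, 0.2, 0.3, 0.35, 0.4, 0.5),
                       n_folds = 10L,
                       n_features = 10L,
                       n_inner_folds = 5L,
                       ridge = 1e-4,
                       n_mc = 1000L,
                       seed = 1L,
                       analysis_window = NULL,
                       ictal_as_interictal = FALSE,
                       lead_analysis = TRUE) {
  stopifnot(is.data.frame(bands), all(c("name", "lo_hz", "hi_hz") %in% names(bands)),
            all(bands$lo_hz < bands$hi_hz),
            block_len > 0, preictal_len > 0, persistence > 0,
            horizon > 0, horizon < persistence,
            min_lead_gap > 0,
            all(tiw_grid > 0), all(tiw_grid < 1),
            n_folds >= 2L, n_features >= 0L, n_inner_folds >= 2L,
            ridge >= 0, n_mc >= 1L)
  if (is.unsorted(bands$lo_hz)) stop("bands must be ordered by lo_hz")
  if (any(bands$lo_hz[-1L] < bands$hi_hz[-nrow(bands)]))
    stop("bands must not overlap (half-open [lo, hi) convention)")
  if (!is.null(analysis_window))
    stopifnot(length(analysis_window) == 2L,
              analysis_window[1L] < analysis_window[2L])
  structure(list(bands = bands, block_len = block_len,
                 preictal_len = preictal_len, persistence = persistence,
                 horizon = horizon, min_lead_gap = min_lead_gap,
                 tiw_grid = tiw_grid, n_folds = as.integer(n_folds),
                 n_features = as.integer(n_features),
                 n_inner_folds = as.integer(n_inner_folds),
                 ridge = ridge, n_mc = as.integer(n_mc),
                 seed = as.integer(seed),
                 analysis_window = analysis_window,
                 ictal_as_interictal = isTRUE(ictal_as_interictal),
                 lead_analysis = isTRUE(lead_analysis)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any key present in the file overrides the corresponding [run_config()]
#' default; `bands` may be given as a list of `{name, lo_hz, hi_hz}` entries.
#'
#' @param path path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$bands)) {
    y$bands <- do.call(rbind, lapply(y$bands, function(b)
      data.frame(name = b$name, lo_hz = as.numeric(b$lo_hz),
                 hi_hz = as.numeric(b$hi_hz))))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

# Derive a reproducible 31-bit sub-seed for a named randomness stream.
derive_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  m <- as.numeric(master) %% 1000003
  as.integer((m * 2654435761 + h * 97 + 1) %% 2147483646) + 1L
}
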