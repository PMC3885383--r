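#' Convert block risks into merged variable-duration warnings
#'
#' Every block whose risk exceeds the threshold opens a warning of length
#' `persistence` starting at the block start; warnings that begin before a
#' previous warning ends are combined with it into a single
#' variable-duration warning. Warnings are clipped to `[0, span)`.
#'
#' @param risks a `risk_series` or any data frame with columns
#'   `block_start_s` and `risk`.
#' @param threshold scalar risk threshold, or a per-block vector (e.g. one
#'   calibrated per cross-validation fold).
#' @param persistence warning persistence in seconds (> 0).
#' @param span record span in seconds; defaults to the `span` attribute of
#'   `risks` or the last block end.
#' @return A [warning_set()].
#' @export
risk_to_warnings <- function(risks, threshold, persistence = 5400,
                             span = NULL) {
  stopifnot(persistence > 0)
  if (is.null(span)) span <- attr(risks, "span")
  if (is.null(span)) {
    bl <- attr(risks, "block_len")
    span <- max(risks$block_start_s) + if (is.null(bl)) 0 else bl
  }
  cmp <- risks$risk > threshold  # NA risk or NA threshold never triggers
  supra <- !is.na(cmp) & cmp
  s <- risks$block_start_s[supra]
  warning_set(pmax(s, 0), pmin(s + persistence, span))
}

#' Calibrate the risk threshold to a target time in warning
#'
#' Picks the threshold from the sorted unique training risks, by bisection
#' over the (monotone, stepwise) realized time-in-warning curve, so that
#' the realized training TIW is closest to the target; exact ties go to
#' the larger threshold (less time in warning). If all risks are equal the
#' threshold is set at that value (no warnings) with a warning.
#'
#' @param risks training-block risks: data frame with `block_start_s`, `risk`.
#' @param target_tiw target proportion of time in warning, in (0, 1).
#' @param persistence warning persistence (s).
#' @param span record span (s) used as the TIW denominator.
#' @param within optional data frame of half-open intervals (`start_s`,
#'   `end_s`): realized TIW is then the warned fraction of that sub-span
#'   (used for per-fold calibration on training time only).
#' @return list with `threshold`, `achieved_tiw`, and `deviation`
#'   (`abs(achieved_tiw - target_tiw)`).
#' @export
calibrate_threshold <- function(risks, target_tiw, persistence = 5400,
                                span = NULL, within = NULL) {
  stopifnot(target_tiw > 0, target_tiw < 1)
  if (is.null(span)) span <- attr(risks, "span")
  stopifnot(!is.null(span) || !is.null(within))
  u <- sort(unique(risks$risk[!is.na(risks$risk)]))
  if (length(u) == 0L) stop("no finite risks to calibrate on")
  tiw_at <- function(theta) {
    ws <- risk_to_warnings(risks, theta, persistence,
                           span = if (is.null(within)) span else
                             max(within$end_s))
    if (is.null(within)) total_interval_length(ws) / span
    else intersect_interval_length(within, ws) /
      total_interval_length(within)
  }
  if (length(u) == 1L) {
    warning("all training risks are equal; threshold set above them (TIW = 0)")
    return(list(threshold = u, achieved_tiw = tiw_at(u), deviation =
                  abs(tiw_at(u) - target_tiw)))
  }
  lo <- 1L; hi <- length(u)
  t_lo <- tiw_at(u[lo])
  t_hi <- tiw_at(u[hi])
  if (t_lo < target_tiw) { hi <- lo; t_hi <- t_lo }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    t_mid <- tiw_at(u[mid])
    if (t_mid >= target_tiw) { lo <- mid; t_lo <- t_mid }
    else { hi <- mid; t_hi <- t_mid }
  }
  d_lo <- abs(t_lo - target_tiw)
  d_hi <- abs(t_hi - target_tiw)
  if (d_hi <= d_lo) list(threshold = u[hi], achieved_tiw = t_hi, deviation = d_hi)
  else list(threshold = u[lo], achieved_tiw = t_lo, deviation = d_lo)
}

#' Score warnings against a seizure catalog
#'
#' A seizure with onset `t` is a true positive when some warning interval
#' `[s, e)` both covers it (`t < e`) and began at least the forecast
#' horizon before it (`s <= t - horizon`); otherwise it is a false
#' negative. A merged warning interval is a false positive when no seizure
#' onset falls inside it (a seizure arriving within the horizon still
#' makes the warning non-false-positive even though the seizure counts as
#' missed). With `lead_only`, sensitivity is computed over lead-flagged
#' seizures only; false positives and time in warning are unchanged.
#'
#' @param warnings a [warning_set()].
#' @param catalog a [seizure_catalog()].
#' @param horizon forecast horizon in seconds.
#' @param span record span in seconds (denominator for TIW and FP/day).
#' @param lead_only restrict sensitivity to lead seizures.
#' @return An object of class `forecast_result`: list with `n_seizures`,
#'   `n_tp`, `sensitivity`, `n_fp`, `fp_per_day`, `tiw`, `span`.
#' @export
score_forecasts <- function(warnings, catalog, horizon = 300, span,
                            lead_only = FALSE) {
  stopifnot(inherits(warnings, "warning_set"),
            inherits(catalog, "seizure_catalog"), span > 0)
  onsets <- catalog$onset_s
  covered <- rep(FALSE, length(onsets))
  forecast_ok <- rep(FALSE, length(onsets))
  if (nrow(warnings) > 0L && length(onsets) > 0L) {
    idx <- findInterval(onsets, warnings$start_s)
    has <- idx > 0L
    covered[has] <- onsets[has] < warnings$end_s[idx[has]]
    forecast_ok <- covered &
      ifelse(has, warnings$start_s[pmax(idx, 1L)] <= onsets - horizon, FALSE)
  }
  n_fp <- if (nrow(warnings) == 0L) 0L else {
    hits <- vapply(seq_len(nrow(warnings)), function(i)
      any(onsets >= warnings$start_s[i] & onsets < warnings$end_s[i]), TRUE)
    sum(!hits)
  }
  consider <- if (lead_only) which(catalog$lead %in% TRUE) else
    seq_along(onsets)
  n_sz <- length(consider)
  n_tp <- sum(forecast_ok[consider])
  structure(list(
    n_seizures = n_sz,
    n_tp = n_tp,
    sensitivity = if (n_sz > 0L) n_tp / n_sz else NA_real_,
    n_fp = as.integer(n_fp),
    fp_per_day = n_fp / (span / 86400),
    tiw = total_interval_length(warnings) / span,
    span = span,
    lead_only = lead_only), class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf(
    "<forecast_result>%s Sn %d/%d = %.3f, FP/day %.3f, TIW %.3f\n",
    if (isTRUE(x$lead_only)) " [lead seizures]" else "",
    x$n_tp, x$n_seizures, x$sensitivity, x$fp_per_day, x$tiw))
  invisible(x)
}

#' Write a warning set to CSV
#' @param warnings a [warning_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_warnings <- function(warnings, path) {
  utils::write.csv(as.data.frame(warnings), path, row.names = FALSE)
  invisible(path)
}
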