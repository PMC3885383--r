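#' Run the full forecasting pipeline over the time-in-warning grid
#'
#' Executes feature extraction (or feature-level simulation), labeling,
#' lead-seizure flagging, contiguous-fold assignment, out-of-fold risk
#' prediction, and — for every target time in warning on the grid —
#' per-fold threshold calibration, warning construction, scoring, and the
#' matched chance-predictor significance test, for all seizures and for
#' lead seizures only. Deterministic for a fixed configuration and seed.
#'
#' @param config a [run_config()].
#' @param features a [pib_features()] object (feature-level input), or `NULL`.
#' @param catalog a [seizure_catalog()]; required with `features` or `record`.
#' @param record an [ieeg_record()] to run feature extraction on, or `NULL`.
#' @param sim a [sim_params()]: simulate the catalog and features instead of
#'   reading inputs (the generator seed defaults to the config seed).
#' @param subject_id identifier used in the report rows.
#' @return An object of class `forecast_report`: list with `rows` (one row
#'   per target TIW), `details` (per-target scoring objects), `risks`,
#'   `catalog`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config(), features = NULL,
                         catalog = NULL, record = NULL, sim = NULL,
                         subject_id = "subject") {
  if (!is.null(sim)) {
    if (is.null(sim$seed)) sim$seed <- config$seed
    catalog <- simulate_seizure_times(sim)
    features <- simulate_pib_features(floor(sim$duration_s / sim$block_len_s),
                                      catalog, sim)
  }
  if (is.null(features) && !is.null(record))
    features <- extract_features(record, config)
  if (is.null(features) || is.null(catalog))
    stop("run_pipeline needs features (or a record, or sim) plus a catalog")

  fm <- features
  if (!is.null(config$analysis_window)) {
    w <- config$analysis_window
    keep <- fm$block_start_s >= w[1L] & fm$block_start_s + fm$block_len <= w[2L]
    fm <- pib_features(fm$block_start_s[keep], fm$X[keep, , drop = FALSE],
                       valid = fm$valid[keep], block_len = fm$block_len)
    inwin <- catalog$onset_s >= w[1L] & catalog$onset_s < w[2L]
    catalog <- seizure_catalog(catalog$onset_s[inwin], catalog$offset_s[inwin])
  }
  fm <- label_blocks(fm, catalog, preictal_len = config$preictal_len,
                     ictal_as_interictal = config$ictal_as_interictal)
  catalog <- find_lead_seizures(catalog, min_gap = config$min_lead_gap)
  fm <- make_folds(fm, k = config$n_folds)

  risks <- cross_val_risk(fm, config)
  models <- attr(risks, "models")
  span_start <- min(fm$block_start_s)
  span_end <- max(fm$block_start_s) + fm$block_len
  span <- span_end - span_start
  fiv <- fold_intervals(fm)

  has_lead <- isTRUE(config$lead_analysis) && sum(catalog$lead %in% TRUE) > 0L
  rows <- list()
  details <- list()
  for (target in config$tiw_grid) {
    theta <- rep(NA_real_, nrow(risks))
    thetas <- numeric(0)
    devs <- numeric(0)
    for (f in names(models)) {
      m <- models[[f]]
      if (!isTRUE(m$ok)) next
      win <- fiv[fiv$fold != m$fold, c("start_s", "end_s")]
      cal <- calibrate_threshold(m$train_risk, target,
                                 persistence = config$persistence,
                                 within = win)
      theta[risks$fold == m$fold] <- cal$threshold
      thetas[f] <- cal$threshold
      devs[f] <- cal$deviation
    }
    ws <- risk_to_warnings(risks, theta, persistence = config$persistence,
                           span = span_end)
    ws <- warning_set(pmax(ws$start_s, span_start), ws$end_s)
    res <- score_forecasts(ws, catalog, horizon = config$horizon, span = span)
    sig <- forecast_p_value(res, catalog, tau = config$persistence,
                            horizon = config$horizon, n_mc = config$n_mc,
                            seed = derive_seed(config$seed,
                                               paste0("chance_all_", target)))
    if (has_lead) {
      res_lead <- score_forecasts(ws, catalog, horizon = config$horizon,
                                  span = span, lead_only = TRUE)
      sig_lead <- forecast_p_value(res_lead, catalog, tau = config$persistence,
                                   horizon = config$horizon,
                                   n_mc = config$n_mc, lead_only = TRUE,
                                   seed = derive_seed(config$seed,
                                                      paste0("chance_lead_", target)))
    } else {
      res_lead <- sig_lead <- NULL
    }
    key <- sprintf("tiw_%g", target)
    details[[key]] <- list(target_tiw = target, warnings = ws,
                           result = res, significance = sig,
                           result_lead = res_lead, significance_lead = sig_lead,
                           thresholds = thetas, tiw_deviation = devs)
    rows[[key]] <- data.frame(
      subject_id = subject_id,
      target_tiw = target,
      sensitivity = res$sensitivity,
      p_value = sig$p_value,
      sensitivity_lead = if (has_lead) res_lead$sensitivity else NA_real_,
      p_value_lead = if (has_lead) sig_lead$p_value else NA_real_,
      fp_per_day = res$fp_per_day,
      realized_tiw = res$tiw,
      mean_tiw_deviation = mean(devs))
  }
  rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.unsorted(rows$realized_tiw[order(rows$target_tiw)]))
    warning("realized time in warning is not non-decreasing in the target")
  structure(list(rows = rows, details = details, risks = risks,
                 catalog = catalog,
                 provenance = list(
                   seed = config$seed,
                   n_mc = config$n_mc,
                   n_folds = config$n_folds,
                   n_features = config$n_features,
                   package_version = as.character(utils::packageVersion("pibcast")))),
            class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat("<forecast_report>\n")
  cat(render_report(x, "tsv"))
  invisible(x)
}

#' Render a forecast report as TSV, JSON, or markdown
#'
#' Sensitivities are shown to 3 decimals, p-values to 4, false positives
#' per day to 3; p-values below 0.05 carry a trailing `*`. The JSON form
#' round-trips the unrounded rows.
#'
#' @param report a `forecast_report` from [run_pipeline()].
#' @param fmt one of `"tsv"`, `"json"`, `"markdown"`.
#' @return A character string.
#' @export
render_report <- function(report, fmt = c("tsv", "json", "markdown")) {
  stopifnot(inherits(report, "forecast_report"))
  fmt <- match.arg(fmt)
  rows <- report$rows
  if (is.null(rows) || nrow(rows) == 0L) stop("report contains no rows")
  if (fmt == "json") {
    return(as.character(jsonlite::toJSON(
      list(rows = rows, provenance = report$provenance),
      auto_unbox = TRUE, digits = NA, na = "null")))
  }
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              paste0(sprintf("%.4f", p),
                                     ifelse(p < 0.05, "*", "")))
  cells <- cbind(
    ID = as.character(rows$subject_id),
    TIW = sprintf("%g", rows$target_tiw),
    S_n = sprintf("%.3f", rows$sensitivity),
    p = fmt_p(rows$p_value),
    S_n_lead = ifelse(is.na(rows$sensitivity_lead), "NA",
                      sprintf("%.3f", rows$sensitivity_lead)),
    p_lead = fmt_p(rows$p_value_lead),
    FP_per_day = sprintf("%.3f", rows$fp_per_day),
    realized_TIW = sprintf("%.3f", rows$realized_tiw))
  if (fmt == "tsv") {
    paste0(paste(colnames(cells), collapse = "\t"), "\n",
           paste(apply(cells, 1L, paste, collapse = "\t"), collapse = "\n"),
           "\n")
  } else {
    hdr <- paste0("| ", paste(colnames(cells), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
    body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(hdr, sep, body, ""), collapse = "\n")
  }
}

#' Parse a JSON report rendered by [render_report()]
#' @param txt JSON string.
#' @return list with `rows` (data frame) and `provenance`.
#' @export
parse_report_json <- function(txt) {
  jsonlite::fromJSON(txt, simplifyVector = TRUE)
}
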