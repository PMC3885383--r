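#' Label feature blocks as pre-ictal, inter-ictal, or ictal-excluded
#'
#' A block is labeled `preictal` when its start lies within
#' `[onset - preictal_len, onset)` for any seizure; pre-ictal windows from
#' clustered seizures simply union. Blocks overlapping an ictal span
#' `[onset, offset)` are labeled `ictal_excluded` (taking precedence over
#' pre-ictal) and are dropped from classifier training and testing, so the
#' classifier learns pre-seizure rather than seizure signatures; set
#' `ictal_as_interictal = TRUE` in the configuration to label them
#' inter-ictal instead. All remaining valid blocks are `interictal`;
#' invalid blocks stay unlabeled (`NA`).
#'
#' @param fm a [pib_features()] object.
#' @param catalog a [seizure_catalog()].
#' @param preictal_len pre-ictal window length before each onset (s).
#' @param ictal_as_interictal label ictal-overlapping blocks inter-ictal.
#' @return `fm` with its `label` field filled.
#' @export
label_blocks <- function(fm, catalog, preictal_len = 5400,
                         ictal_as_interictal = FALSE) {
  stopifnot(inherits(fm, "pib_features"), inherits(catalog, "seizure_catalog"))
  bs <- fm$block_start_s
  stopifnot(!is.unsorted(bs))
  lab <- ifelse(fm$valid, "interictal", NA_character_)
  bl <- fm$block_len
  for (i in seq_len(nrow(catalog))) {
    on <- catalog$onset_s[i]
    idx <- which_in_range(bs, on - preictal_len, on)
    lab[idx] <- ifelse(is.na(lab[idx]), NA_character_, "preictal")
  }
  if (!ictal_as_interictal) {
    for (i in seq_len(nrow(catalog))) {
      # block [b, b+bl) overlaps [onset, offset) iff b > onset-bl and b < offset
      idx <- which_in_range(bs, catalog$onset_s[i] - bl, catalog$offset_s[i])
      idx <- idx[bs[idx] + bl > catalog$onset_s[i]]
      lab[idx] <- ifelse(is.na(lab[idx]), NA_character_, "ictal_excluded")
    }
  }
  fm$label <- lab
  fm
}

#' Flag lead seizures
#'
#' A lead seizure is one preceded by at least `min_gap` seconds with no
#' other seizure onset; the first seizure of a record is always lead.
#'
#' @param catalog a [seizure_catalog()].
#' @param min_gap minimum preceding seizure-free gap in seconds (default 4 h).
#' @return The catalog with its `lead` column filled.
#' @export
find_lead_seizures <- function(catalog, min_gap = 14400) {
  stopifnot(inherits(catalog, "seizure_catalog"), min_gap > 0)
  n <- nrow(catalog)
  if (n == 0L) {
    catalog$lead <- logical(0)
    return(catalog)
  }
  on <- catalog$onset_s
  catalog$lead <- c(TRUE, diff(on) >= min_gap)
  catalog
}

#' Assign contiguous cross-validation folds
#'
#' Splits the record's valid blocks, in time order, into `k` contiguous
#' sub-records whose valid-block counts differ by at most one (the first
#' `n %% k` folds take the extra block). Invalid blocks get `NA`.
#'
#' @param fm a [pib_features()] object.
#' @param k number of folds; must not exceed the number of valid blocks.
#' @return `fm` with its `fold` field filled (integer ids in `1..k`).
#' @export
make_folds <- function(fm, k = 10L) {
  stopifnot(inherits(fm, "pib_features"), k >= 1L)
  vb <- which(fm$valid)
  n <- length(vb)
  if (k > n) stop(sprintf("k = %d folds but only %d valid blocks", k, n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  fold <- rep(NA_integer_, length(fm$valid))
  fold[vb] <- rep(seq_len(k), times = sizes)
  fm$fold <- fold
  fm
}

# Half-open wall-clock interval [first block start, last block end) spanned
# by each fold's valid blocks.
fold_intervals <- function(fm) {
  stopifnot(!is.null(fm$fold))
  ids <- sort(unique(fm$fold[!is.na(fm$fold)]))
  do.call(rbind, lapply(ids, function(f) {
    b <- fm$block_start_s[which(fm$fold == f)]
    data.frame(fold = f, start_s = min(b), end_s = max(b) + fm$block_len)
  }))
}
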