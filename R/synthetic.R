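#' Synthetic-study parameters
#'
#' Defaults emulate the regime of a months-long 16-channel recording at
#' 400 Hz from a subject whose seizures arrive in clusters: lead events
#' from a homogeneous Poisson process (about 5 clusters over 197 days),
#' geometric cluster sizes with mean 5.4 (echoing 27 seizures in 5
#' clusters), log-normal intra-cluster gaps with a 30-minute median, a
#' 90-minute pre-ictal window during which designated (channel, band)
#' powers are multiplied by `effect`, and invalid-data gaps covering
#' `gap_fraction` of the record.
#'
#' @param duration_s record duration in seconds.
#' @param n_channels number of channels.
#' @param fs sampling rate (Hz), raw-signal path only.
#' @param lead_rate expected lead (cluster-initiating) events per day.
#' @param cluster_size_mean mean cluster size (geometric distribution, >= 1).
#' @param intra_gap_median_s median onset-to-onset gap within a cluster (s).
#' @param intra_gap_sdlog log-scale sd of the intra-cluster gap.
#' @param seizure_duration_s fixed ictal duration assigned to each event (s).
#' @param preictal_len_s pre-ictal window length (s).
#' @param effect named vector of multiplicative power gains applied during
#'   pre-ictal windows, names matching feature columns (`ch3_alpha`, ...);
#'   `NULL` means no pre-ictal change (all gains 1).
#' @param ramp `"step"` (full gain across the window) or `"linear"` (gain
#'   ramps log-linearly from none at the window start to full at onset).
#' @param gap_fraction proportion of invalid time, in \[0, 1).
#' @param gap_mean_len_s mean length of one invalid run (s).
#' @param block_len_s feature block length (s), feature-level path.
#' @param baseline_log_mean baseline mean of log10 PIB (log10 uV^2).
#' @param baseline_log_sd baseline sd of log10 PIB.
#' @param feature_cor equicorrelation of the baseline log-PIB noise across
#'   features, in \[0, 1).
#' @param noise_alpha spectral exponent of the 1/f^alpha background
#'   (raw-signal path; 0 = white).
#' @param noise_sd background noise sd in uV (raw-signal path).
#' @param oscillations data frame with columns `channel`, `freq_hz`,
#'   `amplitude` describing band-limited sinusoidal components
#'   (raw-signal path); `NULL` for none.
#' @param memory_budget maximum `n_channels * n_samples` for raw synthesis.
#' @param seed optional integer seed applied by each generator.
#' @return An object of class `sim_params` (a named list).
#' @export
sim_params <- function(duration_s = 197 * 86400,
                       n_channels = 16L,
                       fs = 400,
                       lead_rate = 5 / 197,
                       cluster_size_mean = 5.4,
                       intra_gap_median_s = 1800,
                       intra_gap_sdlog = 0.75,
                       seizure_duration_s = 60,
                       preictal_len_s = 5400,
                       effect = NULL,
                       ramp = c("step", "linear"),
                       gap_fraction = 0.05,
                       gap_mean_len_s = 1800,
                       block_len_s = 60,
                       baseline_log_mean = 1.5,
                       baseline_log_sd = 0.4,
                       feature_cor = 0,
                       noise_alpha = 1,
                       noise_sd = 50,
                       oscillations = NULL,
                       memory_budget = 2e8,
                       seed = NULL) {
  ramp <- match.arg(ramp)
  stopifnot(duration_s > 0, n_channels >= 1L, fs > 0,
            lead_rate >= 0, cluster_size_mean >= 1,
            intra_gap_median_s > 0, intra_gap_sdlog >= 0,
            seizure_duration_s > 0, preictal_len_s > 0,
            gap_fraction >= 0, gap_fraction < 1,
            baseline_log_sd > 0, feature_cor >= 0, feature_cor < 1,
            noise_sd >= 0)
  if (!is.null(effect)) {
    stopifnot(is.numeric(effect), !is.null(names(effect)), all(effect > 0))
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate clustered seizure times
#'
#' A Poisson cluster (Neyman-Scott-like) process: cluster-initiating lead
#' events arrive as a homogeneous Poisson process at `lead_rate` per day;
#' each spawns a cluster whose size is geometric with mean
#' `cluster_size_mean` and whose successive onset gaps are log-normal with
#' median `intra_gap_median_s`. Events past the record end, and the rare
#' follower overlapping a previous event's ictal span, are dropped. Every
#' event gets the fixed ictal duration `seizure_duration_s`. The expected
#' total count is approximately
#' `lead_rate * duration_days * cluster_size_mean`.
#'
#' @param params a [sim_params()].
#' @return A [seizure_catalog()] (possibly empty).
#' @export
simulate_seizure_times <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(derive_seed(params$seed, "seizure_times"))
  days <- params$duration_s / 86400
  n_lead <- stats::rpois(1L, params$lead_rate * days)
  if (n_lead == 0L) return(seizure_catalog())
  lead_t <- sort(stats::runif(n_lead, 0, params$duration_s))
  onsets <- unlist(lapply(lead_t, function(t0) {
    size <- stats::rgeom(1L, 1 / params$cluster_size_mean) + 1L
    if (size == 1L) return(t0)
    gaps <- stats::rlnorm(size - 1L, meanlog = log(params$intra_gap_median_s),
                          sdlog = params$intra_gap_sdlog)
    t0 + c(0, cumsum(gaps))
  }))
  onsets <- sort(onsets)
  onsets <- onsets[onsets + params$seizure_duration_s <= params$duration_s]
  if (length(onsets) == 0L) return(seizure_catalog())
  # drop followers that would overlap the previous event's ictal span
  keep <- rep(TRUE, length(onsets))
  last_end <- -Inf
  for (i in seq_along(onsets)) {
    if (onsets[i] < last_end) keep[i] <- FALSE
    else last_end <- onsets[i] + params$seizure_duration_s
  }
  onsets <- onsets[keep]
  seizure_catalog(onsets, onsets + params$seizure_duration_s)
}

# Logical mask of n units with round(fraction * n) invalid units placed as
# non-overlapping runs of about mean_run units each, uniformly at random.
place_gap_runs <- function(n, fraction, mean_run) {
  total <- round(fraction * n)
  if (total <= 0L) return(rep(FALSE, n))
  k <- max(1L, round(total / mean_run))
  lens <- as.vector(stats::rmultinom(1L, total, rep(1 / k, k)))
  lens <- lens[lens > 0L]
  k <- length(lens)
  free <- n - total
  # distribute the free space over the k+1 slots around the runs
  cuts <- sort(stats::runif(k, 0, 1))
  before <- floor(cuts * (free + 1))
  starts <- before + c(0L, cumsum(lens[-k])) + 1L
  invalid <- rep(FALSE, n)
  for (i in seq_len(k)) invalid[starts[i]:(starts[i] + lens[i] - 1L)] <- TRUE
  invalid
}

# Fraction of the full pre-ictal effect applied to a block starting at bs,
# given the catalog: 0 outside any pre-ictal window; under a linear ramp,
# grows from 0 at the window start to 1 at onset (nearest window wins).
preictal_gain_fraction <- function(bs, catalog, preictal_len, ramp) {
  frac <- rep(0, length(bs))
  for (i in seq_len(nrow(catalog))) {
    on <- catalog$onset_s[i]
    idx <- which_in_range(bs, on - preictal_len, on)
    if (length(idx) == 0L) next
    f <- if (ramp == "step") 1 else (bs[idx] - (on - preictal_len)) / preictal_len
    frac[idx] <- pmax(frac[idx], f)
  }
  frac
}

#' Simulate power-in-band features directly (feature-level shortcut)
#'
#' Draws baseline log10-PIB vectors from a stationary Gaussian
#' (independent across blocks; equicorrelated across features via
#' `feature_cor`) and, for blocks whose start falls inside a pre-ictal
#' window, shifts the designated (channel, band) log-means by
#' `log10(effect)` (scaled by the ramp fraction when `ramp = "linear"`).
#' Features are returned on the PIB scale (`10^log`). Invalid blocks are
#' placed as runs covering `gap_fraction` of the grid, and labels are
#' attached with [label_blocks()]. Months-long records are cheap here,
#' unlike raw-signal synthesis.
#'
#' @param n_blocks number of blocks on the grid (starting at time 0).
#' @param catalog a [seizure_catalog()]; its events should lie within the
#'   block grid span.
#' @param params a [sim_params()].
#' @return A labeled [pib_features()] object.
#' @export
simulate_pib_features <- function(n_blocks, catalog = seizure_catalog(),
                                  params = sim_params()) {
  stopifnot(inherits(params, "sim_params"), n_blocks >= 0)
  bands <- band_definitions()
  cn <- as.vector(t(outer(seq_len(params$n_channels), bands$name,
                          function(i, b) paste0("ch", i, "_", b))))
  if (!is.null(params$effect)) {
    unknown <- setdiff(names(params$effect), cn)
    if (length(unknown) > 0L)
      stop("effect names not among simulated features: ",
           paste(unknown, collapse = ", "))
  }
  if (n_blocks == 0L)
    return(pib_features(numeric(0),
                        matrix(numeric(0), 0L, length(cn),
                               dimnames = list(NULL, cn)),
                        block_len = params$block_len_s))
  if (!is.null(params$seed)) set.seed(derive_seed(params$seed, "pib_features"))
  bs <- (seq_len(n_blocks) - 1L) * params$block_len_s
  p <- length(cn)
  G <- matrix(stats::rnorm(n_blocks * p, sd = params$baseline_log_sd),
              n_blocks, p)
  if (params$feature_cor > 0) {
    # equicorrelated noise via a shared per-block factor
    rho <- params$feature_cor
    shared <- stats::rnorm(n_blocks, sd = params$baseline_log_sd)
    G <- sqrt(1 - rho) * G + sqrt(rho) * shared
  }
  G <- G + params$baseline_log_mean
  colnames(G) <- cn
  if (!is.null(params$effect) && nrow(catalog) > 0L) {
    frac <- preictal_gain_fraction(bs, catalog, params$preictal_len_s,
                                   params$ramp)
    hit <- which(frac > 0)
    for (nm in names(params$effect))
      G[hit, nm] <- G[hit, nm] + frac[hit] * log10(params$effect[[nm]])
  }
  invalid <- place_gap_runs(n_blocks, params$gap_fraction,
                            max(1, params$gap_mean_len_s / params$block_len_s))
  X <- 10^G
  X[invalid, ] <- NA_real_
  fm <- pib_features(bs, X, valid = !invalid, block_len = params$block_len_s)
  label_blocks(fm, catalog, preictal_len = params$preictal_len_s)
}

# 1/f^alpha Gaussian noise of length n at rate fs, unit sd (alpha = 0 gives
# white noise), synthesized in the frequency domain.
colored_noise <- function(n, fs, alpha) {
  if (alpha == 0) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n  # two-sided frequency magnitudes
  g <- c(0, f[-1L]^(-alpha / 2))  # kill DC
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate a raw multichannel iEEG record
#'
#' Each channel is `1/f^alpha` colored background noise (sd `noise_sd`)
#' plus the configured band-limited sinusoidal oscillations with random
#' phases. During pre-ictal windows the amplitude of each oscillation
#' whose (channel, band) appears in `effect` is scaled by `sqrt(effect)`
#' (so its power gains `effect`), following the configured ramp. Invalid
#' runs covering `gap_fraction` of the samples are marked in the validity
#' mask. Raw synthesis is intended for short segments; the sample budget
#' guards against attempting months of raw signal.
#'
#' @param catalog a [seizure_catalog()].
#' @param params a [sim_params()]; `oscillations` gives the components.
#' @return An [ieeg_record()].
#' @export
simulate_raw_ieeg <- function(catalog = seizure_catalog(),
                              params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  n <- round(params$duration_s * params$fs)
  if (n * params$n_channels > params$memory_budget)
    stop("raw synthesis budget exceeded (", n * params$n_channels,
         " samples); use simulate_pib_features() for long records")
  if (!is.null(params$seed)) set.seed(derive_seed(params$seed, "raw_ieeg"))
  bands <- band_definitions()
  t <- (seq_len(n) - 1L) / params$fs
  # per-sample effect ramp fraction, shared across channels
  frac <- if (!is.null(params$effect) && nrow(catalog) > 0L)
    preictal_gain_fraction(t, catalog, params$preictal_len_s, params$ramp)
  else rep(0, n)
  X <- matrix(0, params$n_channels, n)
  for (ch in seq_len(params$n_channels))
    X[ch, ] <- params$noise_sd * colored_noise(n, params$fs, params$noise_alpha)
  osc <- params$oscillations
  if (!is.null(osc)) {
    stopifnot(all(c("channel", "freq_hz", "amplitude") %in% names(osc)))
    for (i in seq_len(nrow(osc))) {
      b <- which(bands$lo_hz <= osc$freq_hz[i] & osc$freq_hz[i] < bands$hi_hz)
      key <- if (length(b) == 1L) paste0("ch", osc$channel[i], "_", bands$name[b])
             else ""
      gain <- rep(1, n)
      if (!is.null(params$effect) && key %in% names(params$effect)) {
        # amplitude gain sqrt(effect) -> power gain effect, ramped
        gain <- sqrt(params$effect[[key]])^frac
      }
      phase <- stats::runif(1L, 0, 2 * pi)
      X[osc$channel[i], ] <- X[osc$channel[i], ] +
        gain * osc$amplitude[i] * sin(2 * pi * osc$freq_hz[i] * t + phase)
    }
  }
  invalid <- place_gap_runs(n, params$gap_fraction,
                            max(1, params$gap_mean_len_s * params$fs))
  ieeg_record(X, fs = params$fs, valid_mask = !invalid)
}
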