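# PREP-style quality criteria: robust (median/IQR-based) statistics with a
# robust Z threshold of 5, flatness/NaN screening, windowed correlation and
# high/low-frequency noisiness.

#' Robust standard deviation from the interquartile range
#'
#' `(Q3 - Q1) * 0.7413` with linear-interpolation quartiles. The factor
#' 0.7413 is the reciprocal of twice the standard-normal upper quartile, so
#' the estimate is consistent for the standard deviation under Gaussianity
#' while ignoring up to 25% outliers in either tail.
#'
#' @param values Numeric vector, length >= 4.
#' @param iqr_to_std The Gaussian-consistency factor.
#' @return A single non-negative number.
#' @export
#' @examples
#' robust_std(c(0, 1, 2, 3))  # 1.5 * 0.7413
robust_std <- function(values, iqr_to_std = 0.7413) {
  if (length(values) < 4L)
    stop("robust_std needs at least 4 values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  (q[2] - q[1]) * iqr_to_std
}

#' Robust Z-score
#'
#' `(x - median(x)) / robust_std(x)`. All zeros when the robust spread is 0
#' (identical values are not evidence of abnormality). `NA` entries are
#' excluded from the median and spread and stay `NA` in the output.
#'
#' @inheritParams robust_std
#' @return Numeric vector of robust Z-scores.
#' @export
robust_zscore <- function(values, iqr_to_std = 0.7413) {
  if (length(values) < 4L)
    stop("robust_zscore needs at least 4 values", call. = FALSE)
  s <- robust_std(values, iqr_to_std)
  m <- median(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(ifelse(is.na(values), NA_real_, 0))
  (values - m) / s
}

# Peak-to-peak per 2 s window for one channel; returns the fraction of
# windows whose amplitude stays below the flatness threshold.
flat_window_fraction <- function(v, S, thresh) {
  W <- length(v) %/% S
  if (W < 1L) return(0)
  X <- matrix(v[1:(W * S)], nrow = S)
  ptp <- apply(X, 2L, function(w) {
    if (anyNA(w)) return(Inf)  # NaN windows are handled by the NaN test
    max(w) - min(w)
  })
  mean(ptp < thresh)
}

#' PREP bad-channel detection
#'
#' Four criteria; (b) and (d) standardize a per-channel statistic across
#' channels with [robust_zscore()] and flag at the robust threshold
#' `cfg$prep_robust_z` (default 5):
#'
#' * `flat` - any NaN in the channel, or peak-to-peak amplitude below
#'   `cfg$flat_thresh_uv` (1e-15 microvolts) over the whole channel or in
#'   more than `cfg$prep_window_frac` (1%) of 2 s windows;
#' * `amplitude` - robust spread ([robust_std()]) of the full filtered
#'   signal, |robust Z| > threshold (both inflated and collapsed amplitude
#'   are abnormal);
#' * `correlation` - within each 2 s window the channel's maximum absolute
#'   correlation with any other channel; flagged when that maximum falls
#'   below `cfg$prep_corr_thresh` (0.4) in more than 1% of windows;
#' * `noisiness` - ratio of high- to low-frequency robust amplitude from
#'   [split_bands()] at `cfg$split_hz` (50 Hz), robust Z > threshold
#'   (one-sided: only an unusually noisy channel is bad).
#'
#' Channels flagged flat/NaN are excluded from the cross-channel
#' standardization and correlation pool of the other criteria so one dead
#' channel cannot mask another.
#'
#' @param rec An [eeg_recording()], at least 4 channels, high-pass filtered.
#' @param cfg A [qc_config()].
#' @return A `channel_qc` tibble: one row per channel.
#' @export
prep_bad_channels <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  M <- nrow(rec$data)
  if (M < 4L)
    stop("PREP channel criteria need >= 4 channels", call. = FALSE)
  x <- rec$data
  S <- round(cfg$epoch_len_s * rec$fs)   # the paper's 2 s windows
  if (ncol(x) < S)
    stop("recording shorter than one ", cfg$epoch_len_s, " s window",
         call. = FALSE)

  has_nan <- apply(x, 1L, anyNA)
  ptp_all <- apply(x, 1L, function(v) {
    r <- range(v, na.rm = TRUE); r[2] - r[1]
  })
  flat_frac <- vapply(seq_len(M), function(m)
    flat_window_fraction(x[m, ], S, cfg$flat_thresh_uv), numeric(1))
  flag_flat <- has_nan | ptp_all < cfg$flat_thresh_uv |
    flat_frac > cfg$prep_window_frac

  usable <- !flag_flat
  if (sum(usable) < 4L)
    stop("fewer than 4 usable (non-flat, non-NaN) channels", call. = FALSE)

  # (b) robust amplitude, standardized across usable channels
  amp <- rep(NA_real_, M)
  amp[usable] <- apply(x[usable, , drop = FALSE], 1L, robust_std,
                       iqr_to_std = cfg$iqr_to_std)
  z_amp <- rep(NA_real_, M)
  z_amp[usable] <- robust_zscore(amp[usable], cfg$iqr_to_std)
  flag_amp <- !is.na(z_amp) & abs(z_amp) > cfg$prep_robust_z

  # (c) windowed maximum absolute correlation among usable channels
  W <- ncol(x) %/% S
  low_frac <- rep(NA_real_, M)
  maxcorr <- matrix(NA_real_, nrow = M, ncol = W)
  ui <- which(usable)
  for (w in seq_len(W)) {
    idx <- ((w - 1) * S + 1):(w * S)
    C <- abs(suppressWarnings(cor(t(x[ui, idx, drop = FALSE]))))
    diag(C) <- NA
    mc <- apply(C, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0L) 0 else max(r)
    })
    maxcorr[ui, w] <- mc
  }
  low_frac[usable] <- rowMeans(maxcorr[usable, , drop = FALSE] <
                                 cfg$prep_corr_thresh)
  flag_corr <- !is.na(low_frac) & low_frac > cfg$prep_window_frac

  # (d) high/low-frequency noisiness ratio
  bands <- split_bands(rec, split_hz = cfg$split_hz)
  ratio <- rep(NA_real_, M)
  lo_amp <- apply(bands$low$data[usable, , drop = FALSE], 1L, robust_std,
                  iqr_to_std = cfg$iqr_to_std)
  hi_amp <- apply(bands$high$data[usable, , drop = FALSE], 1L, robust_std,
                  iqr_to_std = cfg$iqr_to_std)
  ratio[usable] <- hi_amp / lo_amp
  z_noise <- rep(NA_real_, M)
  z_noise[usable] <- robust_zscore(ratio[usable], cfg$iqr_to_std)
  flag_noise <- !is.na(z_noise) & z_noise > cfg$prep_robust_z

  qc_result("channel", rec$labels, "PREP",
            scores = list(flat_fraction = flat_frac, amplitude = amp,
                          low_correlation_fraction = low_frac,
                          noisiness = ratio),
            flags = list(flat = flag_flat, amplitude = flag_amp,
                         correlation = flag_corr, noisiness = flag_noise),
            notes = list(window_s = cfg$epoch_len_s,
                         amplitude_rule = "two-sided |robust Z| > threshold",
                         noisiness_rule = "one-sided robust Z > threshold",
                         threshold = cfg$prep_robust_z))
}

#' PREP-style bad-epoch detection
#'
#' Epoch-level extension of the robust-statistics approach: for each channel
#' and epoch, the median (location) and [robust_std()] (scale) of the epoch's
#' samples are computed; each statistic is standardized across that channel's
#' N epochs with [robust_zscore()]; the epoch-channel score is the larger of
#' the two robust-Z magnitudes, and an epoch is bad when the maximum score
#' over channels exceeds `cfg$prep_robust_z` (default 5). Both components are
#' returned so either a location-only or scale-only reading can be recovered.
#'
#' @param ep An `eeg_epochs` object, at least 4 epochs.
#' @param cfg A [qc_config()].
#' @return An `epoch_qc` tibble with per-epoch maxima of the location and
#'   scale robust Z components, the combined score and the `bad` flag.
#' @export
prep_bad_epochs <- function(ep, cfg = qc_config()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  N <- dim(ep$data)[3]
  if (N < 4L)
    stop("PREP epoch criterion needs >= 4 epochs, got ", N, call. = FALSE)
  med <- apply(ep$data, c(1, 3), median)                      # M x N
  rsd <- apply(ep$data, c(1, 3), robust_std,
               iqr_to_std = cfg$iqr_to_std)
  z_med <- t(apply(med, 1L, robust_zscore, iqr_to_std = cfg$iqr_to_std))
  z_rsd <- t(apply(rsd, 1L, robust_zscore, iqr_to_std = cfg$iqr_to_std))
  score_nm <- pmax(abs(z_med), abs(z_rsd))                    # M x N
  score <- apply(score_nm, 2L, max)
  flags <- list(robust = score > cfg$prep_robust_z)
  qc_result("epoch", seq_len(N), "PREP",
            scores = list(location_z_max = apply(abs(z_med), 2L, max),
                          scale_z_max = apply(abs(z_rsd), 2L, max),
                          robust = score),
            flags = flags,
            notes = list(statistics = "per-epoch median and robust spread, standardized per channel across epochs; score = max component magnitude, max over channels",
                         threshold = cfg$prep_robust_z))
}
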