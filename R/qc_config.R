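#' Quality-control configuration
#'
#' Bundles every numeric constant used by the detection pipeline. Defaults
#' reproduce the field protocol: 2 s epochs, 0.5 Hz high-pass before
#' detection, FASTER flags at |Z| > 3, PREP flags at robust Z > 5 with a
#' windowed-correlation threshold of 0.4 exceeded in more than 1% of 2 s
#' windows, a 48-62 Hz powerline band (covers both 50 and 60 Hz mains), a
#' 7-12 Hz alpha band, Welch spectra with 2 s windows and 50% overlap, and
#' the Gaussian-consistency factor 0.7413 converting an interquartile range
#' to a standard deviation.
#'
#' @param epoch_len_s Epoch length in seconds.
#' @param highpass_hz High-pass cutoff applied before detection, Hz.
#' @param split_hz Low-pass cutoff separating low- and high-frequency
#'   components for the PREP noisiness criterion, Hz.
#' @param faster_z FASTER Z-score threshold (magnitude).
#' @param prep_robust_z PREP robust Z-score threshold.
#' @param prep_corr_thresh PREP windowed maximum-correlation threshold.
#' @param prep_window_frac Fraction of windows allowed to fail before a
#'   channel is flagged (flatness and correlation criteria).
#' @param flat_thresh_uv Peak-to-peak amplitude, in microvolts, below which a
#'   signal counts as flat.
#' @param powerline_band_hz Two-element band (lo, hi) for the powerline
#'   criterion, Hz.
#' @param alpha_band_hz Two-element alpha band (lo, hi), Hz.
#' @param welch_window_s Welch segment length, seconds.
#' @param welch_overlap Welch segment overlap fraction in [0, 1).
#' @param bootstrap_iters Default number of bootstrap subsampling iterations.
#' @param iqr_to_std IQR-to-standard-deviation factor (Gaussian consistency).
#'
#' @return A list of class `qc_config`.
#' @export
#' @examples
#' cfg <- qc_config()
#' cfg$faster_z
qc_config <- function(epoch_len_s = 2.0,
                      highpass_hz = 0.5,
                      split_hz = 50,
                      faster_z = 3,
                      prep_robust_z = 5,
                      prep_corr_thresh = 0.4,
                      prep_window_frac = 0.01,
                      flat_thresh_uv = 1e-15,
                      powerline_band_hz = c(48, 62),
                      alpha_band_hz = c(7, 12),
                      welch_window_s = 2.0,
                      welch_overlap = 0.5,
                      bootstrap_iters = 50,
                      iqr_to_std = 0.7413) {
  cfg <- list(
    epoch_len_s = epoch_len_s, highpass_hz = highpass_hz, split_hz = split_hz,
    faster_z = faster_z, prep_robust_z = prep_robust_z,
    prep_corr_thresh = prep_corr_thresh, prep_window_frac = prep_window_frac,
    flat_thresh_uv = flat_thresh_uv, powerline_band_hz = powerline_band_hz,
    alpha_band_hz = alpha_band_hz, welch_window_s = welch_window_s,
    welch_overlap = welch_overlap, bootstrap_iters = bootstrap_iters,
    iqr_to_std = iqr_to_std
  )
  scalars <- c("epoch_len_s", "highpass_hz", "split_hz", "faster_z",
               "prep_robust_z", "prep_corr_thresh", "prep_window_frac",
               "flat_thresh_uv", "welch_window_s", "bootstrap_iters",
               "iqr_to_std")
  for (nm in scalars) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("qc_config: `", nm, "` must be a single positive number", call. = FALSE)
  }
  if (welch_overlap < 0 || welch_overlap >= 1)
    stop("qc_config: `welch_overlap` must lie in [0, 1)", call. = FALSE)
  for (nm in c("powerline_band_hz", "alpha_band_hz")) {
    b <- cfg[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("qc_config: `", nm, "` must be (lo, hi) with 0 < lo < hi", call. = FALSE)
  }
  structure(cfg, class = "qc_config")
}

# Band must sit below Nyquist when actually used against a sampled recording.
check_band <- function(band, fs, what) {
  if (band[2] >= fs / 2)
    stop(what, ": band upper edge ", band[2], " Hz is not below Nyquist (fs/2 = ",
         fs / 2, " Hz)", call. = FALSE)
  invisible(band)
}
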