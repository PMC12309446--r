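# FASTER-style quality criteria: per-channel / per-epoch statistics are
# standardized into Z-scores across channels (or epochs) and flagged at
# magnitude > 3.

#' Sample Z-score
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (denominator
#' n - 1). A degenerate spread (sd of 0) yields all zeros: identical values
#' carry no evidence of abnormality. `NA` entries are excluded from the mean
#' and sd and stay `NA` in the output.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of Z-scores.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(values) {
  if (length(values) < 2L)
    stop("zscore needs at least 2 values", call. = FALSE)
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(ifelse(is.na(values), NA_real_, 0))
  (values - m) / s
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classical R/S estimate: for dyadic block sizes from 16 up to length/4 the
#' series is split into non-overlapping blocks, each block's range of
#' mean-adjusted cumulative sums is divided by its standard deviation, and
#' the Hurst exponent is the least-squares slope of log mean(R/S) against log
#' block size. White noise gives values near 0.5 (with a small upward
#' small-sample bias); strongly persistent or non-EEG-like signals drift
#' toward 1.
#'
#' @param series Numeric vector, length >= 128, non-constant.
#' @param min_block Smallest block size (default 16).
#' @return The Hurst exponent estimate (a single number).
#' @export
#' @examples
#' hurst_exponent(rnorm(1024))
hurst_exponent <- function(series, min_block = 16L) {
  n <- length(series)
  if (n < 128L)
    stop("series too short for R/S analysis (need >= 128 samples, got ", n, ")",
         call. = FALSE)
  if (anyNA(series) || sd(series) == 0)
    stop("constant or NA series: Hurst exponent undefined", call. = FALSE)
  sizes <- 2^(seq.int(log2(min_block), floor(log2(n / 4))))
  rs_mean <- vapply(sizes, function(b) {
    k <- n %/% b
    X <- matrix(series[1:(k * b)], nrow = b)
    X <- sweep(X, 2L, colMeans(X))
    cs <- apply(X, 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = b)
    R <- apply(cs, 2L, max) - apply(cs, 2L, min)
    S <- apply(X, 2L, sd)
    ok <- S > 0
    if (!any(ok)) return(NA_real_)
    mean(R[ok] / S[ok])
  }, numeric(1))
  ok <- is.finite(rs_mean) & rs_mean > 0
  stats::lsfit(log(sizes[ok]), log(rs_mean[ok]))$coefficients[2]
}

# Assemble a wide channel/epoch QC tibble from named score vectors and a
# threshold rule returning logical flags.
qc_result <- function(unit, ids, method, scores, flags, notes = NULL) {
  out <- tibble(!!unit := ids, method = method)
  for (nm in names(scores)) out[[paste0("score_", nm)]] <- unname(scores[[nm]])
  for (nm in names(flags)) out[[paste0("flag_", nm)]] <- unname(flags[[nm]])
  out$bad <- unname(Reduce(`|`, lapply(flags, function(f) f & !is.na(f))))
  class(out) <- c(paste0(unit, "_qc"), class(out))
  attr(out, "method") <- method
  attr(out, "notes") <- notes
  out
}

#' FASTER bad-channel detection
#'
#' Four per-channel statistics, each standardized across channels with
#' [zscore()] and flagged at |Z| > `cfg$faster_z` (default 3):
#'
#' * `correlation` - mean absolute Pearson correlation of the channel against
#'   every other channel over the full recording (no distance weighting);
#' * `variance` - signal variance;
#' * `hurst` - [hurst_exponent()] of the channel;
#' * `powerline` - mean Welch power spectral density in the powerline band
#'   (48-62 Hz by default, covering both 50 and 60 Hz mains).
#'
#' A channel is bad if any criterion flags it. The recording should already be
#' high-pass filtered (see [highpass()]).
#'
#' @param rec An [eeg_recording()], at least 4 channels.
#' @param cfg A [qc_config()].
#' @return A `channel_qc` tibble: one row per channel with `score_*`,
#'   `flag_*` and `bad` columns.
#' @export
faster_bad_channels <- function(rec, cfg = qc_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  M <- nrow(rec$data)
  if (M < 4L)
    stop("FASTER channel criteria need >= 4 channels (Z-scores across ",
         M, " channels are meaningless)", call. = FALSE)
  check_band(cfg$powerline_band_hz, rec$fs, "powerline criterion")
  x <- rec$data

  C <- suppressWarnings(cor(t(x)))
  diag(C) <- NA
  mean_abs_corr <- rowMeans(abs(C), na.rm = TRUE)
  mean_abs_corr[!is.finite(mean_abs_corr)] <- 0  # constant channel: no correlation

  variance <- apply(x, 1L, var)

  hurst <- vapply(seq_len(M), function(m) {
    tryCatch(hurst_exponent(x[m, ]), error = function(e) NA_real_)
  }, numeric(1))

  psd <- welch_psd(rec, window_s = cfg$welch_window_s,
                   overlap = cfg$welch_overlap)
  band <- psd$freqs >= cfg$powerline_band_hz[1] &
    psd$freqs <= cfg$powerline_band_hz[2]
  powerline <- rowMeans(psd$power[, band, drop = FALSE])

  scores <- list(correlation = mean_abs_corr, variance = variance,
                 hurst = hurst, powerline = powerline)
  flags <- lapply(scores, function(s) abs(zscore(s)) > cfg$faster_z)
  qc_result("channel", rec$labels, "FASTER", scores, flags,
            notes = list(flag_rule = "two-sided |Z| > threshold on all criteria",
                         correlation_statistic = "mean absolute Pearson correlation, unweighted",
                         threshold = cfg$faster_z))
}

#' FASTER bad-epoch detection
#'
#' Three per-epoch statistics, each standardized across the N epochs with
#' [zscore()] and flagged at |Z| > `cfg$faster_z`:
#'
#' * `range` - amplitude range (max - min) within the epoch, averaged across
#'   channels;
#' * `variance` - within-epoch variance, averaged across channels;
#' * `deviation` - the epoch mean of each channel minus that channel's
#'   average epoch mean over all epochs (N x M deviation values), averaged
#'   across the M channels into N deviation parameters.
#'
#' @param ep An `eeg_epochs` object (see [epoch_recording()]), at least 4
#'   epochs.
#' @param cfg A [qc_config()].
#' @return An `epoch_qc` tibble: one row per epoch.
#' @export
faster_bad_epochs <- function(ep, cfg = qc_config()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  N <- dim(ep$data)[3]
  if (N < 4L)
    stop("FASTER epoch criteria need >= 4 epochs, got ", N, call. = FALSE)
  rng_nm <- apply(ep$data, c(1, 3), function(v) max(v) - min(v))  # M x N
  var_nm <- apply(ep$data, c(1, 3), var)
  em <- apply(ep$data, c(1, 3), mean)                             # M x N
  dev_nm <- em - rowMeans(em)
  scores <- list(range = colMeans(rng_nm), variance = colMeans(var_nm),
                 deviation = colMeans(dev_nm))
  flags <- lapply(scores, function(s) abs(zscore(s)) > cfg$faster_z)
  qc_result("epoch", seq_len(N), "FASTER", scores, flags,
            notes = list(deviation_reference = "channel-wise mean of epoch means",
                         threshold = cfg$faster_z))
}
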