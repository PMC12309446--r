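# Welch power spectral density and peak alpha frequency.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper: the signal is cut into
#' segments of `window_s` seconds overlapping by `overlap`, each segment is
#' tapered and Fourier transformed, and the one-sided periodograms are
#' averaged. Frequency resolution is `1/window_s` (0.5 Hz at the default 2 s
#' window). Power is returned in microvolts squared per Hz, so integrating
#' the spectrum over frequency recovers the signal variance.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `eeg_psd`: list with `freqs` (Hz), `power`
#'   (channels x frequencies matrix), `resolution` (Hz), `fs`, `labels`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 2560), 2), fs = 256,
#'                      labels = c("O1", "O2"))
#' psd <- welch_psd(rec)
#' psd$resolution
welch_psd <- function(rec, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  fs <- rec$fs
  S <- round(window_s * fs)
  T_ <- ncol(rec$data)
  if (T_ < S)
    stop("recording too short for a ", window_s, " s Welch window", call. = FALSE)
  step <- max(1L, round(S * (1 - overlap)))
  starts <- seq.int(1L, T_ - S + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, S - 1) / (S - 1)))   # Hann taper
  U <- sum(w^2)
  nfreq <- S %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / S
  M <- nrow(rec$data)
  power <- matrix(0, nrow = M, ncol = nfreq,
                  dimnames = list(rec$labels, NULL))
  for (m in seq_len(M)) {
    segs <- vapply(starts, function(s0) rec$data[m, s0:(s0 + S - 1L)] * w,
                   numeric(S))
    X <- stats::mvfft(segs)
    P <- rowMeans(Mod(X[seq_len(nfreq), , drop = FALSE])^2) / (fs * U)
    P[2:(nfreq - 1L)] <- 2 * P[2:(nfreq - 1L)]  # one-sided: double interior bins
    power[m, ] <- P
  }
  structure(list(freqs = freqs, power = power, resolution = 1 / window_s,
                 fs = fs, labels = rec$labels),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat("<eeg_psd> ", nrow(x$power), " channels, ", length(x$freqs),
      " bins 0-", max(x$freqs), " Hz @ ", x$resolution, " Hz resolution\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.eeg_psd <- function(x, ...) {
  tibble(channel = rep(x$labels, each = length(x$freqs)),
         freq_hz = rep(x$freqs, times = nrow(x$power)),
         power = as.vector(t(x$power)))
}

#' Peak alpha frequency
#'
#' The frequency of the maximum power-spectral-density bin within the alpha
#' band (7-12 Hz inclusive), from a Welch spectrum with 2 s windows and 50%
#' overlap (0.5 Hz bins). The peak is the raw argmax bin, with ties broken
#' toward the lower frequency; no interpolation or 1/f correction is applied.
#' Returned per channel, as the mean across channels, and as the peak of the
#' channel-averaged spectrum (the two summaries can differ; both are
#' labelled).
#'
#' @param rec An [eeg_recording()]; intended for the eyes-closed (EC)
#'   condition, a warning is issued otherwise.
#' @param band Alpha band (lo, hi) in Hz, endpoints inclusive.
#' @param window_s,overlap Welch parameters (see [welch_psd()]).
#' @return An object of class `paf_estimate`: list with `per_channel`
#'   (tibble of `channel`, `paf_hz`), `mean_paf_hz`, `avg_spectrum_paf_hz`.
#' @export
peak_alpha_frequency <- function(rec, band = c(7, 12), window_s = 2,
                                 overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$condition != "EC")
    warning("peak alpha frequency is defined for the eyes-closed (EC) ",
            "condition; this recording is ", rec$condition)
  psd <- welch_psd(rec, window_s = window_s, overlap = overlap)
  if (psd$resolution > 0.5)
    warning("PSD resolution ", psd$resolution,
            " Hz is coarser than the intended 0.5 Hz")
  sel <- which(psd$freqs >= band[1] & psd$freqs <= band[2])
  if (length(sel) == 0L)
    stop("no spectral bins inside the alpha band [", band[1], ", ", band[2],
         "] Hz", call. = FALSE)
  f_band <- psd$freqs[sel]
  per <- apply(psd$power[, sel, drop = FALSE], 1L,
               function(p) f_band[which.max(p)])
  avg_spec <- colMeans(psd$power[, sel, drop = FALSE])
  structure(
    list(per_channel = tibble(channel = psd$labels, paf_hz = unname(per)),
         mean_paf_hz = mean(per),
         avg_spectrum_paf_hz = f_band[which.max(avg_spec)],
         band = band),
    class = "paf_estimate"
  )
}

#' @export
print.paf_estimate <- function(x, ...) {
  cat("<paf_estimate> mean of per-channel peaks: ",
      round(x$mean_paf_hz, 2), " Hz; peak of channel-averaged spectrum: ",
      x$avg_spectrum_paf_hz, " Hz (band ", x$band[1], "-", x$band[2],
      " Hz)\n", sep = "")
  invisible(x)
}

#' @export
tidy.paf_estimate <- function(x, ...) x$per_channel
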