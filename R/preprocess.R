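# Zero-phase FIR filtering and epoching applied before quality detection.

# Hamming-window FIR design; transition bandwidth ~ 3.3/N in normalized
# frequency, so taps = ceiling(3.3 * fs / transition), forced odd (type I,
# exactly linear phase, integer group delay).
design_fir <- function(fs, cutoff_hz, type = c("low", "high"),
                       transition_hz) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must satisfy 0 < cutoff < fs/2", call. = FALSE)
  n_taps <- ceiling(3.3 * fs / transition_hz)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  h <- signal::fir1(n_taps - 1, cutoff_hz / (fs / 2), type)
  if (type == "high") h <- h - sum(h) / length(h)  # exact DC null
  as.numeric(h)
}

# Apply a symmetric FIR with zero phase: reflect-pad by one filter length,
# FFT convolution, compensate the (L-1)/2 group delay, crop the padding.
fir_filter_zerophase <- function(x, h) {
  L <- length(h)
  n <- length(x)
  if (n <= L)
    stop("recording too short for the filter transient (need > ", L,
         " samples, got ", n, ")", call. = FALSE)
  left <- 2 * x[1] - x[(L + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - L)]
  xp <- c(left, x, right)
  m <- length(xp)
  nf <- 2^ceiling(log2(m + L))
  y <- Re(fft(fft(c(xp, numeric(nf - m))) * fft(c(h, numeric(nf - L))),
              inverse = TRUE)) / nf
  d <- (L - 1) %/% 2
  y[(L + d + 1):(L + d + n)]
}

filter_recording <- function(rec, h) {
  out <- rec
  out$data <- t(apply(rec$data, 1, fir_filter_zerophase, h = h))
  rownames(out$data) <- rec$labels
  out
}

#' High-pass filter a recording
#'
#' Zero-phase FIR high-pass (Hamming-window design, symmetric taps applied
#' with group-delay compensation) used to remove drift before bad-channel and
#' bad-epoch detection. Length and metadata are preserved; edges are
#' reflect-padded by one filter length so the first epoch is not contaminated
#' by a startup transient.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff_hz Cutoff frequency in Hz (default 0.5).
#' @param transition_hz Transition bandwidth in Hz; defaults to `cutoff_hz`
#'   (0.5 Hz at the default cutoff).
#' @return A filtered [eeg_recording()].
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 2048), 4), fs = 256,
#'                      labels = paste0("CH", 1:4))
#' filt <- highpass(rec)
highpass <- function(rec, cutoff_hz = 0.5, transition_hz = cutoff_hz) {
  stopifnot(inherits(rec, "eeg_recording"))
  h <- design_fir(rec$fs, cutoff_hz, "high", transition_hz)
  filter_recording(rec, h)
}

#' Split a recording into low- and high-frequency components
#'
#' A zero-phase FIR low-pass at `split_hz` gives the low component; the high
#' component is the sample-aligned residual, so `low + high` reconstructs the
#' input exactly. Used by the PREP noisiness criterion (high/low amplitude
#' ratio at a 50 Hz split).
#'
#' @param rec An [eeg_recording()].
#' @param split_hz Split frequency in Hz (default 50).
#' @param transition_hz Transition bandwidth in Hz (default 5).
#' @return A list with elements `low` and `high`, both [eeg_recording()]s.
#' @export
split_bands <- function(rec, split_hz = 50, transition_hz = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (split_hz >= rec$fs / 2)
    stop("`split_hz` must be below Nyquist (fs/2 = ", rec$fs / 2, " Hz)",
         call. = FALSE)
  h <- design_fir(rec$fs, split_hz, "low", transition_hz)
  low <- filter_recording(rec, h)
  high <- rec
  high$data <- rec$data - low$data
  list(low = low, high = high)
}

#' Cut a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping epochs of `epoch_len_s` seconds; a trailing
#' partial epoch is discarded. Concatenating the epochs in order reproduces
#' the first `N * S` samples of the input exactly.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_len_s Epoch length in seconds (default 2).
#' @return An object of class `eeg_epochs` with `data` of dimension
#'   channels x samples-per-epoch x epochs.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 1280), 4), fs = 256,
#'                      labels = paste0("CH", 1:4))
#' ep <- epoch_recording(rec)
#' dim(ep$data)  # 4 x 512 x 2
epoch_recording <- function(rec, epoch_len_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  S <- round(epoch_len_s * rec$fs)
  T_ <- ncol(rec$data)
  if (T_ < S)
    stop("recording too short to epoch: ", T_, " samples < one epoch of ",
         S, " samples", call. = FALSE)
  N <- T_ %/% S
  arr <- array(rec$data[, 1:(N * S), drop = FALSE], dim = c(nrow(rec$data), S, N),
               dimnames = list(rec$labels, NULL, NULL))
  structure(
    list(data = arr, fs = rec$fs, epoch_len_s = epoch_len_s,
         labels = rec$labels, condition = rec$condition, session = rec$session),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[3], " epochs x ", d[1], " channels x ", d[2],
      " samples (", x$epoch_len_s, " s @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}
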