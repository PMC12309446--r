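# Small in-code fixtures shared across tests.

# Correlated multichannel toy: one dominant shared source plus per-channel
# noise, so clean channels look like plausible (mutually correlated) EEG.
make_toy_rec <- function(M = 8, fs = 256, dur_s = 16, seed = 1,
                         noise_sd = 0.3, condition = "EC") {
  withr::with_seed(seed, {
    T_ <- round(dur_s * fs)
    common <- stats::rnorm(T_)
    x <- outer(rep(1, M), common) + matrix(stats::rnorm(M * T_, sd = noise_sd),
                                           nrow = M)
    eeg_recording(x, fs = fs, labels = sprintf("CH%02d", 1:M),
                  condition = condition)
  })
}

# Fractional Gaussian noise by spectral synthesis: PSD ~ 1/f^(2H-1).
# Independent of the package's pink-noise generator (written as a plain loop
# over spectrum bins).
make_fgn <- function(n, H, seed = 1) {
  withr::with_seed(seed, {
    nf <- n %/% 2
    spec <- complex(real = numeric(nf), imaginary = numeric(nf))
    for (k in seq_len(nf)) {
      f <- k / n
      a <- f^(-(2 * H - 1) / 2)
      spec[k] <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1)) * a
    }
    if (n %% 2 == 0) spec[nf] <- complex(real = Re(spec[nf]), imaginary = 0)
    full <- if (n %% 2 == 0) c(0, spec, Conj(rev(spec[seq_len(nf - 1)])))
            else c(0, spec, Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE))
    (x - mean(x)) / stats::sd(x)
  })
}
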