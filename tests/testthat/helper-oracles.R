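# Naive loop-based reference implementations of the detection criteria,
# written independently of the package's vectorized code paths. Used to
# check exact agreement of statistics and flags on small inputs.

oracle_zscore <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  if (s == 0) return(rep(0, length(v)))
  (v - m) / s
}

oracle_robust_sd <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) * 0.7413
}

oracle_robust_z <- function(v) {
  s <- oracle_robust_sd(v)
  if (s == 0) return(rep(0, length(v)))
  (v - stats::median(v)) / s
}

oracle_hurst <- function(x, min_block = 16) {
  n <- length(x)
  sizes <- c(); rs <- c()
  b <- min_block
  while (b <= n / 4) {
    k <- floor(n / b)
    vals <- c()
    for (j in seq_len(k)) {
      blk <- x[((j - 1) * b + 1):(j * b)]
      if (stats::sd(blk) > 0) {
        z <- cumsum(blk - mean(blk))
        vals <- c(vals, (max(z) - min(z)) / stats::sd(blk))
      }
    }
    sizes <- c(sizes, b); rs <- c(rs, mean(vals))
    b <- b * 2
  }
  unname(stats::coef(stats::lm(log(rs) ~ log(sizes)))[2])
}

# Welch PSD for a single channel, plain loop over segments.
oracle_welch <- function(v, fs, window_s = 2, overlap = 0.5) {
  S <- round(window_s * fs)
  step <- round(S * (1 - overlap))
  starts <- seq(1, length(v) - S + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(S - 1)) / (S - 1)))
  U <- sum(w^2)
  nf <- S %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    X <- stats::fft(v[s0:(s0 + S - 1)] * w)
    acc <- acc + Mod(X[1:nf])^2 / (fs * U)
  }
  P <- acc / length(starts)
  P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
  list(freqs = (0:(nf - 1)) * fs / S, power = P)
}

# FASTER channel flags by explicit per-channel loops.
oracle_faster_channels <- function(rec, cfg = qc_config()) {
  x <- rec$data; M <- nrow(x)
  corr <- var_ <- hurst <- pline <- numeric(M)
  for (m in seq_len(M)) {
    cs <- c()
    for (k in seq_len(M)) if (k != m) cs <- c(cs, abs(stats::cor(x[m, ], x[k, ])))
    corr[m] <- mean(cs)
    var_[m] <- stats::var(x[m, ])
    hurst[m] <- oracle_hurst(x[m, ])
    pw <- oracle_welch(x[m, ], rec$fs, cfg$welch_window_s, cfg$welch_overlap)
    sel <- pw$freqs >= cfg$powerline_band_hz[1] &
      pw$freqs <= cfg$powerline_band_hz[2]
    pline[m] <- mean(pw$power[sel])
  }
  scores <- list(correlation = corr, variance = var_, hurst = hurst,
                 powerline = pline)
  flags <- lapply(scores, function(s) abs(oracle_zscore(s)) > cfg$faster_z)
  list(scores = scores, flags = flags,
       bad = flags$correlation | flags$variance | flags$hurst | flags$powerline)
}

# FASTER epoch flags by explicit loops over epochs and channels.
oracle_faster_epochs <- function(ep, cfg = qc_config()) {
  arr <- ep$data
  M <- dim(arr)[1]; N <- dim(arr)[3]
  rng <- vr <- dv <- numeric(N)
  em <- matrix(0, M, N)
  for (m in seq_len(M)) for (n in seq_len(N)) em[m, n] <- mean(arr[m, , n])
  for (n in seq_len(N)) {
    r <- v <- d <- numeric(M)
    for (m in seq_len(M)) {
      r[m] <- max(arr[m, , n]) - min(arr[m, , n])
      v[m] <- stats::var(arr[m, , n])
      d[m] <- em[m, n] - mean(em[m, ])
    }
    rng[n] <- mean(r); vr[n] <- mean(v); dv[n] <- mean(d)
  }
  scores <- list(range = rng, variance = vr, deviation = dv)
  flags <- lapply(scores, function(s) abs(oracle_zscore(s)) > cfg$faster_z)
  list(scores = scores, flags = flags,
       bad = flags$range | flags$variance | flags$deviation)
}

# PREP channel flags by explicit loops (reuses the package band splitter,
# which is shared plumbing, not detection logic).
oracle_prep_channels <- function(rec, cfg = qc_config()) {
  x <- rec$data; M <- nrow(x)
  S <- round(cfg$epoch_len_s * rec$fs)
  W <- floor(ncol(x) / S)
  flat <- logical(M)
  for (m in seq_len(M)) {
    nwin_flat <- 0
    for (w in seq_len(W)) {
      blk <- x[m, ((w - 1) * S + 1):(w * S)]
      if (!anyNA(blk) && max(blk) - min(blk) < cfg$flat_thresh_uv)
        nwin_flat <- nwin_flat + 1
    }
    flat[m] <- anyNA(x[m, ]) ||
      (max(x[m, ], na.rm = TRUE) - min(x[m, ], na.rm = TRUE)) < cfg$flat_thresh_uv ||
      nwin_flat / W > cfg$prep_window_frac
  }
  ui <- which(!flat)
  amp <- numeric(length(ui))
  for (j in seq_along(ui)) amp[j] <- oracle_robust_sd(x[ui[j], ])
  za <- oracle_robust_z(amp)
  flag_amp <- logical(M); flag_amp[ui] <- abs(za) > cfg$prep_robust_z
  flag_corr <- logical(M)
  for (j in seq_along(ui)) {
    m <- ui[j]; nlow <- 0
    for (w in seq_len(W)) {
      idx <- ((w - 1) * S + 1):(w * S)
      best <- 0
      for (k in ui) if (k != m) {
        r <- abs(stats::cor(x[m, idx], x[k, idx]))
        if (!is.na(r) && r > best) best <- r
      }
      if (best < cfg$prep_corr_thresh) nlow <- nlow + 1
    }
    flag_corr[m] <- nlow / W > cfg$prep_window_frac
  }
  bands <- split_bands(rec, split_hz = cfg$split_hz)
  ratio <- numeric(length(ui))
  for (j in seq_along(ui))
    ratio[j] <- oracle_robust_sd(bands$high$data[ui[j], ]) /
      oracle_robust_sd(bands$low$data[ui[j], ])
  zr <- oracle_robust_z(ratio)
  flag_noise <- logical(M); flag_noise[ui] <- zr > cfg$prep_robust_z
  list(flags = list(flat = flat, amplitude = flag_amp,
                    correlation = flag_corr, noisiness = flag_noise),
       bad = flat | flag_amp | flag_corr | flag_noise)
}

# PREP epoch flags by explicit loops.
oracle_prep_epochs <- function(ep, cfg = qc_config()) {
  arr <- ep$data
  M <- dim(arr)[1]; N <- dim(arr)[3]
  score <- matrix(0, M, N)
  for (m in seq_len(M)) {
    med <- rsd <- numeric(N)
    for (n in seq_len(N)) {
      med[n] <- stats::median(arr[m, , n])
      rsd[n] <- oracle_robust_sd(arr[m, , n])
    }
    zm <- oracle_robust_z(med); zs <- oracle_robust_z(rsd)
    for (n in seq_len(N)) score[m, n] <- max(abs(zm[n]), abs(zs[n]))
  }
  epoch_score <- apply(score, 2, max)
  list(score = epoch_score, bad = epoch_score > cfg$prep_robust_z)
}
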