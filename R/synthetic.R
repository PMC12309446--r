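# Seeded synthetic resting-state EEG with ground-truth artifact labels.
# Emulates the field protocol: 16 channels at 256 Hz, 3 minutes, a 1/f
# background shared across channels, a posterior-weighted alpha rhythm,
# optional mains contamination, and injectable artifacts.

artifact_kinds <- c("flat_channel", "noisy_channel", "uncorrelated_channel",
                    "burst_epoch", "blink")

#' Specification of a synthetic recording
#'
#' Defaults describe the field protocol: 16 channels, 256 Hz, 3 minutes,
#' eyes closed. The background is a mixture of shared pink-noise sources
#' (guaranteeing clean channels stay mutually correlated within 2 s windows)
#' plus per-channel white noise; the alpha rhythm is an amplitude-modulated
#' sinusoid at `alpha_freq_hz`, weighted toward posterior channels. Artifact
#' magnitudes are calibration choices, not field measurements.
#'
#' @param n_channels,fs,duration_s Geometry: channel count, sampling rate
#'   (Hz), duration (seconds).
#' @param condition Recording condition label.
#' @param background_exponent Spectral exponent of the 1/f background (PSD
#'   proportional to `1/f^exponent`).
#' @param background_amp_uv Background standard deviation per channel,
#'   microvolts.
#' @param noise_amp_uv Per-channel white-noise standard deviation,
#'   microvolts.
#' @param alpha_freq_hz Alpha peak frequency, within 7-12 Hz.
#' @param alpha_amp_uv Alpha sinusoid amplitude, microvolts.
#' @param alpha_mod_depth Depth of the slow (0.1 Hz) amplitude modulation in
#'   `[0, 1)`.
#' @param alpha_weights Optional per-channel alpha weights; default is a
#'   frontal-to-posterior gradient from 0.5 to 1.5 over the channel order
#'   (the default montage is ordered front to back).
#' @param line_freq_hz Mains frequency (50 or 60 Hz) or `NULL` for none.
#' @param line_amp_uv Mains amplitude, microvolts.
#' @param line_channels Channel indices receiving mains; default all.
#' @param artifacts List of artifact descriptors, each a list with `kind`
#'   (one of `r paste(artifact_kinds, collapse = ", ")`), a target `channel`
#'   and/or `epoch` index, and an optional `magnitude` (microvolts).
#' @param labels Channel labels; defaults to the standard 16-channel montage
#'   when `n_channels` is 16, else `CH01, CH02, ...`.
#' @param seed Integer seed; the same spec and seed reproduce the recording
#'   bit for bit.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 16, fs = 256, duration_s = 180,
                           condition = "EC",
                           background_exponent = 1.0, background_amp_uv = 15,
                           noise_amp_uv = 2,
                           alpha_freq_hz = 10, alpha_amp_uv = 8,
                           alpha_mod_depth = 0.3, alpha_weights = NULL,
                           line_freq_hz = NULL, line_amp_uv = 0,
                           line_channels = NULL,
                           artifacts = list(), labels = NULL, seed = 1) {
  errors <- character()
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(n_channels >= 1, "n_channels must be >= 1")
  chk(fs > 0, "fs must be positive")
  chk(duration_s > 0, "duration_s must be positive")
  chk(alpha_freq_hz >= 7 && alpha_freq_hz <= 12,
      "alpha_freq_hz must lie in [7, 12]")
  for (nm in c("background_amp_uv", "noise_amp_uv", "alpha_amp_uv",
               "line_amp_uv"))
    chk(get(nm) >= 0, paste(nm, "must be >= 0"))
  chk(alpha_mod_depth >= 0 && alpha_mod_depth < 1,
      "alpha_mod_depth must lie in [0, 1)")
  if (!is.null(line_freq_hz))
    chk(line_freq_hz %in% c(50, 60), "line_freq_hz must be 50 or 60")
  n_epochs <- floor(duration_s / 2)
  for (a in artifacts) {
    if (is.null(a$kind) || !a$kind %in% artifact_kinds) {
      chk(FALSE, paste0("unknown artifact kind '", a$kind %||% "<missing>", "'"))
      next
    }
    if (a$kind %in% c("flat_channel", "noisy_channel", "uncorrelated_channel",
                      "burst_epoch"))
      chk(!is.null(a$channel) && a$channel >= 1 && a$channel <= n_channels,
          paste0(a$kind, ": channel index out of range"))
    if (a$kind %in% c("burst_epoch", "blink"))
      chk(!is.null(a$epoch) && a$epoch >= 1 && a$epoch <= n_epochs,
          paste0(a$kind, ": epoch index out of range"))
    if (!is.null(a$magnitude)) chk(a$magnitude >= 0,
                                   paste0(a$kind, ": magnitude must be >= 0"))
  }
  if (length(errors) > 0)
    stop("invalid synthetic spec:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(labels)) {
    labels <- if (n_channels == 16) default_montage()$label[1:16]
              else sprintf("CH%02d", seq_len(n_channels))
  }
  if (is.null(alpha_weights))
    alpha_weights <- seq(0.5, 1.5, length.out = n_channels)
  structure(
    list(n_channels = n_channels, fs = fs, duration_s = duration_s,
         condition = condition,
         background_exponent = background_exponent,
         background_amp_uv = background_amp_uv, noise_amp_uv = noise_amp_uv,
         alpha_freq_hz = alpha_freq_hz, alpha_amp_uv = alpha_amp_uv,
         alpha_mod_depth = alpha_mod_depth, alpha_weights = alpha_weights,
         line_freq_hz = line_freq_hz, line_amp_uv = line_amp_uv,
         line_channels = line_channels,
         artifacts = artifacts, labels = labels, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1/f^(exponent) noise by spectral synthesis, unit standard deviation.
pink_noise <- function(n, exponent) {
  nf <- n %/% 2
  f <- seq_len(nf) / n
  amp <- f^(-exponent / 2)
  re <- stats::rnorm(nf); im <- stats::rnorm(nf)
  spec <- complex(real = re, imaginary = im) * amp
  if (n %% 2 == 0) {
    spec[nf] <- complex(real = Re(spec[nf]), imaginary = 0)  # Nyquist bin real
    X <- c(0, spec, Conj(rev(spec[seq_len(nf - 1L)])))
  } else {
    X <- c(0, spec, Conj(rev(spec)))
  }
  x <- Re(fft(X, inverse = TRUE))
  x / sd(x)
}

#' Generate a synthetic recording with ground truth
#'
#' Fully reproducible from the spec's seed (the global RNG state is
#' restored). Clean channels share dominant pink-noise sources and a
#' coherent alpha rhythm, so their pairwise windowed correlations stay well
#' above the PREP threshold of 0.4; injected artifacts are recorded in the
#' returned ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param session Optional [session_meta()] attached to the recording.
#' @return A list with `recording` (an [eeg_recording()]) and `truth`
#'   (`bad_channels` and `bad_epochs` tibbles with artifact kinds, and
#'   `true_paf_hz`).
#' @export
#' @examples
#' sim <- generate_recording(synthetic_spec(duration_s = 10, seed = 7))
#' sim$truth$true_paf_hz
generate_recording <- function(spec, session = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_recording_impl(spec, session))
}

generate_recording_impl <- function(spec, session) {
  M <- spec$n_channels; fs <- spec$fs
  T_ <- round(spec$duration_s * fs)
  t <- (seq_len(T_) - 1) / fs
  K <- 4L

  src <- t(vapply(seq_len(K), function(k)
    pink_noise(T_, spec$background_exponent), numeric(T_)))
  A <- cbind(rep(1, M),
             matrix(stats::runif(M * (K - 1L), -0.4, 0.4), nrow = M))
  background <- A %*% src
  background <- background / apply(background, 1L, sd) * spec$background_amp_uv

  phase <- stats::runif(1, 0, 2 * pi)
  mod_phase <- stats::runif(1, 0, 2 * pi)
  envelope <- 1 + spec$alpha_mod_depth * sin(2 * pi * 0.1 * t + mod_phase)
  carrier <- envelope * sin(2 * pi * spec$alpha_freq_hz * t + phase)
  alpha <- outer(spec$alpha_weights * spec$alpha_amp_uv, carrier)

  data <- background + alpha +
    matrix(stats::rnorm(M * T_, sd = spec$noise_amp_uv), nrow = M)

  if (!is.null(spec$line_freq_hz) && spec$line_amp_uv > 0) {
    chans <- spec$line_channels %||% seq_len(M)
    line <- spec$line_amp_uv * sin(2 * pi * spec$line_freq_hz * t +
                                     stats::runif(1, 0, 2 * pi))
    data[chans, ] <- data[chans, , drop = FALSE] +
      matrix(line, nrow = length(chans), ncol = T_, byrow = TRUE)
  }

  S <- round(2 * fs)
  bad_ch <- list(); bad_ep <- list()
  for (a in spec$artifacts) {
    mag <- a$magnitude
    if (a$kind == "flat_channel") {
      data[a$channel, ] <- 0
      bad_ch[[length(bad_ch) + 1]] <- tibble(channel = a$channel,
                                             kind = a$kind)
    } else if (a$kind == "noisy_channel") {
      mag <- mag %||% (10 * spec$background_amp_uv)
      data[a$channel, ] <- data[a$channel, ] + stats::rnorm(T_, sd = mag)
      bad_ch[[length(bad_ch) + 1]] <- tibble(channel = a$channel,
                                             kind = a$kind)
    } else if (a$kind == "uncorrelated_channel") {
      data[a$channel, ] <- spec$background_amp_uv *
        pink_noise(T_, spec$background_exponent) +
        stats::rnorm(T_, sd = spec$noise_amp_uv)
      bad_ch[[length(bad_ch) + 1]] <- tibble(channel = a$channel,
                                             kind = a$kind)
    } else if (a$kind == "burst_epoch") {
      mag <- mag %||% 200
      idx <- ((a$epoch - 1) * S + 1):(a$epoch * S)
      s_loc <- seq_len(S)
      burst <- mag * exp(-((s_loc - S / 2)^2) / (2 * (S / 10)^2)) *
        sin(2 * pi * 5 * s_loc / fs)
      data[a$channel, idx] <- data[a$channel, idx] + burst
      bad_ep[[length(bad_ep) + 1]] <- tibble(epoch = a$epoch, kind = a$kind)
    } else if (a$kind == "blink") {
      mag <- mag %||% 150
      idx <- ((a$epoch - 1) * S + 1):(a$epoch * S)
      s_loc <- seq_len(S)
      # biphasic low-frequency deflection (derivative-of-Gaussian, ~0.3 s),
      # weighted toward frontal channels (channel order runs front to back)
      ctr <- S / 2; width <- 0.15 * fs
      wave <- -mag * (s_loc - ctr) / width * exp(0.5) *
        exp(-((s_loc - ctr)^2) / (2 * width^2))
      frontal_w <- exp(-(seq_len(M) - 1) / 3)
      data[, idx] <- data[, idx] + outer(frontal_w, wave)
      bad_ep[[length(bad_ep) + 1]] <- tibble(epoch = a$epoch, kind = a$kind)
    }
  }

  rec <- eeg_recording(data, fs = fs, labels = spec$labels,
                       condition = spec$condition, session = session)
  truth <- structure(
    list(bad_channels = dplyr::bind_rows(bad_ch) |>
           (\(d) if (nrow(d)) dplyr::distinct(d) else
              tibble(channel = integer(), kind = character()))(),
         bad_epochs = dplyr::bind_rows(bad_ep) |>
           (\(d) if (nrow(d)) dplyr::distinct(d) else
              tibble(epoch = integer(), kind = character()))(),
         true_paf_hz = spec$alpha_freq_hz),
    class = "synthetic_truth"
  )
  list(recording = rec, truth = truth)
}

#' Generate a synthetic cohort with session metadata
#'
#' Draws `n_recordings` independent recordings whose alpha peaks are sampled
#' from `paf_range` (or follow an age-group trend when `age_groups` and
#' `paf_by_age` are given, emulating the decline of peak alpha frequency
#' with adult age), assigns teams, devices, dates, conditions, sex and
#' indoor/outdoor settings round-robin or at random, and optionally injects
#' one random channel artifact per recording with probability
#' `artifact_prob`. All sampling derives from `seed`.
#'
#' @param n_recordings Number of recordings (>= 1).
#' @param seed Integer master seed.
#' @param duration_s Recording length in seconds.
#' @param n_channels Channels per recording.
#' @param paf_range Range (lo, hi) for uniform alpha-peak sampling, Hz.
#' @param paf_on_grid Round sampled peaks to the 0.5 Hz analysis grid.
#' @param age_groups,paf_by_age Optional parallel vectors: age-band labels
#'   and the mean alpha peak (Hz) of each; recordings are spread evenly over
#'   the bands.
#' @param teams,devices,conditions Metadata pools.
#' @param start_date,n_days Sessions are dated `start_date` plus
#'   `0 ... n_days - 1` days, round-robin.
#' @param artifact_prob Probability that a recording receives one injected
#'   bad channel (kind sampled from flat/noisy/uncorrelated).
#' @param p_nonstandard Probability that one channel label is swapped for
#'   its alternate montage position.
#' @return A list of `n_recordings` elements, each with `recording` and
#'   `truth` (see [generate_recording()]).
#' @export
generate_cohort <- function(n_recordings, seed = 1, duration_s = 180,
                            n_channels = 16,
                            paf_range = c(8, 11), paf_on_grid = FALSE,
                            age_groups = NULL, paf_by_age = NULL,
                            teams = c("TN1", "TN2", "NCR1"),
                            devices = c("DEV1", "DEV2", "DEV3"),
                            conditions = c("EC", "EO", "TASK"),
                            start_date = as.Date("2026-01-05"), n_days = 5,
                            artifact_prob = 0, p_nonstandard = 0) {
  if (n_recordings < 1) stop("n_recordings must be >= 1", call. = FALSE)
  if (length(paf_range) != 2 || paf_range[1] > paf_range[2] ||
      paf_range[1] < 7 || paf_range[2] > 12)
    stop("paf_range must be (lo, hi) within [7, 12]", call. = FALSE)
  if (!is.null(age_groups) &&
      (is.null(paf_by_age) || length(paf_by_age) != length(age_groups)))
    stop("age_groups and paf_by_age must be parallel vectors", call. = FALSE)
  montage <- default_montage()
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_recordings), function(i) {
      if (!is.null(age_groups)) {
        gi <- ((i - 1) %% length(age_groups)) + 1
        age <- age_groups[gi]
        paf <- min(12, max(7, stats::rnorm(1, paf_by_age[gi], 0.15)))
      } else {
        age <- "unknown"
        paf <- stats::runif(1, paf_range[1], paf_range[2])
      }
      if (paf_on_grid) paf <- min(12, max(7, round(paf * 2) / 2))
      artifacts <- list()
      if (stats::runif(1) < artifact_prob) {
        kind <- sample(c("flat_channel", "noisy_channel",
                         "uncorrelated_channel"), 1)
        artifacts <- list(list(kind = kind,
                               channel = sample.int(n_channels, 1)))
      }
      labels <- NULL
      if (n_channels == 16 && stats::runif(1) < p_nonstandard) {
        labels <- montage$label[1:16]
        j <- sample.int(16, 1)
        labels[j] <- montage$label[montage$alternate_for %in% labels[j] &
                                     !is.na(montage$alternate_for)][1]
      }
      spec <- synthetic_spec(
        n_channels = n_channels, duration_s = duration_s,
        condition = conditions[((i - 1) %% length(conditions)) + 1],
        alpha_freq_hz = paf, artifacts = artifacts, labels = labels,
        seed = (as.integer(seed) + i * 7919L) %% 2147483647L
      )
      session <- session_meta(
        date = start_date + ((i - 1) %% n_days),
        team_id = teams[((i - 1) %% length(teams)) + 1],
        device_id = devices[((i - 1) %% length(devices)) + 1],
        participant_id = sprintf("P%04d", i),
        indoor_outdoor = sample(c("indoor", "outdoor"), 1),
        sex = sample(c("male", "female"), 1),
        age_group = age
      )
      generate_recording(spec, session = session)
    })
  })
}

#' Write or read a synthetic spec as YAML
#'
#' @param spec A [synthetic_spec()].
#' @param path File path.
#' @return `write_synthetic_spec()` returns `path` invisibly;
#'   `read_synthetic_spec()` returns a [synthetic_spec()].
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  s <- yaml::read_yaml(path)
  do.call(synthetic_spec, s)
}
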