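test_that("generation is bit-reproducible from the seed", {
  spec <- synthetic_spec(duration_s = 10, seed = 123,
                         artifacts = list(list(kind = "flat_channel",
                                               channel = 2)))
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$bad_channels, b$truth$bad_channels)
  c_ <- generate_recording(synthetic_spec(duration_s = 10, seed = 124))
  expect_false(identical(a$recording$data, c_$recording$data))
})

test_that("invalid specs are rejected with every problem listed", {
  err <- expect_error(
    synthetic_spec(alpha_freq_hz = 20, alpha_amp_uv = -1,
                   artifacts = list(list(kind = "nope"),
                                    list(kind = "flat_channel", channel = 99))),
    "invalid synthetic spec"
  )
  for (frag in c("alpha_freq_hz", "alpha_amp_uv", "nope", "out of range"))
    expect_match(conditionMessage(err), frag)
})

test_that("clean channels stay correlated within 2 s windows", {
  sim <- generate_recording(synthetic_spec(duration_s = 30, seed = 130))
  x <- sim$recording$data
  S <- 512
  mins <- vapply(seq_len(ncol(x) %/% S), function(w) {
    C <- abs(cor(t(x[, ((w - 1) * S + 1):(w * S)])))
    diag(C) <- NA
    min(apply(C, 1, max, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(mins >= 0.4))
})

test_that("background spectrum follows the requested 1/f exponent", {
  for (expo in c(0.8, 1.2)) {
    sim <- generate_recording(synthetic_spec(duration_s = 60, seed = 131,
                                             background_exponent = expo,
                                             alpha_amp_uv = 0,
                                             noise_amp_uv = 0))
    psd <- welch_psd(sim$recording, window_s = 4)
    sel <- psd$freqs >= 1 & psd$freqs <= 40
    slope <- unname(coef(lm(log(colMeans(psd$power)[sel]) ~
                              log(psd$freqs[sel])))[2])
    expect_lt(abs(slope + expo), 0.2)
  }
})

test_that("injected artifacts are recoverable by the matching detector", {
  sim <- generate_recording(synthetic_spec(
    duration_s = 60, seed = 132,
    artifacts = list(list(kind = "flat_channel", channel = 9),
                     list(kind = "burst_epoch", channel = 4, epoch = 11))))
  res <- run_qc(sim$recording)
  prep_ch <- res$channel_qc$PREP
  expect_true(prep_ch$flag_flat[9])
  # the burst-target channel (4) may legitimately trip PREP's windowed
  # correlation; every other channel must stay clean
  expect_true(all(which(prep_ch$bad) %in% c(4L, 9L)))
  expect_true(prep_ch$bad[9])
  expect_true(res$epoch_qc$PREP$bad[11] || res$epoch_qc$FASTER$bad[11])
  expect_equal(sim$truth$bad_channels$channel, 9)
  expect_equal(sim$truth$bad_epochs$epoch, 11)
})

test_that("alpha ground truth is recovered on the analysis grid", {
  sim <- generate_recording(synthetic_spec(duration_s = 30, seed = 133,
                                           alpha_freq_hz = 10.0))
  expect_equal(peak_alpha_frequency(sim$recording)$avg_spectrum_paf_hz, 10.0)
  expect_equal(sim$truth$true_paf_hz, 10.0)
})

test_that("cohorts populate sessions and feed the dashboard", {
  cohort <- generate_cohort(12, seed = 5, duration_s = 8, n_days = 3,
                            p_nonstandard = 0.5)
  expect_length(cohort, 12)
  summaries <- qc_summary(lapply(cohort, function(el) run_qc(el$recording)))
  expect_equal(nrow(summaries), 24)   # two methods per recording
  last_day <- max(summaries$date)
  rep_ <- build_daily_report(summaries, last_day, "FASTER")
  expect_equal(rep_$n_recordings_ytd[rep_$scope == "overall"], 12)
  expect_true(any(summaries$n_nonstandard > 0))
})

test_that("an injected age trend in alpha peak is recovered", {
  groups <- c("15-24", "35-44", "55-64")
  cohort <- generate_cohort(18, seed = 6, duration_s = 20,
                            age_groups = groups,
                            paf_by_age = c(9.6, 9.3, 9.0),
                            conditions = "EC")
  paf <- vapply(cohort, function(el)
    peak_alpha_frequency(el$recording)$avg_spectrum_paf_hz, numeric(1))
  age <- vapply(cohort, function(el)
    el$recording$session$age_group, character(1))
  means <- tapply(paf, age, mean)[groups]
  expect_true(all(diff(means) < 0))
})

test_that("specs round-trip through YAML", {
  spec <- synthetic_spec(duration_s = 12, seed = 77, alpha_freq_hz = 9.5,
                         artifacts = list(list(kind = "noisy_channel",
                                               channel = 3, magnitude = 80)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, path)
  back <- read_synthetic_spec(path)
  expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
  expect_equal(generate_recording(back)$recording$data,
               generate_recording(spec)$recording$data, tolerance = 1e-12)
})
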