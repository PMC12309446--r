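test_that("robust spread matches linear-interpolation quartiles", {
  expect_equal(robust_std(c(0, 1, 2, 3)), 1.5 * 0.7413)
  expect_equal(robust_std(rep(2, 8)), 0)
  expect_error(robust_std(1:3), "at least 4")
})

test_that("robust spread is Gaussian-consistent", {
  withr::with_seed(101, z <- rnorm(1e6))
  est <- robust_std(z)
  expect_gt(est, 0.99); expect_lt(est, 1.01)
})

test_that("robust Z-score centers at the median and resists outliers", {
  withr::with_seed(8, v <- rnorm(15))
  v16 <- c(v, 40)
  rz <- robust_zscore(v16)
  expect_equal(median(rz), 0)
  expect_gt(abs(rz[16]), abs(zscore(v16)[16]))
  expect_equal(robust_zscore(rep(3, 6)), rep(0, 6))
  expect_error(robust_zscore(1:3), "at least 4")
})

test_that("PREP flags flat, NaN and uncorrelated channels", {
  rec <- make_toy_rec(M = 16, dur_s = 30, seed = 41)

  rec_flat <- rec; rec_flat$data[6, ] <- 0
  res <- prep_bad_channels(rec_flat)
  expect_true(res$flag_flat[6])
  expect_identical(which(res$bad), 6L)

  rec_nan <- rec; rec_nan$data[2, 100] <- NaN
  res_nan <- prep_bad_channels(rec_nan)
  expect_true(res_nan$flag_flat[2])
  expect_true(res_nan$bad[2])

  rec_unc <- rec
  rec_unc$data[11, ] <- withr::with_seed(99, rnorm(ncol(rec$data)))
  res_unc <- prep_bad_channels(rec_unc)
  expect_true(res_unc$flag_correlation[11])
})

test_that("scale-based PREP criteria are gain invariant, flatness is not", {
  rec <- make_toy_rec(M = 8, dur_s = 20, seed = 42)
  rec$data[4, ] <- withr::with_seed(43, rnorm(ncol(rec$data)))  # uncorrelated
  res <- prep_bad_channels(rec)
  rec_g <- rec; rec_g$data <- rec_g$data * 50
  res_g <- prep_bad_channels(rec_g)
  for (cl in c("flag_amplitude", "flag_correlation", "flag_noisiness"))
    expect_identical(res_g[[cl]], res[[cl]])

  rec_tiny <- rec; rec_tiny$data <- rec_tiny$data * 1e-18
  expect_error(prep_bad_channels(rec_tiny), "usable")  # everything flat now
})

test_that("PREP epoch criterion flags a single-channel burst", {
  rec <- make_toy_rec(M = 8, dur_s = 180, seed = 44, noise_sd = 1)
  ep <- epoch_recording(highpass(rec))
  res_clean <- prep_bad_epochs(ep)
  expect_lte(mean(res_clean$bad), 0.05)

  rec2 <- rec
  idx <- (24 * 512 + 1):(25 * 512)
  rec2$data[3, idx] <- rec2$data[3, idx] * 20
  ep2 <- epoch_recording(highpass(rec2))
  res2 <- prep_bad_epochs(ep2)
  expect_true(res2$bad[25])
  expect_gt(res2$score_scale_z_max[25], 5)
})

test_that("identical epochs yield zero robust scores", {
  one <- matrix(rnorm(4 * 512), 4)
  rec <- eeg_recording(one[, rep(1:512, 8)], fs = 256,
                       labels = paste0("C", 1:4))
  res <- prep_bad_epochs(epoch_recording(rec))
  expect_equal(res$score_robust, rep(0, 8))
  expect_false(any(res$bad))
})

test_that("raising an artifact's amplitude never unflags its epoch", {
  rec0 <- make_toy_rec(M = 6, dur_s = 60, seed = 45, noise_sd = 1)
  idx <- (9 * 512 + 1):(10 * 512)
  flagged_prev <- FALSE
  for (mag in c(2, 5, 10, 25, 60)) {
    rec <- rec0
    rec$data[2, idx] <- rec$data[2, idx] * mag
    flagged <- prep_bad_epochs(epoch_recording(highpass(rec)))$bad[10]
    if (flagged_prev) expect_true(flagged)
    flagged_prev <- flagged
  }
  expect_true(flagged_prev)
})
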