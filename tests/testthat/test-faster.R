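test_that("sample Z-score matches hand computation and handles degeneracy", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore(rep(4, 10)), rep(0, 10))
  withr::with_seed(3, v <- rnorm(50))
  expect_equal(mean(zscore(v)), 0, tolerance = 1e-12)
  expect_equal(sd(zscore(v)), 1, tolerance = 1e-12)
  expect_error(zscore(1), "at least 2")
})

test_that("rescaled-range Hurst estimate behaves as expected", {
  withr::with_seed(42, wn <- rnorm(65536))
  h_wn <- hurst_exponent(wn)
  expect_gt(h_wn, 0.45); expect_lt(h_wn, 0.60)

  fgn <- make_fgn(65536, H = 0.8, seed = 5)
  expect_lt(abs(hurst_exponent(fgn) - 0.8), 0.1)

  expect_error(hurst_exponent(rnorm(64)), "too short")
  expect_error(hurst_exponent(rep(1, 500)), "constant")
})

test_that("Hurst estimate agrees with an independent estimator", {
  skip_if_not_installed("pracma")
  withr::with_seed(7, wn <- rnorm(16384))
  expect_lt(abs(hurst_exponent(wn) -
                  pracma::hurstexp(wn, display = FALSE)$Hs), 0.1)
  fgn <- make_fgn(16384, H = 0.75, seed = 9)
  expect_lt(abs(hurst_exponent(fgn) -
                  pracma::hurstexp(fgn, display = FALSE)$Hs), 0.1)
})

test_that("FASTER channel criteria catch injected channel artifacts", {
  rec <- make_toy_rec(M = 16, dur_s = 30, seed = 21)
  res_clean <- faster_bad_channels(rec)
  expect_lte(sum(res_clean$bad), 1)

  rec_var <- rec
  rec_var$data[7, ] <- rec_var$data[7, ] * 10
  res <- faster_bad_channels(rec_var)
  expect_true(res$flag_variance[7])
  expect_true(res$bad[7])

  rec_line <- rec
  tt <- (0:(ncol(rec$data) - 1)) / rec$fs
  target_sd <- sd(rec$data[3, ])
  rec_line$data[3, ] <- sqrt(2) * target_sd * sin(2 * pi * 50 * tt)
  res_line <- faster_bad_channels(rec_line)
  expect_true(res_line$flag_powerline[3])
})

test_that("FASTER channel detection needs at least 4 channels", {
  rec <- make_toy_rec(M = 3, dur_s = 10, seed = 1)
  expect_error(faster_bad_channels(rec), "4 channels")
})

test_that("FASTER epoch criteria flag a transient burst and little else", {
  rec <- make_toy_rec(M = 8, dur_s = 180, seed = 22, noise_sd = 1)
  ep <- epoch_recording(highpass(rec))
  res_clean <- faster_bad_epochs(ep)
  expect_lte(mean(res_clean$bad), 0.10)

  # 20-sd square pulse on one channel of epoch 40
  rec2 <- rec
  idx <- (39 * 512 + 100):(39 * 512 + 200)
  rec2$data[5, idx] <- rec2$data[5, idx] + 20 * sd(rec2$data[5, ])
  ep2 <- epoch_recording(highpass(rec2))
  res2 <- faster_bad_epochs(ep2)
  expect_true(res2$bad[40])
  expect_true(res2$flag_range[40] || res2$flag_variance[40])
})

test_that("identical epochs are never flagged", {
  one <- matrix(rnorm(4 * 512), 4)
  rec <- eeg_recording(one[, rep(1:512, 8)], fs = 256,
                       labels = paste0("C", 1:4))
  ep <- epoch_recording(rec)
  res <- faster_bad_epochs(ep)
  expect_false(any(res$bad))
  expect_error(faster_bad_epochs(epoch_recording(
    eeg_recording(one, fs = 256, labels = paste0("C", 1:4)))), ">= 4 epochs")
})

test_that("FASTER flags are equivariant to channel permutation and gain", {
  for (s in 1:3) {
    rec <- make_toy_rec(M = 8, dur_s = 20, seed = 30 + s)
    rec$data[3, ] <- rec$data[3, ] * 8   # give it something to flag
    res <- faster_bad_channels(rec)
    perm <- withr::with_seed(s, sample(8))
    rec_p <- eeg_recording(rec$data[perm, ], fs = rec$fs,
                           labels = rec$labels[perm])
    res_p <- faster_bad_channels(rec_p)
    expect_identical(res_p$bad, res$bad[perm])

    rec_g <- rec; rec_g$data <- rec_g$data * 12.5
    res_g <- faster_bad_channels(rec_g)
    expect_identical(res_g$bad, res$bad)

    ep <- epoch_recording(rec)
    expect_identical(faster_bad_epochs(ep)$bad,
                     {epg <- ep; epg$data <- epg$data * 12.5
                      faster_bad_epochs(epg)$bad})
  }
})
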