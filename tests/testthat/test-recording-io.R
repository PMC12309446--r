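test_that("recording constructor validates geometry and metadata", {
  x <- matrix(rnorm(4 * 100), 4)
  expect_error(eeg_recording(x, fs = -1, labels = paste0("C", 1:4)), "positive")
  expect_error(eeg_recording(x, fs = 256, labels = c("a", "a", "b", "c")),
               "unique")
  expect_error(eeg_recording(1:10, fs = 256), "matrix")
  rec <- eeg_recording(x, fs = 256, labels = paste0("C", 1:4))
  expect_s3_class(rec, "eeg_recording")
  expect_identical(rec$labels, paste0("C", 1:4))
})

test_that("CSV round trip preserves data, labels and duration", {
  withr::with_seed(11, {
    rec <- eeg_recording(matrix(rnorm(16 * 512, sd = 20), 16), fs = 256,
                         labels = default_montage()$label[1:16],
                         condition = "EO",
                         session = session_meta("2026-03-02", "TN1", "DEV2",
                                                "P0001", sex = "female"))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, condition = "EO", fs = 256)
  expect_equal(duration_s(back), 2.0)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  # session travelled through the JSON sidecar
  expect_equal(back$session$team_id, "TN1")
  expect_equal(back$session$sex, "female")
  expect_equal(back$session$date, as.Date("2026-03-02"))
})

test_that("EDF round trip recovers the signal to 16-bit quantization", {
  withr::with_seed(12, {
    rec <- eeg_recording(matrix(rnorm(4 * 1024, sd = 30), 4), fs = 256,
                         labels = c("Fp1", "Fp2", "O1", "O2"))
  })
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, 256)
  tol <- max(apply(rec$data, 1, function(v) diff(range(v)))) / 65536
  expect_lt(max(abs(back$data - rec$data)), 2 * tol)
})

test_that("unreadable inputs raise informative errors", {
  expect_error(read_recording("no-such-file.csv", fs = 256), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), path)
  suppressWarnings(expect_error(read_recording(path, fs = 256)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path2)
  expect_error(read_recording(path2), "fs")
})

test_that("montage classification partitions the expected 16 channels", {
  mont <- default_montage()
  std <- mont$label[mont$role == "standard"]
  alt <- mont$label[mont$role == "alternate"]
  expect_equal(unlist(classify_montage(std)), c(n_standard = 16,
                                                n_nonstandard = 0,
                                                n_missing = 0))
  expect_equal(unlist(classify_montage(c(std[1:15], alt[16]))),
               c(n_standard = 15, n_nonstandard = 1, n_missing = 0))
  expect_equal(unlist(classify_montage(std[1:14])),
               c(n_standard = 14, n_nonstandard = 0, n_missing = 2))
  expect_error(classify_montage(c(std[1:15], "XX9")), "XX9")
})

test_that("montage classification is invariant to label order", {
  mont <- default_montage()
  labs <- c(mont$label[mont$role == "standard"][1:12],
            mont$label[mont$role == "alternate"][1:2])
  for (s in 1:5) {
    shuffled <- withr::with_seed(s, sample(labs))
    expect_identical(classify_montage(shuffled), classify_montage(labs))
  }
})
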