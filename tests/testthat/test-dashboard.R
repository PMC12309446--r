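mk_summary <- function(id, date, team, cond = "EC", method = "PREP",
                       pct_ch = 0, pct_ep = 0, n_ch = 16, n_ep = 90,
                       nonstd = 0, missing = 0, device = "DEV1") {
  tibble::tibble(recording_id = id, condition = cond, method = method,
                 pct_bad_channels = pct_ch, pct_bad_epochs = pct_ep,
                 n_channels = n_ch, n_epochs = n_ep,
                 n_nonstandard = nonstd, n_missing = missing,
                 date = as.Date(date), team_id = team, device_id = device,
                 participant_id = id, indoor_outdoor = "indoor",
                 sex = "unknown", age_group = "unknown")
}

test_that("pooled percentages count channels, not recordings", {
  s <- dplyr::bind_rows(
    mk_summary("r1", "2026-02-10", "TN1", pct_ch = 6.25),   # 1 of 16
    mk_summary("r2", "2026-02-10", "TN1"),
    mk_summary("r3", "2026-02-10", "TN2")
  )
  rep_ <- build_daily_report(s, "2026-02-10", method = "PREP")
  ov <- rep_[rep_$scope == "overall", ]
  expect_equal(ov$pct_bad_channels_on_date, 100 * 1 / 48)
  expect_equal(ov$mean_pct_bad_channels_on_date, 6.25 / 3)
  expect_equal(ov$n_recordings_on_date, 3)
})

test_that("team and condition rows partition the overall counts", {
  s <- dplyr::bind_rows(
    mk_summary("r1", "2026-02-09", "TN1", cond = "EC", pct_ch = 12.5),
    mk_summary("r2", "2026-02-09", "TN2", cond = "EO"),
    mk_summary("r3", "2026-02-10", "TN1", cond = "TASK", nonstd = 1),
    mk_summary("r4", "2026-02-10", "TN2", cond = "EC", missing = 2),
    mk_summary("r5", "2026-02-10", "TN3", cond = "EC", pct_ch = 6.25)
  )
  rep_ <- build_daily_report(s, "2026-02-10", method = "PREP")
  ov <- rep_[rep_$scope == "overall", ]
  teams <- rep_[rep_$scope == "team", ]
  tasks <- rep_[rep_$scope == "task", ]
  for (col in c("n_recordings_on_date", "n_recordings_ytd",
                "n_nonstandard_ytd", "n_missing_ytd")) {
    expect_equal(sum(teams[[col]]), ov[[col]])
    expect_equal(sum(tasks[[col]]), ov[[col]])
  }
  expect_true(all(rep_$n_recordings_ytd >= rep_$n_recordings_on_date))
  pct_cols <- grep("^pct_", names(rep_), value = TRUE)
  expect_true(all(as.matrix(rep_[pct_cols]) >= 0 &
                    as.matrix(rep_[pct_cols]) <= 100))
})

test_that("report date boundaries are enforced", {
  s <- dplyr::bind_rows(
    mk_summary("r1", "2026-02-01", "TN1"),
    mk_summary("r2", "2025-12-30", "TN1")   # previous year: not YTD
  )
  rep_ <- build_daily_report(s, "2026-02-10", method = "PREP")
  ov <- rep_[rep_$scope == "overall", ]
  expect_equal(ov$n_recordings_on_date, 0)
  expect_equal(ov$n_recordings_ytd, 1)

  expect_error(build_daily_report(s, "2026-01-30", method = "PREP"), "future")

  empty <- build_daily_report(s[0, ], "2026-02-10", method = "PREP")
  expect_equal(nrow(empty), 1)
  expect_equal(empty$n_recordings_ytd, 0)
  expect_equal(empty$pct_bad_channels_ytd, 0)
})

test_that("daily batches pool to the same report as the full set", {
  withr::with_seed(80, {
    rows <- lapply(1:12, function(i)
      mk_summary(paste0("r", i), as.Date("2026-03-01") + (i %% 4),
                 c("TN1", "TN2")[1 + i %% 2],
                 cond = c("EC", "EO", "TASK")[1 + i %% 3],
                 pct_ch = sample(c(0, 6.25, 12.5), 1),
                 pct_ep = runif(1, 0, 20)))
  })
  all_s <- dplyr::bind_rows(rows)
  batches <- dplyr::bind_rows(all_s[1:5, ], all_s[6:12, ])
  expect_equal(build_daily_report(batches, "2026-03-05", "PREP"),
               build_daily_report(all_s, "2026-03-05", "PREP"))
})

test_that("rendered CSV reports round-trip and markdown has one row each", {
  s <- dplyr::bind_rows(mk_summary("r1", "2026-02-10", "TN1", pct_ch = 6.25),
                        mk_summary("r2", "2026-02-10", "TN2"))
  rep_ <- build_daily_report(s, "2026-02-10", method = "PREP")
  csv <- render_report(rep_, "csv")
  back <- readr::read_csv(I(csv), show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep_))
  md <- render_report(rep_, "markdown")
  expect_equal(length(strsplit(md, "\n")[[1]]), nrow(rep_) + 2)
})
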