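# Daily field report: on-date and year-to-date counts and pooled quality
# percentages, overall and broken down by task, team and device.

pool_rows <- function(df) {
  if (nrow(df) == 0L)
    return(list(n = 0L, nonstd = 0L, missing = 0L,
                pct_ch = 0, pct_ep = 0, mean_pct_ch = 0, mean_pct_ep = 0))
  bad_ch <- df$pct_bad_channels * df$n_channels / 100
  bad_ep <- df$pct_bad_epochs * df$n_epochs / 100
  list(
    n = nrow(df),
    nonstd = sum(df$n_nonstandard, na.rm = TRUE),
    missing = sum(df$n_missing, na.rm = TRUE),
    pct_ch = 100 * sum(bad_ch) / sum(df$n_channels),
    pct_ep = 100 * sum(bad_ep) / sum(df$n_epochs),
    mean_pct_ch = mean(df$pct_bad_channels),
    mean_pct_ep = mean(df$pct_bad_epochs)
  )
}

dashboard_row <- function(scope, scope_id, on, ytd) {
  a <- pool_rows(on); b <- pool_rows(ytd)
  tibble(
    scope = scope, scope_id = scope_id,
    n_recordings_on_date = a$n, n_recordings_ytd = b$n,
    n_nonstandard_on_date = a$nonstd, n_nonstandard_ytd = b$nonstd,
    n_missing_on_date = a$missing, n_missing_ytd = b$missing,
    pct_bad_channels_on_date = a$pct_ch, pct_bad_channels_ytd = b$pct_ch,
    pct_bad_epochs_on_date = a$pct_ep, pct_bad_epochs_ytd = b$pct_ep,
    mean_pct_bad_channels_on_date = a$mean_pct_ch,
    mean_pct_bad_channels_ytd = b$mean_pct_ch,
    mean_pct_bad_epochs_on_date = a$mean_pct_ep,
    mean_pct_bad_epochs_ytd = b$mean_pct_ep
  )
}

#' Build the daily field-team quality report
#'
#' From pooled per-recording summaries (see [qc_summary()]) and a report
#' date, produces one row per scope: overall, each recording condition, each
#' field team and each device. Each row carries on-date and year-to-date
#' (same calendar year, up to and including the report date) recording
#' counts, nonstandard/missing channel counts, and percentages of bad
#' channels and bad epochs. Percentages are pooled (channel- or
#' epoch-count-weighted) across the scope; the unweighted mean of
#' per-recording percentages is emitted alongside in `mean_pct_*` columns.
#' Condition rows and team rows each partition the overall counts exactly.
#'
#' @param summaries Summary tibble from [qc_summary()] (one method, or pass
#'   `method` to filter).
#' @param report_date The report date (`Date` or string).
#' @param method `"FASTER"` or `"PREP"`.
#' @return A tibble of dashboard rows.
#' @export
build_daily_report <- function(summaries, report_date,
                               method = c("FASTER", "PREP")) {
  method <- match.arg(method)
  report_date <- as.Date(report_date)
  df <- dplyr::filter(summaries, .data$method == !!method)
  if (nrow(df) > 0 && any(is.na(df$date)))
    stop("summaries without a session date cannot be placed on the dashboard",
         call. = FALSE)
  if (nrow(df) > 0 && any(df$date > report_date))
    stop("future-dated recordings relative to the report date", call. = FALSE)
  ytd <- dplyr::filter(df, format(.data$date, "%Y") == format(report_date, "%Y"),
                       .data$date <= report_date)
  on <- dplyr::filter(ytd, .data$date == report_date)
  rows <- list(dashboard_row("overall", "all", on, ytd))
  for (cond in c("EC", "EO", "TASK")) {
    if (!cond %in% ytd$condition) next
    rows[[length(rows) + 1]] <- dashboard_row(
      "task", cond,
      dplyr::filter(on, .data$condition == cond),
      dplyr::filter(ytd, .data$condition == cond))
  }
  for (team in sort(unique(ytd$team_id))) {
    rows[[length(rows) + 1]] <- dashboard_row(
      "team", team,
      dplyr::filter(on, .data$team_id == team),
      dplyr::filter(ytd, .data$team_id == team))
  }
  for (dev in sort(unique(ytd$device_id))) {
    rows[[length(rows) + 1]] <- dashboard_row(
      "device", dev,
      dplyr::filter(on, .data$device_id == dev),
      dplyr::filter(ytd, .data$device_id == dev))
  }
  dplyr::bind_rows(rows)
}

#' Render a dashboard report as text
#'
#' @param rows Tibble from [build_daily_report()].
#' @param format `"csv"` or `"markdown"`.
#' @return A single string (CSV with header, or a markdown pipe table).
#' @export
render_report <- function(rows, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") return(readr::format_csv(rows))
  cols <- names(rows)
  fmt_cell <- function(v) {
    if (is.numeric(v)) formatC(v, format = "g", digits = 6) else as.character(v)
  }
  header <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", length(cols)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste0("| ", paste(vapply(rows[i, ], fmt_cell, ""), collapse = " | "), " |")
  }, "")
  paste(c(header, sep, body), collapse = "\n")
}
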