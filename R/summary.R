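# One-call pipeline: filter, epoch, run both detection methods, summarize.

#' Run the full quality-control pipeline on one recording
#'
#' High-pass filters the recording, cuts it into epochs, runs the requested
#' detection methods at both channel and epoch level, classifies the montage,
#' and returns per-method summaries plus the detailed per-channel and
#' per-epoch results.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [qc_config()].
#' @param methods Character subset of `c("FASTER", "PREP")`.
#' @param recording_id Identifier used in the summary; defaults to the
#'   session participant id, else `"rec"`.
#' @param montage Montage for [classify_montage()]; labels outside it yield
#'   `NA` montage counts rather than an error (the summary still records
#'   quality).
#' @return An object of class `qc_run`: list with `summary` (tibble, one row
#'   per method), `channel_qc` and `epoch_qc` (named lists of result
#'   tibbles).
#' @export
#' @examples
#' \donttest{
#' sim <- generate_recording(synthetic_spec(duration_s = 20, seed = 1))
#' res <- run_qc(sim$recording)
#' res$summary
#' }
run_qc <- function(rec, cfg = qc_config(), methods = c("FASTER", "PREP"),
                   recording_id = NULL, montage = default_montage()) {
  stopifnot(inherits(rec, "eeg_recording"))
  methods <- match.arg(methods, c("FASTER", "PREP"), several.ok = TRUE)
  if (is.null(recording_id))
    recording_id <- if (!is.null(rec$session)) rec$session$participant_id else "rec"
  filt <- highpass(rec, cutoff_hz = cfg$highpass_hz)
  ep <- epoch_recording(filt, epoch_len_s = cfg$epoch_len_s)
  mont <- tryCatch(
    classify_montage(rec$labels, montage = montage),
    error = function(e) tibble(n_standard = NA_integer_,
                               n_nonstandard = NA_integer_,
                               n_missing = NA_integer_)
  )
  channel_qc <- list(); epoch_qc <- list(); rows <- list()
  for (m in methods) {
    ch <- if (m == "FASTER") faster_bad_channels(filt, cfg)
          else prep_bad_channels(filt, cfg)
    epr <- if (m == "FASTER") faster_bad_epochs(ep, cfg)
           else prep_bad_epochs(ep, cfg)
    channel_qc[[m]] <- ch
    epoch_qc[[m]] <- epr
    rows[[m]] <- dplyr::bind_cols(
      tibble(recording_id = recording_id, condition = rec$condition,
             method = m,
             pct_bad_channels = percent_bad(ch),
             pct_bad_epochs = percent_bad(epr),
             n_channels = nrow(ch), n_epochs = nrow(epr),
             n_nonstandard = mont$n_nonstandard, n_missing = mont$n_missing),
      session_tibble(rec$session)
    )
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 channel_qc = channel_qc, epoch_qc = epoch_qc),
            class = "qc_run")
}

#' @export
print.qc_run <- function(x, ...) {
  cat("<qc_run>\n")
  print(x$summary)
  invisible(x)
}

#' Extract the per-recording quality summary
#'
#' @param x A `qc_run` object (or a list of them, which are row-bound).
#' @return A tibble, one row per recording and method.
#' @export
qc_summary <- function(x) {
  if (inherits(x, "qc_run")) return(x$summary)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "qc_run")))
    return(dplyr::bind_rows(lapply(x, function(r) r$summary)))
  stop("`x` must be a qc_run or a list of qc_run objects", call. = FALSE)
}
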