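#' Read a recording from disk
#'
#' Two interchange formats are supported. CSV: one column per channel with a
#' header row of channel labels, one row per sample, values in microvolts;
#' the sampling rate is not stored in the file and must be supplied via `fs`.
#' EDF: standard 16-bit EDF, read by the built-in parser; signals whose
#' physical dimension is volts are converted to microvolts on read. If a
#' `<basename>.session.json` sidecar exists next to the file it is loaded as
#' session metadata unless `session` is given explicitly.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @param condition Recording condition (`"EC"`, `"EO"`, `"TASK"`).
#' @param session Optional [session_meta()]; overrides any sidecar.
#' @param fs Sampling rate in Hz, required for CSV.
#'
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           condition = c("EC", "EO", "TASK"),
                           session = NULL, fs = NULL) {
  format <- match.arg(format)
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (is.null(session)) session <- read_session_sidecar(path)
  if (format == "csv") {
    if (is.null(fs) || !is.numeric(fs) || fs <= 0)
      stop("CSV recordings need a positive `fs` (not stored in the file)",
           call. = FALSE)
    df <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_double())),
      error = function(e) stop("unreadable CSV: ", conditionMessage(e),
                               call. = FALSE)
    )
    if (readr::problems(df) |> nrow() > 0)
      stop("malformed CSV: inconsistent columns in ", path, call. = FALSE)
    eeg_recording(t(as.matrix(df)), fs = fs, labels = names(df),
                  condition = condition, session = session)
  } else {
    edf <- read_edf(path)
    eeg_recording(edf$data, fs = edf$fs, labels = edf$labels,
                  condition = condition, session = session)
  }
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()]. CSV is written loss-free (full double
#' precision); EDF quantizes to 16 bits over each channel's observed range.
#' Session metadata, when present, is written to a `<basename>.session.json`
#' sidecar.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @param sidecar Write the session sidecar when session metadata exists.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf"),
                            sidecar = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$labels
    readr::write_csv(df, path, progress = FALSE)
  } else {
    write_edf(rec, path)
  }
  if (sidecar && !is.null(rec$session)) write_session_sidecar(rec$session, path)
  invisible(path)
}

session_sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".session.json")
}

write_session_sidecar <- function(session, path) {
  s <- unclass(session)
  s$date <- format(s$date)
  jsonlite::write_json(s, session_sidecar_path(path), auto_unbox = TRUE)
  invisible(session_sidecar_path(path))
}

read_session_sidecar <- function(path) {
  sp <- session_sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  s <- jsonlite::read_json(sp, simplifyVector = TRUE)
  session_meta(date = s$date, team_id = s$team_id, device_id = s$device_id,
               participant_id = s$participant_id,
               indoor_outdoor = s$indoor_outdoor, sex = s$sex,
               age_group = s$age_group)
}
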