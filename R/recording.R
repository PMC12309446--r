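#' Construct an EEG recording
#'
#' A recording is a channels-by-samples matrix in microvolts plus its sampling
#' rate, ordered channel labels, recording condition and session metadata.
#' All downstream processing assumes microvolts; no unit conversion happens
#' silently.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique channel names, one per row.
#' @param condition Recording condition: `"EC"` (eyes closed), `"EO"` (eyes
#'   open) or `"TASK"`.
#' @param session Optional [session_meta()] object.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 512), 4), fs = 256,
#'                      labels = c("Fp1", "Fp2", "O1", "O2"))
#' rec
eeg_recording <- function(data, fs, labels = rownames(data),
                          condition = c("EC", "EO", "TASK"), session = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("`data` needs at least one channel and one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data) || anyDuplicated(labels))
    stop("`labels` must be ", nrow(data), " unique channel names", call. = FALSE)
  if (!is.null(session) && !inherits(session, "session_meta"))
    stop("`session` must be built with session_meta()", call. = FALSE)
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         condition = condition, session = session),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 3), " s), condition ",
      x$condition, "\n", sep = "")
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  if (!is.null(x$session))
    cat("  session: ", x$session$participant_id, " / team ", x$session$team_id,
        " / device ", x$session$device_id, " / ", format(x$session$date), "\n",
        sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' Session metadata for a field recording
#'
#' Grouping keys used by the dashboard and the condition contrasts: date,
#' field team, device, participant, indoor/outdoor setting, sex and age group.
#'
#' @param date Recording date (`Date` or parseable string).
#' @param team_id,device_id,participant_id Non-empty identifier strings.
#' @param indoor_outdoor One of `"indoor"`, `"outdoor"`, `"unknown"`.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param age_group Free-form age-band label, or `"unknown"`.
#'
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(date, team_id, device_id, participant_id,
                         indoor_outdoor = c("unknown", "indoor", "outdoor"),
                         sex = c("unknown", "male", "female"),
                         age_group = "unknown") {
  date <- as.Date(date)
  if (is.na(date)) stop("`date` must be a valid date", call. = FALSE)
  for (nm in c("team_id", "device_id", "participant_id")) {
    v <- get(nm)
    if (!is.character(v) || length(v) != 1L || !nzchar(v))
      stop("`", nm, "` must be a non-empty string", call. = FALSE)
  }
  structure(
    list(date = date, team_id = team_id, device_id = device_id,
         participant_id = participant_id,
         indoor_outdoor = match.arg(indoor_outdoor),
         sex = match.arg(sex), age_group = as.character(age_group)),
    class = "session_meta"
  )
}

# One-row tibble of session fields (all-unknown when session is absent).
session_tibble <- function(session) {
  if (is.null(session)) {
    return(tibble(date = as.Date(NA), team_id = NA_character_,
                  device_id = NA_character_, participant_id = NA_character_,
                  indoor_outdoor = "unknown", sex = "unknown",
                  age_group = "unknown"))
  }
  tibble(date = session$date, team_id = session$team_id,
         device_id = session$device_id, participant_id = session$participant_id,
         indoor_outdoor = session$indoor_outdoor, sex = session$sex,
         age_group = session$age_group)
}
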