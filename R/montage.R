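#' Default 16-channel field montage
#'
#' The headset uses 16 of the 32 positions of the 10-20 international system,
#' eight per hemisphere, with an alternate nearby position permitted per
#' channel when hair obstructs the standard site. The exact electrode names
#' are not fixed by the protocol description, so the shipped montage file
#' (`inst/extdata/montage_flex16.csv`) documents the assumed names and is
#' user-editable: pass your own data frame with columns `label` and `role`
#' (`"standard"`/`"alternate"`) to [classify_montage()] to override it.
#'
#' @return A tibble with columns `label`, `role`, `alternate_for`.
#' @export
#' @examples
#' default_montage()
default_montage <- function() {
  path <- system.file("extdata", "montage_flex16.csv", package = "eegqc")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Classify channel labels against the montage
#'
#' Counts how many of a recording's channels sit at standard positions, how
#' many use the permitted alternate positions, and how many of the expected
#' 16 are missing. The three counts always partition 16. Labels outside the
#' standard and alternate sets are an error (they indicate a metadata-capture
#' problem, which the daily report is meant to surface, not absorb).
#'
#' @param labels Character vector of channel names.
#' @param montage Montage definition; defaults to [default_montage()].
#' @param n_expected Expected channel count (16 for the field protocol).
#'
#' @return A tibble with columns `n_standard`, `n_nonstandard`, `n_missing`.
#' @export
#' @examples
#' classify_montage(default_montage()$label[1:15])
classify_montage <- function(labels, montage = default_montage(),
                             n_expected = 16L) {
  if (length(labels) == 0L) stop("`labels` must be non-empty", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  std <- montage$label[montage$role == "standard"]
  alt <- montage$label[montage$role == "alternate"]
  unknown <- setdiff(labels, c(std, alt))
  if (length(unknown) > 0L)
    stop("channel labels outside the montage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n_std <- sum(labels %in% std)
  n_alt <- sum(labels %in% alt)
  if (n_std + n_alt > n_expected)
    stop("more channels (", n_std + n_alt, ") than the expected ",
         n_expected, call. = FALSE)
  tibble(n_standard = n_std, n_nonstandard = n_alt,
         n_missing = n_expected - n_std - n_alt)
}
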