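#' Raven-style selection tables
#'
#' Selection tables are the tab-separated annotation format used in
#' bioacoustics to mark time-frequency boxes around sounds. The columns used
#' here are `Selection`, `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`,
#' `High Freq (Hz)`, `Channel` (semicolon-separated sensor ids) and
#' optionally `Session` and `Score`.
#'
#' @param file Path to a tab-separated selection table.
#' @param selections A selection-table data frame.
#' @param seed Optional seed recorded in the file header.
#' @return `read_selection_table()` returns a `selection_table` data frame.
#' @export
read_selection_table <- function(file) {
  if (!file.exists(file)) {
    stop(sprintf("missing selection table: %s", file), call. = FALSE)
  }
  tab <- read_table_with_header(file, sep = "\t")
  needed <- c("Selection", "Begin Time (s)", "End Time (s)")
  if (!all(needed %in% names(tab))) {
    stop("selection table schema mismatch: need columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  structure(tab, class = c("selection_table", "data.frame"))
}

#' @rdname read_selection_table
#' @export
write_selection_table <- function(selections, file, seed = NULL) {
  write_table_with_header(selections, file, file_header_line(seed),
                          sep = "\t")
  invisible(file)
}

#' One selection as a record for the localizer
#'
#' Validates the analyst's selection rules: a localizable song unit must be
#' visible on at least three channels, and (when `session_duration` is
#' given) must come from a song session lasting at least `min_session` s.
#'
#' @param selection One row of a selection table.
#' @param min_channels Minimum number of channels.
#' @param session_duration Optional duration (s) of the session the unit
#'   belongs to.
#' @param min_session Minimum session duration in seconds (30 min default).
#' @return A list with `id`, `begin`, `end`, `channels`, `session`.
#' @export
selection_record <- function(selection, min_channels = 3,
                             session_duration = NULL, min_session = 1800) {
  begin <- selection[["Begin Time (s)"]]
  end <- selection[["End Time (s)"]]
  if (end <= begin) stop("selection end must be after begin", call. = FALSE)
  channels <- selection[["Channel"]]
  channels <- if (is.character(channels)) {
    as.integer(strsplit(channels, ";")[[1]])
  } else as.integer(channels)
  if (length(channels) < min_channels) {
    stop(sprintf("selection must be visible on >= %d channels", min_channels),
         call. = FALSE)
  }
  if (!is.null(session_duration) && session_duration < min_session) {
    stop(sprintf("session shorter than %d s; not eligible for tracking",
                 min_session), call. = FALSE)
  }
  list(id = selection[["Selection"]], begin = begin, end = end,
       channels = channels,
       session = if (is.null(selection[["Session"]])) "S1"
                 else selection[["Session"]])
}
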