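#' Export a session in the THEME dialect
#'
#' The THEME dialect splits a session into two files: a `.vvt` category
#' file listing, for each dimension, the dimension name followed by its
#' codes; and a tab-separated `.rdt` record file with a `Time  Event`
#' header, a leading `"t0 <TAB> :"` start-of-observation line, one line
#' per record, and a terminating `"&"` line.  Event-based records carry
#' no durations, so rows are written at a conventional constant time
#' increment (`time_step`); the turn code is written first, remaining
#' codes follow, comma-separated.
#'
#' Record `i` (0-based) is stamped `(i + 2) * time_step`: the start line
#' takes `time_step` and the `&` terminator takes the increment after
#' the last record.
#'
#' @param session An `obs_session`.
#' @param time_step Positive integer time increment between rows
#'   (default 5).
#' @param vvt_path,rdt_path Optional file paths to write to.
#' @return List with character-vector elements `vvt` and `rdt` (the file
#'   lines), invisibly when paths are given.
#' @export
write_theme <- function(session, time_step = 5L, vvt_path = NULL, rdt_path = NULL) {
  stopifnot(inherits(session, "obs_session"))
  time_step <- as.integer(time_step)
  if (is.na(time_step) || time_step <= 0L) stop("`time_step` must be a positive integer")
  rep <- validate_session(session)
  if (!rep$is_valid) {
    stop(paste0("session fails validation:\n", format_validation(rep)), call. = FALSE)
  }
  ins <- session$instrument
  vvt <- unlist(lapply(names(ins$dimensions), function(nm) c(nm, ins$dimensions[[nm]])))

  n <- length(session$records)
  rows <- vapply(seq_len(n), function(i) {
    paste(order_record(session$records[[i]], ins), collapse = ",")
  }, character(1))
  rdt <- c(
    "Time\tEvent",
    sprintf("%d\t:", time_step),
    if (n > 0L) sprintf("%d\t%s", (seq_len(n) + 1L) * time_step, rows),
    sprintf("%d\t&", (n + 2L) * time_step)
  )
  out <- list(vvt = vvt, rdt = rdt)
  if (!is.null(vvt_path)) writeLines(vvt, vvt_path)
  if (!is.null(rdt_path)) writeLines(rdt, rdt_path)
  if (is.null(vvt_path) && is.null(rdt_path)) out else invisible(out)
}

#' Read a THEME .rdt record file back into code rows
#'
#' Inverse of the record part of [write_theme()]: recovers the ordered
#' code rows (and their time stamps) from an `.rdt` file.  Bound to an
#' instrument, the rows become a full `obs_session`.
#'
#' @param path `.rdt` file path, or lines via `text`.
#' @param text Lines of the file, as an alternative to `path`.
#' @param instrument Optional [observation_instrument()]; when given, an
#'   `obs_session` is returned instead of the raw rows.
#' @param label Session label for the bound session.
#' @return With `instrument`: an `obs_session`.  Otherwise a list with
#'   `times` (integer vector) and `records` (list of code vectors).
#' @export
read_theme_rdt <- function(path = NULL, text = NULL, instrument = NULL, label = "") {
  if (is.null(text)) text <- readLines(path, warn = FALSE)
  lines <- trimws(text)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !grepl("^time\\b", lines[1], ignore.case = TRUE)) {
    stop("not a THEME record file: missing 'Time Event' header")
  }
  lines <- lines[-1L]
  times <- integer(0)
  records <- list()
  terminated <- FALSE
  for (ln in lines) {
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) < 2L) stop(sprintf("malformed record line: '%s'", ln))
    t <- suppressWarnings(as.integer(parts[1]))
    if (is.na(t)) stop(sprintf("non-numeric time stamp in line: '%s'", ln))
    ev <- paste(parts[-1L], collapse = "")
    if (ev == ":") next                       # start-of-observation marker
    if (ev == "&") { terminated <- TRUE; break }
    times <- c(times, t)
    records[[length(records) + 1L]] <- toupper(strsplit(ev, ",", fixed = TRUE)[[1]])
  }
  if (!terminated) stop("record file not terminated by '&'")
  if (!is.null(instrument)) {
    return(obs_session(records, instrument, label = label))
  }
  list(times = times, records = records)
}
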