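#' Multi-event sessions
#'
#' A session is an ordered list of observation units.  Each unit (one row
#' of the code matrix) is a set of co-occurring codes, at most one per
#' instrument dimension: typically a speaker code plus the communication
#' strategies coded for that conversational turn.  The data are
#' event-based: order carries the information, units have no duration,
#' and the internal clock is simply the 0-based row index.
#'
#' @param records List of character vectors, one per observation unit.
#' @param instrument The [observation_instrument()] the session is coded
#'   with.
#' @param label Free-text session label.
#' @param validate Check the records against the instrument and fail on
#'   violations (default `TRUE`).
#' @return An object of class `obs_session`.
#' @seealso [parse_session()], [validate_session()]
#' @export
obs_session <- function(records, instrument, label = "", validate = TRUE) {
  stopifnot(inherits(instrument, "obs_instrument"), is.list(records))
  records <- lapply(records, function(r) toupper(as.character(r)))
  if (any(lengths(records) == 0L)) stop("every record must contain at least one code")
  ses <- structure(
    list(records = records, instrument = instrument, label = label),
    class = "obs_session"
  )
  if (validate) {
    rep <- validate_session(ses)
    if (!rep$is_valid) {
      stop(paste0("invalid session:\n", format_validation(rep)), call. = FALSE)
    }
  }
  ses
}

#' @export
print.obs_session <- function(x, ...) {
  cat(sprintf("<obs_session> '%s': %d records, %d distinct codes\n",
              x$label, length(x$records),
              length(unique(unlist(x$records)))))
  n <- min(6L, length(x$records))
  for (i in seq_len(n)) {
    cat(sprintf("  [%d] %s\n", i - 1L, paste(x$records[[i]], collapse = " ")))
  }
  if (length(x$records) > n) cat(sprintf("  ... %d more\n", length(x$records) - n))
  invisible(x)
}

#' @export
length.obs_session <- function(x) length(x$records)

#' Parse a multi-event session body
#'
#' Rows of the multi-event dialect are whitespace-separated code lists:
#' every row is terminated by `"."` except the last, which is terminated
#' by `"/"` (end of session).  Codes are matched case-insensitively
#' against the instrument.
#'
#' @param text Character scalar or vector of lines holding the session
#'   body (no declaration block; see [read_sds()] for whole files).
#' @param instrument The [observation_instrument()] to bind the session to.
#' @param label Session label.
#' @return An `obs_session`.
#' @examples
#' ins <- parse_instrument("($TURN = T M) ($DYN = QA RP);")
#' parse_session("T QA.\nM RP/", ins)
#' @export
parse_session <- function(text, instrument, label = "") {
  stopifnot(inherits(instrument, "obs_instrument"))
  blob <- paste(text, collapse = "\n")
  # separate terminators that are glued to the preceding code
  blob <- gsub("\\.", " . ", blob)
  blob <- gsub("/", " / ", blob)
  toks <- strsplit(trimws(blob), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty session body")
  records <- list()
  cur <- character(0)
  ended <- FALSE
  for (tk in toks) {
    if (ended) stop("content found after the '/' end-of-session terminator")
    if (tk == "." || tk == "/") {
      if (length(cur) == 0L) {
        stop(sprintf("empty record before terminator '%s' at row %d",
                     tk, length(records)))
      }
      records[[length(records) + 1L]] <- cur
      cur <- character(0)
      if (tk == "/") ended <- TRUE
    } else {
      cur <- c(cur, toupper(tk))
    }
  }
  # report coding errors (unknown codes, exclusivity) before format errors:
  # they are the more actionable diagnosis
  probe <- c(records, if (length(cur)) list(cur))
  if (length(probe)) {
    rep <- validate_session(
      obs_session(probe, instrument, label = label, validate = FALSE))
    if (!rep$is_valid) {
      stop(paste0("session body violates the instrument:\n",
                  format_validation(rep)), call. = FALSE)
    }
  }
  if (!ended) stop("session body not terminated by '/'")
  obs_session(records, instrument, label = label, validate = FALSE)
}

#' Read / write a full multi-event file
#'
#' A full file is a declaration block (see [parse_instrument()])
#' followed by the session body (see [parse_session()]).
#'
#' @param path File path, or a character vector of lines via `text`.
#' @param text Lines of the file, as an alternative to `path`.
#' @param label Session label; defaults to the file name.
#' @return `read_sds()` returns an `obs_session` (with the instrument
#'   bound); `write_sds()` invisibly returns the lines written.
#' @export
read_sds <- function(path = NULL, text = NULL, label = NULL) {
  if (is.null(text)) {
    text <- readLines(path, warn = FALSE)
    if (is.null(label)) label <- basename(path)
  }
  if (is.null(label)) label <- ""
  blob <- paste(text, collapse = "\n")
  semi <- regexpr(";", blob, fixed = TRUE)
  if (semi < 0) stop("no declaration block terminator ';' found")
  instrument <- parse_instrument(substr(blob, 1L, semi))
  body <- substr(blob, semi + 1L, nchar(blob))
  parse_session(body, instrument, label = label)
}

#' @rdname read_sds
#' @param session An `obs_session`.
#' @export
write_sds <- function(session, path = NULL) {
  stopifnot(inherits(session, "obs_session"))
  ins <- session$instrument
  decl <- vapply(names(ins$dimensions), function(nm) {
    sprintf("($%s = %s)", nm, paste(ins$dimensions[[nm]], collapse = " "))
  }, character(1))
  decl[length(decl)] <- paste0(decl[length(decl)], ";")
  n <- length(session$records)
  rows <- vapply(seq_len(n), function(i) {
    term <- if (i == n) "/" else "."
    paste0(paste(order_record(session$records[[i]], ins), collapse = " "), term)
  }, character(1))
  lines <- c(decl, rows)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# turn code first, then content codes in instrument declaration order
order_record <- function(codes, instrument) {
  all_codes <- instrument_codes(instrument)
  turn_codes <- if (is.na(instrument$turn_dimension)) character(0) else
    instrument$dimensions[[instrument$turn_dimension]]
  known <- codes[codes %in% all_codes]
  unknown <- codes[!codes %in% all_codes]
  tc <- known[known %in% turn_codes]
  cc <- known[!known %in% turn_codes]
  cc <- cc[order(match(cc, all_codes))]
  c(tc, cc, unknown)
}

#' Validate a session against its instrument
#'
#' Checks that every code is declared in the instrument and that no
#' record carries two codes of the same dimension (the category systems
#' are mutually exclusive).  Validation never throws: problems are
#' returned as report content.
#'
#' @param session An `obs_session`.
#' @param instrument Instrument to validate against; defaults to the one
#'   bound to the session.
#' @return A list of class `obs_validation` with elements
#'   `unknown_codes` (data.frame: index, code), `exclusivity_violations`
#'   (data.frame: index, dimension, codes) and `is_valid`.  Indices are
#'   0-based record positions.
#' @export
validate_session <- function(session, instrument = session$instrument) {
  stopifnot(inherits(session, "obs_session"), inherits(instrument, "obs_instrument"))
  dim_of <- code_dimension(instrument)
  unk_idx <- integer(0); unk_code <- character(0)
  exc_idx <- integer(0); exc_dim <- character(0); exc_codes <- character(0)
  for (i in seq_along(session$records)) {
    codes <- session$records[[i]]
    known <- codes %in% names(dim_of)
    if (any(!known)) {
      unk_idx <- c(unk_idx, rep(i - 1L, sum(!known)))
      unk_code <- c(unk_code, codes[!known])
    }
    dims <- dim_of[codes[known]]
    if (anyDuplicated(dims)) {
      for (d in unique(dims[duplicated(dims)])) {
        exc_idx <- c(exc_idx, i - 1L)
        exc_dim <- c(exc_dim, d)
        exc_codes <- c(exc_codes, paste(codes[known][dims == d], collapse = " "))
      }
    }
  }
  structure(
    list(
      unknown_codes = data.frame(index = unk_idx, code = unk_code,
                                 stringsAsFactors = FALSE),
      exclusivity_violations = data.frame(index = exc_idx, dimension = exc_dim,
                                          codes = exc_codes,
                                          stringsAsFactors = FALSE),
      is_valid = length(unk_idx) == 0L && length(exc_idx) == 0L
    ),
    class = "obs_validation"
  )
}

format_validation <- function(rep) {
  out <- character(0)
  if (nrow(rep$unknown_codes)) {
    out <- c(out, sprintf("  unknown code '%s' at row %d",
                          rep$unknown_codes$code, rep$unknown_codes$index))
  }
  if (nrow(rep$exclusivity_violations)) {
    out <- c(out, sprintf("  codes {%s} of dimension %s co-occur at row %d",
                          rep$exclusivity_violations$codes,
                          rep$exclusivity_violations$dimension,
                          rep$exclusivity_violations$index))
  }
  paste(out, collapse = "\n")
}

#' @export
print.obs_validation <- function(x, ...) {
  if (x$is_valid) cat("<obs_validation> valid\n")
  else cat("<obs_validation> INVALID\n", format_validation(x), "\n")
  invisible(x)
}

#' Code frequencies of a session
#'
#' Counts each code once per record in which it appears.  The relative
#' frequency denominator is the total record count by default; pass
#' `within_turn` to restrict both counts and denominator to the records
#' of one speaker (e.g. the share of a therapist's interventions that
#' are paraphrasing).
#'
#' @param session An `obs_session`.
#' @param within_turn Optional turn code restricting the tally to that
#'   speaker's records.
#' @return data.frame with columns `code`, `count`, `rel_freq`, ordered
#'   by decreasing count.
#' @export
code_frequencies <- function(session, within_turn = NULL) {
  stopifnot(inherits(session, "obs_session"))
  records <- session$records
  if (length(records) == 0L) stop("empty session")
  if (!is.null(within_turn)) {
    within_turn <- toupper(within_turn)
    records <- Filter(function(r) within_turn %in% r, records)
  }
  denom <- length(records)
  tokens <- unlist(lapply(records, unique))
  if (length(tokens) == 0L) {
    return(data.frame(code = character(0), count = integer(0),
                      rel_freq = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- sort(table(tokens), decreasing = TRUE)
  data.frame(
    code = names(tab),
    count = as.integer(tab),
    rel_freq = as.numeric(tab) / denom,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Serialize a session to JSON
#'
#' @param session An `obs_session`.
#' @return JSON string with fields `label`, `instrument` (see
#'   [instrument_to_json()]) and `records` (array of code arrays).
#' @export
session_to_json <- function(session) {
  stopifnot(inherits(session, "obs_session"))
  jsonlite::toJSON(
    list(
      label = session$label,
      instrument = jsonlite::fromJSON(instrument_to_json(session$instrument),
                                      simplifyVector = FALSE),
      records = lapply(session$records, as.list)
    ),
    auto_unbox = TRUE, null = "null"
  )
}

#' @rdname session_to_json
#' @param json JSON string produced by [session_to_json()].
#' @export
session_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ins <- instrument_from_json(jsonlite::toJSON(x$instrument, auto_unbox = TRUE,
                                               null = "null"))
  obs_session(lapply(x$records, unlist), ins, label = x$label)
}

#' Packaged session fragments
#'
#' The two session fragments shipped with the package: short excerpts of
#' an early and a late group-therapy session, coded with
#' [study_instrument()].
#'
#' @param which `"early"` (11 records) or `"late"` (10 records).
#' @return An `obs_session`.
#' @export
study_session <- function(which = c("early", "late")) {
  which <- match.arg(which)
  file <- if (which == "early") "session5.sds" else "session29.sds"
  read_sds(system.file("extdata", file, package = "obseq"),
           label = if (which == "early") "session-5" else "session-29")
}
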