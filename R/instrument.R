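#' Observation instruments
#'
#' An observation instrument is a *field format combined with category
#' systems*: an ordered collection of named dimensions, each holding a
#' closed set of mutually exclusive category codes.  One dimension (the
#' *turn* dimension) identifies the speaker of each observation unit; the
#' remaining dimensions code the content of the intervention.
#'
#' Codes must be unique across the whole instrument: the multi-event
#' dialect writes a row as a bag of codes with no dimension labels, so a
#' code shared by two dimensions would be unparseable.
#'
#' @param dimensions Named list of character vectors; names are dimension
#'   names, elements are the category codes of that dimension, in order.
#' @param turn_dimension Name of the dimension holding speaker codes.
#'   Use `NA` for instruments with no turn dimension.
#' @return An object of class `obs_instrument`.
#' @examples
#' ins <- observation_instrument(
#'   list(TURN = c("T", "M"), DYN = c("QA", "RP")),
#'   turn_dimension = "TURN"
#' )
#' instrument_codes(ins)
#' @export
observation_instrument <- function(dimensions, turn_dimension = NA_character_) {
  if (!is.list(dimensions) || length(dimensions) == 0L ||
      is.null(names(dimensions)) || any(!nzchar(names(dimensions)))) {
    stop("`dimensions` must be a non-empty named list of character vectors")
  }
  dimensions <- lapply(dimensions, function(x) toupper(as.character(x)))
  if (any(lengths(dimensions) == 0L)) {
    stop("every dimension must declare at least one code")
  }
  all_codes <- unlist(dimensions, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    dup <- all_codes[duplicated(all_codes)][1L]
    owners <- names(dimensions)[vapply(dimensions, function(x) dup %in% x, logical(1))]
    stop(sprintf("code '%s' declared in more than one dimension (%s)",
                 dup, paste(owners, collapse = ", ")))
  }
  if (!is.na(turn_dimension)) {
    turn_dimension <- toupper(turn_dimension)
    if (!turn_dimension %in% names(dimensions)) {
      stop(sprintf("turn dimension '%s' is not a declared dimension", turn_dimension))
    }
  }
  structure(
    list(dimensions = dimensions, turn_dimension = turn_dimension),
    class = "obs_instrument"
  )
}

#' @export
print.obs_instrument <- function(x, ...) {
  cat(sprintf("<obs_instrument> %d dimensions, %d codes\n",
              length(x$dimensions), length(instrument_codes(x))))
  for (nm in names(x$dimensions)) {
    tag <- if (identical(nm, x$turn_dimension)) " [turn]" else ""
    cat(sprintf("  %s%s: %s\n", nm, tag, paste(x$dimensions[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' All codes of an instrument
#'
#' @param instrument An [observation_instrument()].
#' @param turn One of `"all"`, `"content"` (non-turn codes only) or
#'   `"turn"` (speaker codes only).
#' @return Character vector of codes in declaration order.
#' @export
instrument_codes <- function(instrument, turn = c("all", "content", "turn")) {
  stopifnot(inherits(instrument, "obs_instrument"))
  turn <- match.arg(turn)
  dims <- instrument$dimensions
  if (turn != "all" && !is.na(instrument$turn_dimension)) {
    keep <- names(dims) == instrument$turn_dimension
    dims <- if (turn == "turn") dims[keep] else dims[!keep]
  }
  unlist(dims, use.names = FALSE)
}

#' Dimension owning each code
#'
#' @param instrument An [observation_instrument()].
#' @return Named character vector mapping code -> dimension name.
#' @export
code_dimension <- function(instrument) {
  stopifnot(inherits(instrument, "obs_instrument"))
  dims <- instrument$dimensions
  stats::setNames(rep(names(dims), lengths(dims)), unlist(dims, use.names = FALSE))
}

#' Parse a multi-event declaration block into an instrument
#'
#' The multi-event dialect opens with a declaration block listing one
#' parenthesized category set per dimension, e.g. `($HUM = R EO)`, the
#' whole block terminated by `";"`.  Codes are canonicalized to upper
#' case.  The last declared set is taken as the turn dimension when its
#' name is `TURN` (case-insensitive); pass `turn_dimension` to override.
#'
#' @param text Character scalar (possibly multi-line) or character vector
#'   of lines containing the declaration block.
#' @param turn_dimension Name of the turn dimension, or `NULL` to
#'   auto-detect a dimension named `TURN` (`NA` if none is present).
#' @return An [observation_instrument()].
#' @examples
#' parse_instrument("($A = X Y) ($TURN = T M);")
#' @export
parse_instrument <- function(text, turn_dimension = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  decl_lines <- character(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) next
    decl_lines <- c(decl_lines, ln)
    bad <- gsub("\\(\\s*\\$\\s*[A-Za-z0-9_.-]+\\s*=[^()]*\\)", "", ln)
    if (grepl("[^\\s;]", bad, perl = TRUE)) {
      stop(sprintf("malformed declaration syntax at line %d: '%s'", i, trimws(ln)))
    }
    if (grepl(";", ln, fixed = TRUE)) break
  }
  blob <- paste(decl_lines, collapse = "\n")
  if (!grepl(";", blob, fixed = TRUE)) {
    stop("declaration block not terminated by ';'")
  }
  m <- gregexpr("\\(\\s*\\$\\s*([A-Za-z0-9_.-]+)\\s*=([^()]*)\\)", blob)
  sets <- regmatches(blob, m)[[1]]
  if (length(sets) == 0L) {
    stop("no '($NAME = code ...)' sets found in declaration block")
  }
  dims <- list()
  for (s in sets) {
    name <- toupper(sub("\\(\\s*\\$\\s*([A-Za-z0-9_.-]+)\\s*=.*", "\\1", s))
    body <- sub("\\(\\s*\\$\\s*[A-Za-z0-9_.-]+\\s*=([^()]*)\\)", "\\1", s)
    codes <- toupper(strsplit(trimws(body), "\\s+")[[1]])
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0L) stop(sprintf("dimension '%s' declares no codes", name))
    if (name %in% names(dims)) stop(sprintf("dimension '%s' declared twice", name))
    dims[[name]] <- codes
  }
  if (is.null(turn_dimension)) {
    turn_dimension <- if ("TURN" %in% names(dims)) "TURN" else NA_character_
  }
  observation_instrument(dims, turn_dimension = turn_dimension)
}

#' The packaged group-therapy observation instrument
#'
#' The instrument used throughout the package's worked examples: 13
#' content dimensions totalling 28 communication-strategy codes, plus a
#' turn dimension of speaker codes.  It is parsed from the declaration
#' block shipped in `inst/extdata/study_instrument.sds`, which declares
#' seven speaker codes (co-therapist and six group members).  The
#' published record rows additionally use the code `T` for the lead
#' therapist, which the printed declaration block omits; by default the
#' fixture therefore adds `T` to the turn dimension so that the shipped
#' session fragments parse (eight speakers in total).
#'
#' @param add_therapist Add code `T` (lead therapist) to the turn
#'   dimension (default `TRUE`).  With `FALSE` the instrument is exactly
#'   the parsed declaration block: 7 turn codes, 28 content codes.
#' @return An [observation_instrument()].
#' @examples
#' ins <- study_instrument()
#' length(instrument_codes(ins, "content"))  # 28
#' @export
study_instrument <- function(add_therapist = TRUE) {
  path <- system.file("extdata", "study_instrument.sds", package = "obseq")
  ins <- parse_instrument(readLines(path, warn = FALSE))
  if (add_therapist) {
    ins$dimensions[[ins$turn_dimension]] <-
      c("T", ins$dimensions[[ins$turn_dimension]])
  }
  ins
}

#' Alias map between the two published code spellings
#'
#' The instrument's categories circulate under two spellings; this map
#' pairs the conceptual-description names with the names used in the
#' record dialect (which the packaged fixture adopts).
#'
#' @return Named character vector: names are conceptual-listing codes,
#'   values the record-dialect codes.
#' @export
code_aliases <- function() {
  c(QC = "QACL", QV = "PV", EX = "EE", ORD = "DO")
}

#' Serialize an instrument to JSON
#'
#' @param instrument An [observation_instrument()].
#' @return A JSON string with fields `dimensions` (ordered name/codes
#'   pairs) and `turn_dimension`.
#' @export
instrument_to_json <- function(instrument) {
  stopifnot(inherits(instrument, "obs_instrument"))
  jsonlite::toJSON(
    list(
      dimensions = lapply(
        names(instrument$dimensions),
        function(nm) list(name = nm, codes = instrument$dimensions[[nm]])
      ),
      turn_dimension = instrument$turn_dimension
    ),
    auto_unbox = TRUE, null = "null"
  )
}

#' @rdname instrument_to_json
#' @param json JSON string produced by [instrument_to_json()].
#' @export
instrument_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  dims <- stats::setNames(
    lapply(x$dimensions, function(d) unlist(d$codes)),
    vapply(x$dimensions, function(d) d$name, character(1))
  )
  td <- x$turn_dimension
  observation_instrument(dims, if (is.null(td)) NA_character_ else td)
}
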