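#' Configuration for the synthetic session generator
#'
#' Describes a turn-taking multi-event session: a Markov chain over
#' speakers, a per-speaker emission distribution over content codes,
#' optional lag rules that plant sequential dependencies (after a
#' trigger code at row `i`, the content code of row `i + lag` is
#' overwritten with a response code with a given probability), and
#' optional recurring patterns (an ordered list of content codes written
#' at a fixed gap, inserted a given number of times at non-overlapping
#' anchors).  A seed is mandatory: generation is fully deterministic
#' given the configuration.
#'
#' @param instrument The [observation_instrument()] sessions are coded
#'   with.
#' @param n_rows Number of records to generate.
#' @param turn_matrix Square stochastic matrix of speaker-to-speaker
#'   transition probabilities; row and column names are turn codes, rows
#'   sum to 1.
#' @param emissions Named list mapping each speaker to a named
#'   probability vector over content codes (each summing to 1).
#' @param lag_rules `NULL` or a data.frame with columns `trigger`,
#'   `response`, `lag` (>= 1), `prob` (in `[0, 1]`), applied in row
#'   order; later rules may overwrite the responses of earlier ones.
#' @param patterns `NULL` or a list of lists with elements `codes`
#'   (ordered content codes), `gap` (>= 1 rows between components) and
#'   `n` (number of insertions).
#' @param seed Integer random seed.
#' @return List of class `generator_config`.
#' @seealso [generate_session()], [study_like_config()]
#' @export
generator_config <- function(instrument, n_rows, turn_matrix, emissions,
                             lag_rules = NULL, patterns = NULL, seed) {
  cfg <- structure(
    list(instrument = instrument, n_rows = as.integer(n_rows),
         turn_matrix = turn_matrix, emissions = emissions,
         lag_rules = lag_rules, patterns = patterns,
         seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config A `generator_config`.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ins <- config$instrument
  if (!inherits(ins, "obs_instrument")) stop("config lacks a valid instrument")
  if (is.na(config$n_rows) || config$n_rows < 1L) stop("`n_rows` must be >= 1")
  if (is.na(config$seed)) stop("a seed is required")
  tm <- config$turn_matrix
  if (!is.matrix(tm) || nrow(tm) != ncol(tm) ||
      is.null(rownames(tm)) || !identical(rownames(tm), colnames(tm))) {
    stop("`turn_matrix` must be square with matching row/column speaker names")
  }
  turn_codes <- instrument_codes(ins, "turn")
  if (!all(rownames(tm) %in% turn_codes)) {
    stop("turn_matrix speakers must be turn codes of the instrument")
  }
  if (any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0)) {
    stop("turn_matrix rows must be nonnegative and sum to 1")
  }
  if (!setequal(names(config$emissions), rownames(tm))) {
    stop("`emissions` must name exactly the speakers of `turn_matrix`")
  }
  content_codes <- instrument_codes(ins, "content")
  for (sp in names(config$emissions)) {
    em <- config$emissions[[sp]]
    if (is.null(names(em)) || !all(names(em) %in% content_codes)) {
      stop(sprintf("emission codes of speaker %s must be content codes", sp))
    }
    if (any(em < 0) || abs(sum(em) - 1) > 1e-9) {
      stop(sprintf("emission probabilities of speaker %s must sum to 1", sp))
    }
  }
  if (!is.null(config$lag_rules)) {
    lr <- config$lag_rules
    need <- c("trigger", "response", "lag", "prob")
    if (!is.data.frame(lr) || !all(need %in% names(lr))) {
      stop("`lag_rules` must be a data.frame with trigger/response/lag/prob")
    }
    if (any(lr$lag < 1L)) stop("lag rules require lag >= 1")
    if (any(lr$prob < 0 | lr$prob > 1)) stop("lag rule probabilities must be in [0, 1]")
    if (!all(lr$response %in% content_codes)) stop("lag rule responses must be content codes")
  }
  if (!is.null(config$patterns)) {
    for (p in config$patterns) {
      if (!all(c("codes", "gap", "n") %in% names(p))) {
        stop("each pattern needs `codes`, `gap` and `n`")
      }
      if (p$gap < 1L || p$n < 1L) stop("pattern gap and n must be >= 1")
      if (!all(toupper(p$codes) %in% content_codes)) {
        stop("pattern codes must be content codes")
      }
      span <- (length(p$codes) - 1L) * p$gap + 1L
      if (p$n * span > config$n_rows) {
        stop("pattern insertions exceed the session capacity")
      }
    }
  }
  invisible(config)
}

#' Generate a synthetic multi-event session
#'
#' Row `i` receives a speaker code from the turn Markov chain (initial
#' speaker drawn uniformly) and a content code from that speaker's
#' emission distribution.  Lag rules are then applied in declaration
#' order: wherever the trigger fired at row `i`, the content code of row
#' `i + lag` is overwritten with the response with the stated
#' probability.  Finally each configured pattern is written `n` times at
#' uniformly drawn anchors, rejection-sampled (up to 1000 tries per
#' insertion) so that no two insertions overlap; exhaustion raises a
#' capacity error.  The same configuration and seed always produce the
#' identical session.
#'
#' @param config A [generator_config()].
#' @return An `obs_session` valid against the configured instrument.
#' @export
generate_session <- function(config) {
  validate_generator_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_rows
  speakers <- rownames(config$turn_matrix)
  turn <- character(n)
  turn[1] <- sample(speakers, 1L)
  if (n > 1L) {
    for (i in 2:n) {
      turn[i] <- sample(speakers, 1L, prob = config$turn_matrix[turn[i - 1L], ])
    }
  }
  content <- character(n)
  for (sp in speakers) {
    idx <- which(turn == sp)
    if (length(idx)) {
      em <- config$emissions[[sp]]
      content[idx] <- sample(names(em), length(idx), replace = TRUE, prob = em)
    }
  }

  if (!is.null(config$lag_rules)) {
    for (r in seq_len(nrow(config$lag_rules))) {
      rule <- config$lag_rules[r, ]
      trig <- toupper(rule$trigger); resp <- toupper(rule$response)
      lg <- as.integer(rule$lag)
      idx <- which((content == trig | turn == trig) & seq_len(n) + lg <= n)
      if (length(idx)) {
        hit <- stats::runif(length(idx)) < rule$prob
        content[idx[hit] + lg] <- resp
      }
    }
  }

  if (!is.null(config$patterns)) {
    occupied <- logical(n)
    for (p in config$patterns) {
      codes <- toupper(p$codes)
      gap <- as.integer(p$gap)
      span <- (length(codes) - 1L) * gap + 1L
      offsets <- (seq_along(codes) - 1L) * gap
      for (k in seq_len(p$n)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          anchor <- sample.int(n - span + 1L, 1L)
          rows <- anchor + offsets
          if (!any(occupied[anchor:(anchor + span - 1L)])) {
            content[rows] <- codes
            occupied[anchor:(anchor + span - 1L)] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place all pattern insertions without overlap (capacity error)")
        }
      }
    }
  }

  records <- lapply(seq_len(n), function(i) c(turn[i], content[i]))
  obs_session(records, config$instrument,
              label = sprintf("synthetic-seed-%d", config$seed))
}

#' A study-like generator configuration
#'
#' A ready-made [generator_config()] over [study_instrument()]
#' emulating a group-therapy conversation: eight speakers (lead
#' therapist `T`, co-therapist and six adolescents), turn-taking that
#' returns to the therapist about half the time, and a therapist
#' emission mix dominated by questioning (25%), mentalization (15%) and
#' paraphrasing (10%) — the shares the package's worked examples assume
#' — with the remaining mass spread over the other content codes.
#' Adolescent speakers mostly continue the topic or answer (`EC`, `RA`)
#' with some laughter and joking (`R`, `EO`).
#'
#' @param seed Integer random seed (mandatory).
#' @param n_rows Number of records (default 600).
#' @param lag_rules,patterns Optional plants, as in
#'   [generator_config()].
#' @return A `generator_config`.
#' @examples
#' ses <- generate_session(study_like_config(seed = 1, n_rows = 60))
#' validate_session(ses)$is_valid
#' @export
study_like_config <- function(seed, n_rows = 600L, lag_rules = NULL,
                              patterns = NULL) {
  ins <- study_instrument()
  speakers <- instrument_codes(ins, "turn")      # T O G D JM F L M
  content <- instrument_codes(ins, "content")
  k <- length(speakers)
  tm <- matrix(0, k, k, dimnames = list(speakers, speakers))
  for (sp in speakers) {
    others <- setdiff(speakers, sp)
    if (sp == "T") {
      tm[sp, others] <- 1 / length(others)
    } else {
      tm[sp, "T"] <- 0.5
      rest <- setdiff(others, "T")
      tm[sp, rest] <- 0.5 / length(rest)
    }
  }
  spread <- function(named_mass) {
    rest <- setdiff(content, names(named_mass))
    left <- 1 - sum(named_mass)
    c(named_mass, stats::setNames(rep(left / length(rest), length(rest)), rest))
  }
  therapist <- spread(c(QA = 0.25, MNT = 0.15, RP = 0.10, FF = 0.08))
  adolescent <- spread(c(EC = 0.25, RA = 0.20, R = 0.10, EO = 0.08))
  emissions <- stats::setNames(
    lapply(speakers, function(sp) if (sp == "T") therapist else adolescent),
    speakers)
  generator_config(ins, n_rows = n_rows, turn_matrix = tm,
                   emissions = emissions, lag_rules = lag_rules,
                   patterns = patterns, seed = seed)
}
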