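#' Convert a session into an event series
#'
#' Re-expresses a multi-event session as a set of point processes on the
#' record index timeline: each code becomes an event-type whose
#' occurrence times are the (0-based) indices of the records containing
#' it, and — when `include_pairs = TRUE` — each observed co-occurrence
#' of a turn code with a content code additionally becomes a composite
#' event-type named `"TURN,CODE"` (e.g. `"T,QA"`), so that "the
#' therapist asks a question" can be treated as a unit.  The horizon `T`
#' is the record count; successive records are one time unit apart
#' (event-based data carry no durations).
#'
#' @param session An `obs_session`.
#' @param include_pairs Register turn-by-content co-occurrence
#'   event-types in addition to the atomic codes.
#' @return List of class `event_series`: `times` (named list of strictly
#'   increasing integer vectors) and `horizon`.
#' @export
session_to_series <- function(session, include_pairs = TRUE) {
  stopifnot(inherits(session, "obs_session"))
  n <- length(session$records)
  if (n == 0L) stop("empty session")
  ins <- session$instrument
  turn_codes <- if (is.na(ins$turn_dimension)) character(0) else
    ins$dimensions[[ins$turn_dimension]]
  times <- list()
  for (i in seq_len(n)) {
    codes <- unique(session$records[[i]])
    keys <- codes
    if (include_pairs) {
      tc <- codes[codes %in% turn_codes]
      cc <- codes[!codes %in% turn_codes]
      if (length(tc) == 1L && length(cc) > 0L) {
        keys <- c(keys, paste(tc, cc, sep = ","))
      }
    }
    for (k in keys) times[[k]] <- c(times[[k]], i - 1L)
  }
  structure(list(times = times, horizon = n), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d event-types over %d time units\n",
              length(x$times), x$horizon))
  invisible(x)
}

#' Critical-interval significance test for an ordered event-type pair
#'
#' Tests whether occurrences of event-type B follow occurrences of
#' event-type A within the window `[t + d1, t + d2]` more often than a
#' random-rate null predicts.  Under the null, B occurs independently at
#' each time unit with probability `lambda = N_B / T`, so the chance
#' that a given A-occurrence has at least one B in its
#' `w = d2 - d1 + 1`-unit window is `p0 = 1 - (1 - lambda)^w`.  With `C`
#' the number of A-occurrences actually followed by at least one B in
#' the window (several Bs in one window count once), the p-value is the
#' upper binomial tail `P(X >= C)`, `X ~ Binomial(N_A, p0)`.
#'
#' @param a_times,b_times Sorted nonnegative integer occurrence times.
#' @param horizon Total number of time units `T`.
#' @param d1,d2 Window bounds, `0 <= d1 <= d2`.
#' @return List: `p_value`, `successes` (`C`), `p0`, `n_a`, `n_b`,
#'   `window`, `degenerate` (`TRUE` when `lambda >= 1`, i.e. B occupies
#'   every time unit and the test is uninformative: `p_value = 1`).
#' @examples
#' critical_interval_test(seq(0, 90, 10), seq(1, 91, 10), 100, 1, 1)
#' @export
critical_interval_test <- function(a_times, b_times, horizon, d1 = 1L, d2 = 1L) {
  if (horizon <= 0L) stop("`horizon` must be positive")
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (is.na(d1) || is.na(d2) || d1 < 0L || d1 > d2) stop("need 0 <= d1 <= d2")
  n_a <- length(a_times); n_b <- length(b_times)
  if (n_a < 1L || n_b < 1L) stop("both event-types need at least one occurrence")
  lambda <- n_b / horizon
  if (lambda >= 1) {
    return(list(p_value = 1, successes = n_a, p0 = 1, n_a = n_a, n_b = n_b,
                window = c(d1, d2), degenerate = TRUE))
  }
  w <- d2 - d1 + 1L
  p0 <- 1 - (1 - lambda)^w
  b <- sort(b_times)
  # at least one b in [a + d1, a + d2]?
  C <- sum(findInterval(a_times + d2, b) - findInterval(a_times + d1 - 1L, b) >= 1L)
  p <- stats::pbinom(C - 1L, n_a, p0, lower.tail = FALSE)
  list(p_value = p, successes = C, p0 = p0, n_a = n_a, n_b = n_b,
       window = c(d1, d2), degenerate = FALSE)
}

#' Detection parameters for T-pattern search
#'
#' @param min_occ Minimum number of pattern occurrences (default 30).
#' @param alpha Significance level for the critical-interval test
#'   (default 0.005).
#' @param d1,d2 Critical-interval window applied at every level; the
#'   default `[1, 1]` fixes the temporal distance between components to
#'   one observation unit, which suits event-based data.
#' @param max_interval With `free_interval = TRUE`, largest `d2`
#'   searched.
#' @param free_interval Search over windows `[1, d]`, `d <=
#'   max_interval`, keeping the window with the smallest binomial tail
#'   (uncorrected for the selection; the number of candidates tried is
#'   recorded on each pattern).
#' @param max_levels Maximum pattern depth (levels of composition).
#' @return List of class `detection_params`.
#' @export
detection_params <- function(min_occ = 30L, alpha = 0.005, d1 = 1L, d2 = 1L,
                             max_interval = 5L, free_interval = FALSE,
                             max_levels = 3L) {
  if (min_occ < 1L) stop("`min_occ` must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(min_occ = as.integer(min_occ), alpha = alpha,
                 d1 = as.integer(d1), d2 = as.integer(d2),
                 max_interval = as.integer(max_interval),
                 free_interval = isTRUE(free_interval),
                 max_levels = as.integer(max_levels)),
            class = "detection_params")
}

# greedy earliest-match pairing of left/right occurrences; spans of one
# pattern may not overlap
match_occurrences <- function(a_times, b_times, d1, d2) {
  b <- sort(b_times)
  starts <- integer(0); ends <- integer(0)
  j <- 1L
  last_end <- -1L
  for (a in sort(a_times)) {
    if (a <= last_end) next
    while (j <= length(b) && (b[j] < a + d1 || b[j] <= last_end)) j <- j + 1L
    if (j > length(b)) break
    if (b[j] <= a + d2) {
      starts <- c(starts, a); ends <- c(ends, b[j])
      last_end <- b[j]
      j <- j + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

tp_unit_event <- function(name, times) {
  list(name = name, times = as.integer(sort(times)), m = 1L,
       terminals = name, is_pattern = FALSE)
}

#' Detect T-patterns in an event series
#'
#' Level-wise bottom-up search for recurrent temporal patterns.  Level 1
#' tests every ordered pair of distinct event-types with the
#' critical-interval test; pairs significant at `alpha` whose
#' greedy-matched, non-overlapping occurrences number at least `min_occ`
#' become two-leaf patterns.  Subsequent levels treat detected patterns
#' as units (occurrence time = time of the first terminal) and pair them
#' with all units whose terminal sets are disjoint from theirs,
#' repeating until nothing is added or `max_levels` is reached.
#' Finally, redundancy reduction drops any pattern that occurs as a
#' subtree of another detected pattern at exactly the same set of start
#' times.  Output is sorted by decreasing pattern length `m`, then
#' increasing p-value.
#'
#' @param series An [session_to_series()] result.
#' @param params A [detection_params()] list.
#' @return List of class `tpattern_set`; each element is a `tpattern`
#'   list with `name` (canonical nested-parenthesis form), `left`,
#'   `right` (units), `times`, `occurrences` (data.frame `start`,
#'   `end`), `interval` (`c(d1, d2)`), `p_value`, `m`, `terminals`,
#'   `n_candidate_windows`.
#' @export
detect_tpatterns <- function(series, params = detection_params()) {
  stopifnot(inherits(series, "event_series"), inherits(params, "detection_params"))
  if (length(series$times) == 0L) stop("empty event series")
  horizon <- series$horizon

  units <- lapply(names(series$times), function(nm)
    tp_unit_event(nm, series$times[[nm]]))
  names(units) <- vapply(units, `[[`, character(1), "name")

  windows <- if (params$free_interval) {
    lapply(seq_len(params$max_interval), function(d) c(1L, d))
  } else {
    list(c(params$d1, params$d2))
  }

  test_pair <- function(u, v) {
    best <- NULL
    for (wdw in windows) {
      ct <- critical_interval_test(u$times, v$times, horizon, wdw[1], wdw[2])
      if (is.null(best) || ct$p_value < best$p_value) {
        best <- ct
      }
    }
    best
  }

  compose <- function(u, v, ct) {
    occ <- match_occurrences(u$times, v$times, ct$window[1], ct$window[2])
    if (nrow(occ) < params$min_occ) return(NULL)
    list(name = paste0("(", u$name, " ", v$name, ")"),
         left = u, right = v,
         times = occ$start, occurrences = occ,
         interval = ct$window, p_value = ct$p_value,
         m = u$m + v$m, terminals = c(u$terminals, v$terminals),
         n_candidate_windows = length(windows), is_pattern = TRUE)
  }

  eligible <- function(u) length(u$times) >= params$min_occ
  detected <- list()
  frontier <- names(units)            # unit names new at the previous level
  for (level in seq_len(params$max_levels)) {
    added <- character(0)
    unames <- names(units)
    for (a in unames) {
      for (b in unames) {
        if (a == b) next
        if (!(a %in% frontier || b %in% frontier) && level > 1L) next
        if (level == 1L && !(a %in% frontier || b %in% frontier)) next
        u <- units[[a]]; v <- units[[b]]
        if (!eligible(u) || !eligible(v)) next
        if (length(intersect(u$terminals, v$terminals)) > 0L) next
        ct <- test_pair(u, v)
        if (ct$degenerate || ct$p_value >= params$alpha) next
        pat <- compose(u, v, ct)
        if (is.null(pat)) next
        if (!is.null(units[[pat$name]])) next
        units[[pat$name]] <- pat
        detected[[pat$name]] <- pat
        added <- c(added, pat$name)
      }
    }
    if (length(added) == 0L) break
    frontier <- added
  }

  detected <- reduce_redundant(detected)
  ord <- order(-vapply(detected, `[[`, integer(1), "m"),
               vapply(detected, `[[`, numeric(1), "p_value"))
  structure(unname(detected[ord]), class = "tpattern_set",
            params = params, horizon = horizon)
}

# start times of every subtree instance inside a pattern's occurrences
subtree_starts <- function(unit, starts) {
  res <- list()
  res[[unit$name]] <- starts
  if (isTRUE(unit$is_pattern)) {
    sel <- match(starts, unit$times)
    right_starts <- unit$occurrences$end[sel]
    res <- c(res, subtree_starts(unit$left, starts),
             subtree_starts(unit$right, right_starts))
  }
  res
}

# completeness competition: drop P when a detected Q contains it as a
# subtree occurring at exactly the same set of start times
reduce_redundant <- function(detected) {
  if (length(detected) < 2L) return(detected)
  keep <- rep(TRUE, length(detected))
  nms <- names(detected)
  for (i in seq_along(detected)) {
    p <- detected[[i]]
    for (j in seq_along(detected)) {
      if (i == j) next
      q <- detected[[j]]
      if (q$m <= p$m) next
      sub <- subtree_starts(q, q$times)
      s <- sub[[p$name]]
      if (!is.null(s) && length(s) == length(p$times) &&
          setequal(s, p$times)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  detected[keep]
}

#' @export
print.tpattern_set <- function(x, ...) {
  cat(sprintf("<tpattern_set> %d pattern(s)\n", length(x)))
  for (p in x) {
    cat(sprintf("  %s  m=%d  n=%d  p=%.3g  [%d,%d]\n", p$name, p$m,
                nrow(p$occurrences), p$p_value, p$interval[1], p$interval[2]))
  }
  invisible(x)
}

#' Textual report of detected T-patterns
#'
#' One block per pattern: the nested-parenthesis tree, the per-node
#' critical intervals, the occurrence count and p-value, and the first
#' occurrences.  An empty set yields a "no patterns detected" report.
#'
#' @param patterns A `tpattern_set` (or list of patterns).
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
pattern_report <- function(patterns, path = NULL) {
  lines <- character(0)
  if (length(patterns) == 0L) {
    lines <- "no patterns detected"
  } else {
    for (k in seq_along(patterns)) {
      p <- patterns[[k]]
      lines <- c(lines, sprintf("pattern %d: %s", k, p$name),
                 sprintf("  length m = %d, occurrences = %d, p = %.4g",
                         p$m, nrow(p$occurrences), p$p_value))
      lines <- c(lines, render_tree(p, indent = "  "))
      head_occ <- utils::head(p$occurrences, 5L)
      lines <- c(lines, sprintf("  occurrences (first %d): %s", nrow(head_occ),
                                paste(sprintf("[%d,%d]", head_occ$start,
                                              head_occ$end), collapse = " ")))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

render_tree <- function(unit, indent = "") {
  if (!isTRUE(unit$is_pattern)) {
    return(paste0(indent, unit$name))
  }
  c(paste0(indent, sprintf("[%d,%d]", unit$interval[1], unit$interval[2])),
    render_tree(unit$left, paste0(indent, "  ")),
    render_tree(unit$right, paste0(indent, "  ")))
}

# terminal instance times of each occurrence, for plotting
expand_occurrences <- function(unit, starts = unit$times, occ_id = seq_along(starts)) {
  if (!isTRUE(unit$is_pattern)) {
    return(data.frame(terminal = rep(unit$name, length(starts)),
                      time = starts, occurrence = occ_id,
                      stringsAsFactors = FALSE))
  }
  sel <- match(starts, unit$times)
  rights <- unit$occurrences$end[sel]
  rbind(expand_occurrences(unit$left, starts, occ_id),
        expand_occurrences(unit$right, rights, occ_id))
}

#' Occurrence raster of a detected T-pattern
#'
#' Time on the x-axis, the pattern's terminal event-types stacked on the
#' y-axis in pattern order; one point per terminal instance, connected
#' within each occurrence.
#'
#' @param pattern A single `tpattern` from [detect_tpatterns()].
#' @param title Plot title (defaults to the pattern name).
#' @return A ggplot object.
#' @export
plot_tpattern_occurrences <- function(pattern, title = pattern$name) {
  df <- expand_occurrences(pattern)
  df$terminal <- factor(df$terminal, levels = rev(pattern$terminals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$terminal,
                                   group = .data$occurrence)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Time (observation units)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}
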