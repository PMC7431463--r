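#' @keywords internal
code_presence <- function(session, code) {
  code <- toupper(code)
  vapply(session$records, function(r) code %in% r, logical(1))
}

#' Lagged 2x2 co-occurrence table
#'
#' For a given (criterion) behavior and a conditional behavior, builds
#' the 2x2 table of co-occurrence over all record pairs `(i, i + lag)`
#' with both indices inside the session: rows classify the presence of
#' the given behavior at `i`, columns the presence of the conditional at
#' `i + lag`.  Positive lags look forward, negative lags backward; lag 0
#' counts within-record co-occurrence and is only defined for two
#' distinct codes.  A code "occurs" at a record if it appears anywhere
#' in the record's co-occurrence set, whatever its dimension.
#'
#' @param session An `obs_session`.
#' @param given,conditional Behavior codes.
#' @param lag Signed integer offset in records.
#' @return A 2x2 integer matrix of class `lag_table` (rows: given
#'   yes/no at `i`; columns: conditional yes/no at `i + lag`) with
#'   attributes `given`, `conditional`, `lag` and `n_pairs`.
#' @examples
#' ins <- parse_instrument("($D = A B);")
#' ses <- obs_session(as.list(rep(c("A", "B"), 5)), ins)
#' lag_table(ses, "A", "B", 1)
#' @export
lag_table <- function(session, given, conditional, lag) {
  stopifnot(inherits(session, "obs_session"))
  given <- toupper(given); conditional <- toupper(conditional)
  lag <- as.integer(lag)
  n <- length(session$records)
  if (abs(lag) >= n) stop(sprintf("|lag| = %d out of range for a %d-record session",
                                  abs(lag), n))
  if (lag == 0L && given == conditional) {
    stop("lag 0 of a code with itself is undefined (a code always co-occurs with itself)")
  }
  pa <- code_presence(session, given)
  pb <- code_presence(session, conditional)
  m <- abs(lag)
  if (lag >= 0L) {
    a <- pa[seq_len(n - m)]
    b <- pb[seq_len(n - m) + m]
  } else {
    a <- pa[seq_len(n - m) + m]
    b <- pb[seq_len(n - m)]
  }
  x11 <- sum(a & b); x10 <- sum(a & !b); x01 <- sum(!a & b); x00 <- sum(!a & !b)
  out <- matrix(as.integer(c(x11, x01, x10, x00)), nrow = 2,
                dimnames = list(given = c("yes", "no"),
                                conditional = c("yes", "no")))
  structure(out, class = c("lag_table", class(out)),
            given = given, conditional = conditional, lag = lag,
            n_pairs = n - m)
}

#' Allison-Liker adjusted residual of a lagged 2x2 table
#'
#' Standardizes the observed joint count `x` against its expectation
#' under independence, `m = (row margin x column margin) / N`:
#'
#'   `z = (x - m) / sqrt(m * (1 - rowmargin/N) * (1 - colmargin/N))`
#'
#' Under the null of no sequential association, `z` is asymptotically
#' standard normal; `|z| > 1.96` marks a significant relationship at
#' alpha = 0.05 (activation when `z > 0`, inhibition when `z < 0`).
#' Degenerate margins (a behavior occurring never or always among the
#' paired records) leave the residual undefined and `NA` is returned —
#' a missing value, never 0.
#'
#' @param table A `lag_table`, or any 2x2 count matrix laid out the same
#'   way.
#' @return The adjusted residual `z` (scalar, possibly `NA`).
#' @export
adjusted_residual <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) stop("`table` must be a 2x2 count matrix")
  x <- table[1, 1]
  rowm <- sum(table[1, ])
  colm <- sum(table[, 1])
  n <- sum(table)
  if (n < 1L) stop("empty table")
  if (rowm == 0L || rowm == n || colm == 0L || colm == n) return(NA_real_)
  m <- rowm * colm / n
  (x - m) / sqrt(m * (1 - rowm / n) * (1 - colm / n))
}

#' Lag sequential residual matrix
#'
#' Computes, for one given behavior and a set of conditional behaviors,
#' the observed and expected counts, conditional and expected
#' probabilities, and adjusted residuals across a range of lags.  A
#' minimum of 30 records is required for the analysis to be considered
#' valid; shorter sessions are rejected unless `allow_short = TRUE`
#' (which downgrades the rejection to a warning).
#'
#' Lag-0 entries are computed only for conditional behaviors in a
#' different dimension than the given behavior (categories within a
#' dimension are mutually exclusive, so a same-dimension lag-0 residual
#' is structurally degenerate); other lag-0 entries are reported as
#' undefined.
#'
#' @param session An `obs_session`.
#' @param given The given (criterion) behavior code.
#' @param conditionals Character vector of conditional behavior codes.
#' @param lags Integer vector of lags, e.g. `-5:5`.
#' @param alpha Two-sided significance level for the `significant` flag
#'   (default 0.05, critical value `qnorm(1 - alpha/2)`).
#' @param allow_short Permit sessions shorter than 30 records.
#' @return data.frame of class `residual_matrix` with columns
#'   `conditional`, `lag`, `observed`, `expected`, `p_cond`, `p_exp`,
#'   `z`, `significant`; attributes `given`, `n_rows`, `alpha`,
#'   `z_crit`.
#' @export
residual_matrix <- function(session, given, conditionals, lags,
                            alpha = 0.05, allow_short = FALSE) {
  stopifnot(inherits(session, "obs_session"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  given <- toupper(given); conditionals <- toupper(conditionals)
  lags <- sort(unique(as.integer(lags)))
  n <- length(session$records)
  if (n < 30L) {
    msg <- sprintf(
      "a minimum of 30 records is required for a valid lag sequential analysis (got %d)", n)
    if (allow_short) warning(msg) else stop(msg)
  }
  dim_of <- code_dimension(session$instrument)
  z_crit <- stats::qnorm(1 - alpha / 2)
  rows <- vector("list", length(conditionals) * length(lags))
  k <- 0L
  for (cond in conditionals) {
    for (lg in lags) {
      k <- k + 1L
      same_dim <- !is.na(dim_of[given]) && !is.na(dim_of[cond]) &&
        identical(unname(dim_of[given]), unname(dim_of[cond]))
      if (lg == 0L && (cond == given || same_dim)) {
        rows[[k]] <- data.frame(conditional = cond, lag = lg, observed = NA_integer_,
                                expected = NA_real_, p_cond = NA_real_,
                                p_exp = NA_real_, z = NA_real_,
                                significant = NA, stringsAsFactors = FALSE)
        next
      }
      tab <- lag_table(session, given, cond, lg)
      x <- tab[1, 1]; rowm <- sum(tab[1, ]); colm <- sum(tab[, 1]); np <- sum(tab)
      z <- adjusted_residual(tab)
      rows[[k]] <- data.frame(
        conditional = cond, lag = lg, observed = as.integer(x),
        expected = rowm * colm / np,
        p_cond = if (rowm > 0) x / rowm else NA_real_,
        p_exp = colm / np,
        z = z,
        significant = if (is.na(z)) NA else abs(z) > z_crit,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("residual_matrix", "data.frame"),
            given = given, n_rows = n, alpha = alpha, z_crit = z_crit)
}

#' Construct the behavior pattern around a given behavior
#'
#' Reads a [residual_matrix()] outward from lag 0 and assembles, lag by
#' lag, the conditional behaviors with a significant adjusted residual
#' (`z > z_crit`: activation; `z < -z_crit`: inhibition).  In each
#' direction construction stops at the first applicable rule:
#'
#' * `"no-more-significant"` — the direction holds no (further)
#'   significant behaviors;
#' * `"two-empty-lags"` — two consecutive lags without significant
#'   behaviors were encountered after at least one contributing lag;
#' * `"max-lag"` (only with `strict_maxlag = TRUE`) — two consecutive
#'   lags both contain significant behaviors; the nearer lag is taken as
#'   the MAX LAG and construction stops after it.
#'
#' Undefined residuals count as empty.  Lag-0 entries, when present and
#' significant, are always part of the pattern.
#'
#' @param matrix A `residual_matrix` over a contiguous lag range
#'   containing 0 (or touching it).
#' @param alpha Significance level; defaults to the one the matrix was
#'   built with.
#' @param strict_maxlag Apply stop rule `"max-lag"` (default `FALSE`;
#'   the rule is an interpretive convention and is off unless asked
#'   for).
#' @return List of class `behavior_pattern`: `given`, `entries`
#'   (data.frame `lag`, `conditional`, `z`, `relationship`), and
#'   `truncation` (named character, reasons for the prospective and
#'   retrospective directions).
#' @export
construct_pattern <- function(matrix, alpha = attr(matrix, "alpha"),
                              strict_maxlag = FALSE) {
  stopifnot(inherits(matrix, "residual_matrix"))
  lags <- sort(unique(matrix$lag))
  if (!all(diff(lags) == 1L)) stop("the residual matrix must cover a contiguous lag range")
  if (min(lags) > 0L || max(lags) < 0L) {
    stop("the lag range must contain (or touch) lag 0")
  }
  z_crit <- stats::qnorm(1 - alpha / 2)
  sig_rows <- function(lg) {
    sub <- matrix[matrix$lag == lg & !is.na(matrix$z) & abs(matrix$z) > z_crit, ]
    sub[order(-abs(sub$z)), ]
  }
  entries <- list()
  add <- function(sub) {
    if (nrow(sub)) {
      entries[[length(entries) + 1L]] <<- data.frame(
        lag = sub$lag, conditional = sub$conditional, z = sub$z,
        relationship = ifelse(sub$z > 0, "activation", "inhibition"),
        stringsAsFactors = FALSE)
    }
  }
  if (0L %in% lags) add(sig_rows(0L))

  walk <- function(direction) {
    dir_lags <- if (direction > 0) lags[lags > 0L] else rev(lags[lags < 0L])
    consec_empty <- 0L
    contributed <- FALSE
    prev_sig <- FALSE
    for (lg in dir_lags) {
      sub <- sig_rows(lg)
      has <- nrow(sub) > 0L
      if (strict_maxlag && has && prev_sig) {
        return("max-lag")                       # nearer lag was the MAX LAG
      }
      if (has) {
        add(sub)
        contributed <- TRUE
        consec_empty <- 0L
      } else {
        consec_empty <- consec_empty + 1L
        if (consec_empty >= 2L) {
          return(if (contributed) "two-empty-lags" else "no-more-significant")
        }
      }
      prev_sig <- has
    }
    "no-more-significant"
  }
  truncation <- c(prospective = walk(+1L), retrospective = walk(-1L))
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(lag = integer(0), conditional = character(0), z = numeric(0),
               relationship = character(0), stringsAsFactors = FALSE)
  entries <- entries[order(entries$lag, -abs(entries$z)), ]
  rownames(entries) <- NULL
  structure(
    list(given = attr(matrix, "given"), entries = entries, truncation = truncation,
         alpha = alpha, z_crit = z_crit),
    class = "behavior_pattern"
  )
}

#' @export
print.behavior_pattern <- function(x, ...) {
  cat(sprintf("<behavior_pattern> given = %s (alpha = %g)\n", x$given, x$alpha))
  if (nrow(x$entries) == 0L) {
    cat("  no significant conditional behaviors\n")
  } else {
    for (i in seq_len(nrow(x$entries))) {
      e <- x$entries[i, ]
      cat(sprintf("  lag %+d: %s (z = %.2f, %s)\n",
                  e$lag, e$conditional, e$z, e$relationship))
    }
  }
  cat(sprintf("  truncation: prospective = %s; retrospective = %s\n",
              x$truncation[["prospective"]], x$truncation[["retrospective"]]))
  invisible(x)
}
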