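#' Cohen's kappa for two aligned coders
#'
#' Chance-corrected interobserver agreement for two coders who assigned
#' one categorical code to the same ordered sequence of observation
#' units: `kappa = (po - pe) / (1 - pe)`, with `po` the observed
#' proportion of agreement and `pe` the agreement expected from the
#' marginal code distributions of the k x k confusion matrix.
#'
#' When both coders are constant and identical, `pe = 1` and the ratio
#' is undefined; the conventional value `kappa = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param coder_a,coder_b Character vectors of equal length: the two
#'   coders' codes, unit by unit.
#' @return List of class `kappa_result`: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_units`, `band` (see [landis_koch_band()]),
#'   `degenerate`, and the `confusion` matrix.
#' @examples
#' cohens_kappa(c("A", "A", "B"), c("A", "B", "B"))
#' @export
cohens_kappa <- function(coder_a, coder_b) {
  coder_a <- as.character(coder_a)
  coder_b <- as.character(coder_b)
  if (length(coder_a) != length(coder_b)) {
    stop("coder sequences must have equal length (aligned observation units)")
  }
  n <- length(coder_a)
  if (n < 1L) stop("at least one observation unit is required")
  levs <- sort(unique(c(coder_a, coder_b)))
  conf <- table(factor(coder_a, levels = levs), factor(coder_b, levels = levs))
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  degenerate <- pe >= 1 - 1e-12
  kappa <- if (degenerate) 1 else (po - pe) / (1 - pe)
  structure(
    list(
      kappa = kappa,
      observed_agreement = po,
      expected_agreement = pe,
      n_units = n,
      band = landis_koch_band(kappa),
      degenerate = degenerate,
      confusion = unclass(conf)
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s)%s\n", x$kappa, x$band,
              if (x$degenerate) " [degenerate: pe = 1]" else ""))
  cat(sprintf("  observed agreement %.3f, expected %.3f, n = %d\n",
              x$observed_agreement, x$expected_agreement, x$n_units))
  invisible(x)
}

#' Landis-Koch qualitative band for a kappa value
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return One of `"poor"` (< 0), `"slight"` (0-0.20), `"fair"`
#'   (0.21-0.40), `"moderate"` (0.41-0.60), `"substantial"` (0.61-0.80)
#'   or `"almost perfect"` (0.81-1.00).
#' @export
landis_koch_band <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa < -1 || kappa > 1) {
    stop("`kappa` must be a single value in [-1, 1]")
  }
  eps <- 1e-9   # keep ratio arithmetic off the band boundaries
  if (kappa < 0) "poor"
  else if (kappa <= 0.20 + eps) "slight"
  else if (kappa <= 0.40 + eps) "fair"
  else if (kappa <= 0.60 + eps) "moderate"
  else if (kappa <= 0.80 + eps) "substantial"
  else "almost perfect"
}

#' Interobserver agreement between two codings of one session
#'
#' Aligns two sessions record by record and computes Cohen's kappa per
#' instrument dimension, plus a pooled kappa over the concatenated
#' dimension-wise codings.  Within a dimension, a record in which a
#' coder used no code of that dimension is scored as the explicit
#' pseudo-category `"<none>"`, so disagreement about whether the
#' dimension applies at all counts against agreement.
#'
#' @param session_a,session_b Two `obs_session`s of equal length coded
#'   with the same instrument.
#' @param dimensions Dimension names to include (default: all).
#' @return data.frame with one row per dimension plus a `"<pooled>"`
#'   row: `dimension`, `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_units`, `band`, `degenerate`.
#' @export
session_agreement <- function(session_a, session_b,
                              dimensions = names(session_a$instrument$dimensions)) {
  stopifnot(inherits(session_a, "obs_session"), inherits(session_b, "obs_session"))
  if (length(session_a$records) != length(session_b$records)) {
    stop("sessions must have the same number of records to be aligned")
  }
  ins <- session_a$instrument
  dim_code <- function(session, dim) {
    codes <- ins$dimensions[[dim]]
    vapply(session$records, function(r) {
      hit <- r[r %in% codes]
      if (length(hit) == 0L) "<none>" else hit[1L]
    }, character(1))
  }
  rows <- list()
  pooled_a <- character(0); pooled_b <- character(0)
  for (dm in dimensions) {
    a <- dim_code(session_a, dm)
    b <- dim_code(session_b, dm)
    # prefix so identical codes in different dimensions stay distinct when pooled
    pooled_a <- c(pooled_a, paste(dm, a, sep = ":"))
    pooled_b <- c(pooled_b, paste(dm, b, sep = ":"))
    k <- cohens_kappa(a, b)
    rows[[dm]] <- data.frame(dimension = dm, kappa = k$kappa,
                             observed_agreement = k$observed_agreement,
                             expected_agreement = k$expected_agreement,
                             n_units = k$n_units, band = k$band,
                             degenerate = k$degenerate,
                             stringsAsFactors = FALSE)
  }
  k <- cohens_kappa(pooled_a, pooled_b)
  rows[["<pooled>"]] <- data.frame(dimension = "<pooled>", kappa = k$kappa,
                                   observed_agreement = k$observed_agreement,
                                   expected_agreement = k$expected_agreement,
                                   n_units = k$n_units, band = k$band,
                                   degenerate = k$degenerate,
                                   stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
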