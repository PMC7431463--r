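#' Cochran's Zsum reduction
#'
#' Aggregates independent standard-normal statistics into one score:
#' `Zsum = sum(z) / sqrt(n)`.  Applied to the adjusted residuals of one
#' conditional behavior across a span of lags, whose residuals are
#' treated as independent because each lag is a separate computation.
#'
#' @param z Numeric vector of adjusted residuals (no `NA`s; drop
#'   undefined residuals before calling and reduce `n` accordingly).
#' @return Scalar Zsum.
#' @examples
#' zsum(rep(1.96, 5))  # 1.96 * sqrt(5)
#' @export
zsum <- function(z) {
  if (length(z) == 0L) stop("`z` must contain at least one residual")
  if (anyNA(z)) stop("`z` contains NA; drop undefined residuals first")
  sum(z) / sqrt(length(z))
}

#' Build a polar vector from a prospective/retrospective Zsum pair
#'
#' Each conditional behavior of a polar coordinate analysis is
#' summarized as a vector whose coordinates are the prospective Zsum
#' (x-axis) and retrospective Zsum (y-axis):
#'
#' * `length = sqrt(zsum_p^2 + zsum_r^2)`; lengths above 1.96 mark a
#'   significant focal-conditional association;
#' * quadrant from the sign pair (zero counts as positive):
#'   `(+,+)` I mutual activation, `(-,+)` II focal inhibits / is
#'   activated, `(-,-)` III mutual inhibition, `(+,-)` IV focal
#'   activates / is inhibited;
#' * angle from `phi0 = arcsin(|zsum_r| / length)` mapped into the
#'   quadrant's arc: I `phi0`, II `180 - phi0`, III `180 + phi0`,
#'   IV `360 - phi0` (degrees in `[0, 360)`).
#'
#' A zero-length vector has no direction: it is returned with
#' `angle_deg` and `quadrant` set to `NA` and `degenerate = TRUE`.
#'
#' @param zsum_p,zsum_r Prospective and retrospective Zsum values.
#' @param focal,conditional Optional behavior codes carried along for
#'   reporting.
#' @param crit Significance threshold on the vector length (default
#'   1.96).
#' @return List of class `polar_vector`: `focal`, `conditional`,
#'   `zsum_prospective`, `zsum_retrospective`, `length`, `angle_deg`,
#'   `quadrant`, `significant`, `degenerate`.
#' @examples
#' polar_vector(2.69, 4.23)   # quadrant I, length 5.01
#' polar_vector(0.4, -0.26)   # quadrant IV
#' @export
polar_vector <- function(zsum_p, zsum_r, focal = NA_character_,
                         conditional = NA_character_, crit = 1.96) {
  stopifnot(is.numeric(zsum_p), is.numeric(zsum_r),
            length(zsum_p) == 1L, length(zsum_r) == 1L)
  len <- sqrt(zsum_p^2 + zsum_r^2)
  if (len == 0 || is.na(len)) {
    return(structure(
      list(focal = focal, conditional = conditional,
           zsum_prospective = zsum_p, zsum_retrospective = zsum_r,
           length = len, angle_deg = NA_real_, quadrant = NA_character_,
           significant = FALSE, degenerate = TRUE),
      class = "polar_vector"))
  }
  phi0 <- asin(abs(zsum_r) / len) * 180 / pi
  pos_p <- zsum_p >= 0
  pos_r <- zsum_r >= 0
  if (pos_p && pos_r)       { quadrant <- "I";   angle <- phi0 }
  else if (!pos_p && pos_r) { quadrant <- "II";  angle <- 180 - phi0 }
  else if (!pos_p && !pos_r){ quadrant <- "III"; angle <- 180 + phi0 }
  else                      { quadrant <- "IV";  angle <- 360 - phi0 }
  angle <- angle %% 360
  structure(
    list(focal = focal, conditional = conditional,
         zsum_prospective = zsum_p, zsum_retrospective = zsum_r,
         length = len, angle_deg = angle, quadrant = quadrant,
         significant = len > crit, degenerate = FALSE),
    class = "polar_vector")
}

#' @export
print.polar_vector <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<polar_vector> %s -> %s: zero-length (degenerate)\n",
                x$focal, x$conditional))
  } else {
    cat(sprintf(
      "<polar_vector> %s -> %s: quadrant %s, length %.2f%s, angle %.2f deg (Zp %.2f, Zr %.2f)\n",
      x$focal, x$conditional, x$quadrant, x$length,
      if (x$significant) "(*)" else "", x$angle_deg,
      x$zsum_prospective, x$zsum_retrospective))
  }
  invisible(x)
}

#' Polar coordinate map of a focal behavior
#'
#' Runs the lag sequential analysis around one focal behavior and
#' reduces it to one vector per conditional behavior.  The prospective
#' Zsum aggregates the adjusted residuals at lags `+1 .. +n_lags`.  The
#' retrospective Zsum depends on `mode`:
#'
#' * `"genuine"` (default) — genuine retrospectivity: the session is
#'   read backward in time and the residuals at lags `+1 .. +n_lags` of
#'   the reversed session are aggregated (backward feeding from lag 0 to
#'   -1, -1 to -2, ...);
#' * `"classic"` — the residuals at lags `-1 .. -n_lags` of the original
#'   session, read forward.
#'
#' Lags whose residual is undefined (degenerate margins) are dropped
#' from the aggregation, reducing the divisor `n`, with a warning.
#'
#' @param session An `obs_session` (>= 30 records unless
#'   `allow_short = TRUE`).
#' @param focal Focal behavior code.
#' @param conditionals Conditional behavior codes (must not include the
#'   focal code).
#' @param n_lags Number of prospective and retrospective lags (default
#'   5; at least 5 is the usual recommendation).
#' @param mode `"genuine"` or `"classic"` retrospectivity.
#' @param alpha Significance level passed to [residual_matrix()].
#' @param crit Length threshold for the significance flag.
#' @param allow_short Permit sessions shorter than 30 records.
#' @return data.frame of class `polar_map` with one row per
#'   conditional: `conditional`, `quadrant`, `zsum_prospective`,
#'   `zsum_retrospective`, `length`, `angle_deg`, `significant`,
#'   `n_prospective`, `n_retrospective`; attributes `focal`, `mode`,
#'   `n_lags`.
#' @export
polar_map <- function(session, focal, conditionals, n_lags = 5L,
                      mode = c("genuine", "classic"), alpha = 0.05,
                      crit = 1.96, allow_short = FALSE) {
  stopifnot(inherits(session, "obs_session"))
  mode <- match.arg(mode)
  focal <- toupper(focal); conditionals <- toupper(conditionals)
  n_lags <- as.integer(n_lags)
  if (n_lags < 1L) stop("`n_lags` must be >= 1")
  if (focal %in% conditionals) {
    stop("the focal behavior cannot be one of its own conditional behaviors")
  }
  rm_pro <- residual_matrix(session, focal, conditionals, seq_len(n_lags),
                            alpha = alpha, allow_short = allow_short)
  if (mode == "classic") {
    rm_ret <- residual_matrix(session, focal, conditionals, -seq_len(n_lags),
                              alpha = alpha, allow_short = allow_short)
  } else {
    rev_session <- session
    rev_session$records <- rev(session$records)
    rm_ret <- suppressWarnings(
      residual_matrix(rev_session, focal, conditionals, seq_len(n_lags),
                      alpha = alpha, allow_short = TRUE))
  }
  side_zsum <- function(rm, cond) {
    z <- rm$z[rm$conditional == cond]
    keep <- !is.na(z)
    if (sum(keep) < length(z)) {
      warning(sprintf("%d undefined residual(s) dropped from the Zsum of %s",
                      sum(!keep), cond))
    }
    if (!any(keep)) return(list(zsum = NA_real_, n = 0L))
    list(zsum = zsum(z[keep]), n = sum(keep))
  }
  rows <- lapply(conditionals, function(cond) {
    p <- side_zsum(rm_pro, cond)
    r <- side_zsum(rm_ret, cond)
    if (is.na(p$zsum) || is.na(r$zsum)) {
      return(data.frame(conditional = cond, quadrant = NA_character_,
                        zsum_prospective = p$zsum, zsum_retrospective = r$zsum,
                        length = NA_real_, angle_deg = NA_real_,
                        significant = NA, n_prospective = p$n,
                        n_retrospective = r$n, stringsAsFactors = FALSE))
    }
    v <- polar_vector(p$zsum, r$zsum, focal = focal, conditional = cond,
                      crit = crit)
    data.frame(conditional = cond, quadrant = v$quadrant,
               zsum_prospective = v$zsum_prospective,
               zsum_retrospective = v$zsum_retrospective,
               length = v$length, angle_deg = v$angle_deg,
               significant = v$significant, n_prospective = p$n,
               n_retrospective = r$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("polar_map", "data.frame"),
            focal = focal, mode = mode, n_lags = n_lags, crit = crit)
}

#' Four-quadrant vector map of polar coordinate results
#'
#' Draws the vectors of a polar coordinate analysis: prospective Zsum on
#' the x-axis, retrospective Zsum on the y-axis, a circle of radius
#' `crit` (1.96 by default) marking the significance boundary, one
#' labeled arrow per conditional behavior.  Zero-length (degenerate)
#' vectors are drawn as an origin marker, with a warning.
#'
#' @param vectors A `polar_map` data.frame, a list of
#'   [polar_vector()]s, or any data.frame with columns
#'   `zsum_prospective`, `zsum_retrospective`, `conditional`.
#' @param crit Radius of the significance circle.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_polar_map <- function(vectors, crit = 1.96, title = NULL) {
  if (inherits(vectors, "polar_vector")) vectors <- list(vectors)
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, lapply(vectors, function(v) {
      data.frame(conditional = v$conditional,
                 zsum_prospective = v$zsum_prospective,
                 zsum_retrospective = v$zsum_retrospective,
                 stringsAsFactors = FALSE)
    }))
  }
  if (nrow(vectors) == 0L) stop("at least one vector is required")
  zero <- vectors$zsum_prospective == 0 & vectors$zsum_retrospective == 0
  if (any(zero)) {
    warning(sprintf("%d zero-length vector(s) drawn as origin markers", sum(zero)))
  }
  theta <- seq(0, 2 * pi, length.out = 361)
  circle <- data.frame(x = crit * cos(theta), y = crit * sin(theta))
  lim <- max(crit, abs(vectors$zsum_prospective),
             abs(vectors$zsum_retrospective), na.rm = TRUE) * 1.15
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle, ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_segment(
      data = vectors[!zero, , drop = FALSE],
      ggplot2::aes(x = 0, y = 0, xend = .data$zsum_prospective,
                   yend = .data$zsum_retrospective),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.25, "cm"))) +
    ggplot2::geom_point(
      data = vectors[zero, , drop = FALSE],
      ggplot2::aes(x = .data$zsum_prospective, y = .data$zsum_retrospective),
      shape = 4, size = 3) +
    ggplot2::geom_text(
      data = vectors,
      ggplot2::aes(x = .data$zsum_prospective, y = .data$zsum_retrospective,
                   label = .data$conditional),
      hjust = -0.2, vjust = -0.4, size = 3.2) +
    ggplot2::coord_fixed(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(x = "Prospective Zsum", y = "Retrospective Zsum",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Export a polar vector map to a file
#'
#' @param vectors See [plot_polar_map()].
#' @param path Output file (format from the extension, e.g. `.pdf` or
#'   `.png`).
#' @param width,height Device size in inches.
#' @param ... Passed to [plot_polar_map()].
#' @return The path, invisibly.
#' @export
export_polar_plot <- function(vectors, path, width = 6, height = 6, ...) {
  p <- plot_polar_map(vectors, ...)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}

#' Published polar coordinate worked examples
#'
#' The prospective/retrospective Zsum pairs reported for the therapist
#' as focal behavior in the early and late worked-example sessions,
#' transcribed at their printed two-decimal precision.  Feeding them to
#' [polar_vector()] reproduces the published vector lengths, angles and
#' quadrants (within the rounding of the printed inputs).
#'
#' @return data.frame with columns `session` (`"early"`/`"late"`),
#'   `conditional`, `zsum_prospective`, `zsum_retrospective`.
#' @examples
#' tab <- study_polar_inputs()
#' polar_vector(tab$zsum_prospective[2], tab$zsum_retrospective[2])
#' @export
study_polar_inputs <- function() {
  data.frame(
    session = rep(c("early", "late"), each = 3L),
    conditional = rep(c("QA", "RP", "MNT"), 2L),
    zsum_prospective = c(2.28, 2.69, -1.76, 5.23, 0.4, 4.38),
    zsum_retrospective = c(0.44, 4.23, -0.45, 2.85, -0.26, 6.13),
    stringsAsFactors = FALSE
  )
}
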