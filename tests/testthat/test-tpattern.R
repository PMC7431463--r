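test_that("sessions convert to event series with co-occurrence pair types", {
  ses <- study_session("early")
  ser <- session_to_series(ses)
  expect_identical(ser$horizon, 11L)
  expect_identical(ser$times[["T,QA"]], 0L)
  expect_identical(ser$times[["R"]], c(3L, 10L))
  expect_identical(ser$times[["T"]], c(0L, 2L, 5L, 7L))
  expect_true("T,RP" %in% names(ser$times))

  one <- obs_session(list(c("T", "MNT")), two_dim_instrument())
  ser1 <- session_to_series(one)
  expect_identical(ser1$horizon, 1L)
  expect_setequal(names(ser1$times), c("T", "MNT", "T,MNT"))
  expect_true(all(vapply(ser1$times, identical, logical(1), 0L)))

  no_pairs <- session_to_series(one, include_pairs = FALSE)
  expect_setequal(names(no_pairs$times), c("T", "MNT"))
  expect_error(session_to_series(obs_session(list(), two_dim_instrument())),
               "empty")
})

test_that("critical interval test matches its closed forms", {
  # B follows every A at distance 1: p = p0^10 = (1/10)^10
  ct <- critical_interval_test(seq(0, 90, 10), seq(1, 91, 10), 100, 1, 1)
  expect_identical(ct$successes, 10L)
  expect_equal(ct$p_value, 1e-10, tolerance = 1e-6)

  # C = 0 is never significant
  ct0 <- critical_interval_test(c(0, 10, 20), c(5, 15, 25), 100, 1, 1)
  expect_identical(ct0$successes, 0L)
  expect_equal(ct0$p_value, 1)

  # B everywhere: degenerate, p = 1
  ctd <- critical_interval_test(c(0, 2), 0:9, 10, 1, 1)
  expect_true(ctd$degenerate)
  expect_equal(ctd$p_value, 1)

  expect_error(critical_interval_test(0, 1, 0, 1, 1), "horizon")
  expect_error(critical_interval_test(0, 1, 10, 2, 1), "d1 <= d2")
})

test_that("critical interval test agrees with brute force on random series", {
  set.seed(77)
  for (rep in 1:25) {
    horizon <- sample(50:200, 1)
    a <- sort(sample(0:(horizon - 1), sample(5:15, 1)))
    b <- sort(sample(0:(horizon - 1), sample(5:25, 1)))
    d2 <- sample(1:3, 1)
    ct <- critical_interval_test(a, b, horizon, 1, d2)
    expect_equal(ct$p_value, brute_force_ci_p(a, b, horizon, 1, d2),
                 tolerance = 1e-10)
  }
})

test_that("the null rejection rate of the interval test is conservative", {
  set.seed(13)
  rejections <- 0L
  n_rep <- 400L
  for (i in seq_len(n_rep)) {
    horizon <- 150L
    a <- sort(sample(0:(horizon - 1), 25))
    b <- sort(sample(0:(horizon - 1), 25))
    ct <- critical_interval_test(a, b, horizon, 1, 1)
    if (ct$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a planted lag-1 pair is detected and the min_occ gate holds", {
  plant_series <- function(n_plant, seed) {
    cfg <- study_like_config(
      seed = seed, n_rows = 600,
      patterns = list(list(codes = c("CD", "RB"), gap = 1, n = n_plant)))
    session_to_series(generate_session(cfg), include_pairs = FALSE)
  }
  ser <- plant_series(40, seed = 5)
  det <- detect_tpatterns(ser, detection_params(min_occ = 30, alpha = 0.005))
  expect_true("(CD RB)" %in% vapply(det, `[[`, character(1), "name"))

  ser29 <- plant_series(29, seed = 5)
  det29 <- detect_tpatterns(ser29, detection_params(min_occ = 30, alpha = 0.005))
  expect_false("(CD RB)" %in% vapply(det29, `[[`, character(1), "name"))
})

test_that("every reported occurrence satisfies its node's interval", {
  cfg <- study_like_config(
    seed = 9, n_rows = 600,
    patterns = list(list(codes = c("CD", "RB"), gap = 1, n = 45),
                    list(codes = c("PV", "RT"), gap = 1, n = 40)))
  ser <- session_to_series(generate_session(cfg), include_pairs = FALSE)
  det <- detect_tpatterns(ser, detection_params(min_occ = 30, alpha = 0.005))
  expect_gt(length(det), 0L)
  audit <- function(p) {
    occ <- p$occurrences
    gaps <- occ$end - occ$start
    expect_true(all(gaps >= p$interval[1] & gaps <= p$interval[2]))
    expect_true(all(diff(occ$start) > 0))
    expect_gte(nrow(occ), 30L)
  }
  for (p in det) audit(p)
})

test_that("detection is invariant to a constant time shift", {
  cfg <- study_like_config(
    seed = 4, n_rows = 400,
    patterns = list(list(codes = c("CD", "RB"), gap = 1, n = 35)))
  ser <- session_to_series(generate_session(cfg), include_pairs = FALSE)
  shifted <- ser
  shifted$times <- lapply(ser$times, function(t) t + 50L)
  par <- detection_params(min_occ = 30, alpha = 0.005)
  names_of <- function(d) sort(vapply(d, `[[`, character(1), "name"))
  expect_identical(names_of(detect_tpatterns(ser, par)),
                   names_of(detect_tpatterns(shifted, par)))
})

test_that("detection counts are monotone in min_occ and alpha", {
  cfg <- study_like_config(
    seed = 8, n_rows = 600,
    patterns = list(list(codes = c("CD", "RB"), gap = 1, n = 50),
                    list(codes = c("PV", "RT"), gap = 1, n = 38)))
  ser <- session_to_series(generate_session(cfg), include_pairs = FALSE)
  counts_occ <- vapply(c(20, 30, 40, 60), function(mo) {
    length(detect_tpatterns(ser, detection_params(min_occ = mo, alpha = 0.005)))
  }, numeric(1))
  expect_true(all(diff(counts_occ) <= 0))
  counts_alpha <- vapply(c(1e-6, 1e-3, 0.005, 0.05), function(al) {
    length(detect_tpatterns(ser, detection_params(min_occ = 30, alpha = al)))
  }, numeric(1))
  expect_true(all(diff(counts_alpha) >= 0))
})

test_that("multi-level assembly nests patterns and reports render", {
  # hand-built series: A -> B -> C chains repeated 40 times, spaced out
  starts <- seq(0, by = 10, length.out = 40)
  ser <- structure(
    list(times = list(A = starts, B = starts + 1L, C = starts + 2L),
         horizon = 400L),
    class = "event_series")
  det <- detect_tpatterns(
    ser, detection_params(min_occ = 30, alpha = 0.005, d1 = 1, d2 = 2))
  nms <- vapply(det, `[[`, character(1), "name")
  expect_true(any(grepl("^\\(\\(", nms) | grepl("\\)\\)$", nms)))
  top <- det[[1]]
  expect_identical(top$m, 3L)

  rep_lines <- pattern_report(det)
  expect_true(any(grepl("pattern 1:", rep_lines)))
  expect_identical(pattern_report(list()), "no patterns detected")

  p <- plot_tpattern_occurrences(top)
  expect_s3_class(p, "ggplot")
})

test_that("redundancy reduction drops subtrees with identical start times", {
  starts <- seq(0, by = 10, length.out = 40)
  ser <- structure(
    list(times = list(A = starts, B = starts + 1L, C = starts + 2L),
         horizon = 400L),
    class = "event_series")
  det <- detect_tpatterns(
    ser, detection_params(min_occ = 30, alpha = 0.005, d1 = 1, d2 = 2))
  nms <- vapply(det, `[[`, character(1), "name")
  # (A B) always extends to the 3-leaf pattern at the same starts
  top_names <- nms[grepl("^\\(\\(A B\\)", nms)]
  if (length(top_names) > 0) expect_false("(A B)" %in% nms)
})
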