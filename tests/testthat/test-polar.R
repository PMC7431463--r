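test_that("Zsum follows Cochran's reduction", {
  expect_equal(zsum(rep(0, 5)), 0)
  expect_equal(zsum(rep(1.96, 5)), 1.96 * sqrt(5))
  expect_equal(zsum(2.3), 2.3)
  expect_error(zsum(numeric(0)), "at least one")
  expect_error(zsum(c(1, NA)), "NA")
})

test_that("polar vectors reproduce the published worked examples", {
  inputs <- study_polar_inputs()
  printed <- data.frame(
    session = inputs$session, conditional = inputs$conditional,
    quadrant = c("I", "I", "III", "I", "IV", "I"),
    length = c(2.33, 5.01, 1.81, 5.95, 0.48, 7.54),
    angle = c(10.97, 57.51, 194.25, 28.56, 326.74, 54.45),
    starred = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  for (i in seq_len(nrow(inputs))) {
    v <- polar_vector(inputs$zsum_prospective[i], inputs$zsum_retrospective[i])
    expect_identical(v$quadrant, printed$quadrant[i])
    expect_equal(v$length, printed$length[i], tolerance = 0.02 / printed$length[i])
    expect_lt(abs(v$angle_deg - printed$angle[i]), 0.3)
    expect_identical(v$significant, printed$starred[i])
  }
})

test_that("quadrant, angle and degenerate conventions hold", {
  # zero treated as positive: boundary vector lies in quadrant I at 0 degrees
  v <- polar_vector(1, 0)
  expect_identical(v$quadrant, "I")
  expect_equal(v$angle_deg, 0)
  expect_equal(v$length, 1)

  expect_identical(polar_vector(-1, 0.5)$quadrant, "II")
  expect_identical(polar_vector(-1, -0.5)$quadrant, "III")
  expect_identical(polar_vector(0.5, -1)$quadrant, "IV")

  z <- polar_vector(0, 0)
  expect_true(z$degenerate)
  expect_true(is.na(z$angle_deg))
  expect_true(is.na(z$quadrant))
  expect_false(z$significant)
})

test_that("angle and length round-trip the Zsum pair", {
  set.seed(3)
  for (i in 1:50) {
    p <- runif(1, -5, 5); r <- runif(1, -5, 5)
    v <- polar_vector(p, r)
    expect_equal(v$length * cos(v$angle_deg * pi / 180), p, tolerance = 1e-9)
    expect_equal(v$length * sin(v$angle_deg * pi / 180), r, tolerance = 1e-9)
    expect_gte(v$length, max(abs(p), abs(r)) - 1e-12)
    expect_lte(v$length, abs(p) + abs(r) + 1e-12)
    arc <- switch(v$quadrant, I = c(0, 90), II = c(90, 180),
                  III = c(180, 270), IV = c(270, 360))
    expect_gte(v$angle_deg, arc[1])
    expect_lt(v$angle_deg, arc[2])
  }
})

test_that("polar_map recovers a planted asymmetric dependency in quadrant IV", {
  ins <- two_dim_instrument()
  tm <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("T", "M"), c("T", "M")))
  em <- list(T = c(QA = 0.6, RP = 0.4), M = c(EC = 0.05, MNT = 0.95))
  # EC strongly follows QA, and QA is suppressed right after EC
  cfg <- generator_config(
    ins, 500, tm, em,
    lag_rules = data.frame(trigger = c("QA", "EC"), response = c("EC", "RP"),
                           lag = 1, prob = 0.95),
    seed = 21)
  ses <- generate_session(cfg)
  pm <- polar_map(ses, "QA", "EC", n_lags = 5)
  expect_identical(pm$quadrant, "IV")
  expect_true(pm$significant)
  expect_error(polar_map(ses, "QA", c("QA", "EC")), "focal")
})

test_that("classic and genuine retrospectivity coincide on palindromes", {
  codes <- c("A", "B", "C", "A", "B", rep(c("A", "B", "C"), 12))
  pal <- c(codes, rev(codes))
  ses <- obs_session(as.list(pal), single_dim_instrument(c("A", "B", "C")))
  cls <- suppressWarnings(polar_map(ses, "A", c("B", "C"), mode = "classic"))
  gen <- suppressWarnings(polar_map(ses, "A", c("B", "C"), mode = "genuine"))
  expect_equal(cls$zsum_retrospective, gen$zsum_retrospective, tolerance = 1e-12)
})

test_that("vector plots build for published shapes and degenerate input", {
  inputs <- study_polar_inputs()
  early <- inputs[inputs$session == "early", ]
  p <- plot_polar_map(early)
  expect_s3_class(p, "ggplot")
  expect_warning(
    plot_polar_map(data.frame(conditional = "X", zsum_prospective = 0,
                              zsum_retrospective = 0)),
    "zero-length")
  path <- tempfile(fileext = ".pdf")
  suppressMessages(export_polar_plot(early, path))
  expect_true(file.exists(path) && file.size(path) > 0)
  unlink(path)
})
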