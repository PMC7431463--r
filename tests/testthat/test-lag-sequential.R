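test_that("lagged tables count pairs exactly", {
  ses <- alternating_session(5)   # A B A B ... (10 rows)
  tab <- lag_table(ses, "A", "B", 1)
  expect_identical(attr(tab, "n_pairs"), 9L)
  expect_identical(tab[1, 1], 5L)          # every A is followed by B
  expect_identical(sum(tab[1, ]), 5L)      # given margin
  expect_identical(sum(tab[, 1]), 5L)      # conditional margin

  absent <- lag_table(ses, "C", "B", 1)
  expect_identical(absent[1, 1], 0L)
  expect_identical(sum(absent[1, ]), 0L)

  expect_error(lag_table(ses, "A", "A", 0), "lag 0")
  expect_error(lag_table(ses, "A", "B", 10), "out of range")
})

test_that("the adjusted residual matches its closed form and sign convention", {
  ses <- alternating_session(5)
  z <- adjusted_residual(lag_table(ses, "A", "B", 1))
  expect_equal(z, 3, tolerance = 1e-12)
  expect_equal(z, (5 - 25 / 9) / sqrt((25 / 9) * (4 / 9) * (4 / 9)),
               tolerance = 1e-12)

  # x = m exactly -> z = 0
  tab <- matrix(c(2L, 2L, 2L, 2L), 2)
  expect_equal(adjusted_residual(tab), 0)

  # degenerate margins are reported missing, never 0
  expect_true(is.na(adjusted_residual(matrix(c(0L, 0L, 5L, 4L), 2))))
})

test_that("adjusted residuals agree with brute-force pair enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(10:50, 1)
    codes <- c("A", "B", "C")
    ses <- obs_session(as.list(sample(codes, n, replace = TRUE)),
                       single_dim_instrument(codes))
    for (lag in c(-3, -2, -1, 1, 2, 3)) {
      z <- adjusted_residual(lag_table(ses, "A", "B", lag))
      ref <- brute_force_residual(ses$records, "A", "B", lag)
      if (is.na(ref)) expect_true(is.na(z)) else
        expect_equal(z, ref, tolerance = 1e-12)
    }
  }
})

test_that("time reversal mirrors the sign of the lag", {
  ses <- iid_session(80, seed = 5)
  rev_ses <- ses
  rev_ses$records <- rev(ses$records)
  for (lag in 1:4) {
    expect_equal(adjusted_residual(lag_table(rev_ses, "A", "B", lag)),
                 adjusted_residual(lag_table(ses, "A", "B", -lag)),
                 tolerance = 1e-12)
  }
})

test_that("residual_matrix enforces the 30-record validity floor", {
  short <- iid_session(29, seed = 2)
  expect_error(residual_matrix(short, "A", "B", -2:2), "minimum of 30")
  expect_warning(residual_matrix(short, "A", "B", -2:2, allow_short = TRUE),
                 "minimum of 30")
})

test_that("residual_matrix recovers a planted lag-1 dependency", {
  ins <- two_dim_instrument()
  tm <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("T", "M"), c("T", "M")))
  em <- list(T = c(QA = 0.5, RP = 0.3, MNT = 0.2),
             M = c(EC = 0.8, RP = 0.2))
  cfg <- generator_config(
    ins, 400, tm, em,
    lag_rules = data.frame(trigger = "QA", response = "EC",
                           lag = 1, prob = 0.9),
    seed = 11)
  ses <- generate_session(cfg)
  rm <- residual_matrix(ses, "QA", c("EC", "RP"), -2:2)
  z_planted <- rm$z[rm$conditional == "EC" & rm$lag == 1]
  expect_gt(z_planted, 1.96)
  expect_true(rm$significant[rm$conditional == "EC" & rm$lag == 1])

  # a code never occurring is flagged undefined everywhere
  rm2 <- residual_matrix(ses, "QA", "FO", -2:2)
  expect_true(all(is.na(rm2$z)))
})

test_that("pattern construction applies the three stop rules", {
  # synthetic residual_matrix-shaped inputs
  fake_matrix <- function(entries, lags, given = "T", alpha = 0.05) {
    grid <- expand.grid(conditional = unique(entries$conditional), lag = lags,
                        stringsAsFactors = FALSE)
    grid$z <- 0
    for (i in seq_len(nrow(entries))) {
      grid$z[grid$conditional == entries$conditional[i] &
               grid$lag == entries$lag[i]] <- entries$z[i]
    }
    grid$observed <- 1L; grid$expected <- 1; grid$p_cond <- 0.5; grid$p_exp <- 0.5
    grid$significant <- abs(grid$z) > stats::qnorm(1 - alpha / 2)
    structure(grid[c("conditional", "lag", "observed", "expected",
                     "p_cond", "p_exp", "z", "significant")],
              class = c("residual_matrix", "data.frame"),
              given = given, n_rows = 100L, alpha = alpha,
              z_crit = stats::qnorm(1 - alpha / 2))
  }

  # published late-session pattern shape: MNT at -3, RP at -1, MNT at 0, QA at +1
  m <- fake_matrix(data.frame(conditional = c("MNT", "RP", "MNT", "QA"),
                              lag = c(-3L, -1L, 0L, 1L),
                              z = c(3.45, 3.52, 8.52, 2.83)),
                   lags = -3:2)
  pat <- construct_pattern(m)
  expect_identical(nrow(pat$entries), 4L)
  expect_true(all(pat$entries$relationship == "activation"))
  expect_setequal(pat$entries$lag, c(-3L, -1L, 0L, 1L))

  # all-empty matrix stops immediately with rule (a)
  empty <- fake_matrix(data.frame(conditional = "QA", lag = 1L, z = 0), -3:3)
  p0 <- construct_pattern(empty)
  expect_identical(nrow(p0$entries), 0L)
  expect_identical(unname(p0$truncation), rep("no-more-significant", 2))

  # significant at +-1 only, empty beyond: rule (b)
  m1 <- fake_matrix(data.frame(conditional = c("QA", "QA"), lag = c(-1L, 1L),
                               z = c(2.5, -2.5)), -3:3)
  p1 <- construct_pattern(m1)
  expect_identical(unname(p1$truncation), rep("two-empty-lags", 2))
  expect_identical(p1$entries$relationship, c("activation", "inhibition"))

  # rule (c) only under strict_maxlag: consecutive significant lags
  m2 <- fake_matrix(data.frame(conditional = c("QA", "RP", "MNT"),
                               lag = c(1L, 2L, 3L), z = c(3, 3, 3)), -3:3)
  lax <- construct_pattern(m2)
  expect_identical(nrow(lax$entries), 3L)
  strict <- construct_pattern(m2, strict_maxlag = TRUE)
  expect_identical(strict$truncation[["prospective"]], "max-lag")
  expect_identical(nrow(strict$entries), 1L)
})

test_that("null i.i.d. sequences flag at close to the nominal rate", {
  flags <- 0L; total <- 0L
  for (s in 1:120) {
    ses <- iid_session(150, seed = 1000 + s)
    rm <- residual_matrix(ses, "A", c("B", "C", "D"), c(-2, -1, 1, 2))
    z <- rm$z[!is.na(rm$z)]
    flags <- flags + sum(abs(z) > 1.96)
    total <- total + length(z)
  }
  expect_gt(flags / total, 0.02)
  expect_lt(flags / total, 0.08)
})
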