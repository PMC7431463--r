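# tiny instruments and sessions used across the suite

two_dim_instrument <- function() {
  parse_instrument("($TURN = T M) ($DYN = QA RP MNT EC);", turn_dimension = "TURN")
}

single_dim_instrument <- function(codes = c("A", "B", "C", "D")) {
  observation_instrument(list(C = codes))
}

alternating_session <- function(n_pairs = 5) {
  obs_session(as.list(rep(c("A", "B"), n_pairs)), single_dim_instrument())
}

# i.i.d. uniform single-code session over a given alphabet
iid_session <- function(n, codes = c("A", "B", "C", "D"), seed = 1) {
  ins <- single_dim_instrument(codes)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  obs_session(as.list(sample(codes, n, replace = TRUE)), ins)
}

# brute-force adjusted residual: explicit pair enumeration, independent
# of lag_table()/adjusted_residual() internals
brute_force_residual <- function(records, given, conditional, lag) {
  n <- length(records)
  x <- 0; rowm <- 0; colm <- 0; N <- 0
  for (i in seq_len(n)) {
    j <- i + lag
    if (j < 1 || j > n) next
    N <- N + 1
    a <- given %in% records[[i]]
    b <- conditional %in% records[[j]]
    if (a) rowm <- rowm + 1
    if (b) colm <- colm + 1
    if (a && b) x <- x + 1
  }
  if (rowm == 0 || rowm == N || colm == 0 || colm == N) return(NA_real_)
  m <- rowm * colm / N
  (x - m) / sqrt(m * (1 - rowm / N) * (1 - colm / N))
}

# brute-force critical-interval p-value: direct window scan plus an
# independently coded binomial upper tail
brute_force_ci_p <- function(a_times, b_times, horizon, d1, d2) {
  C <- 0
  for (a in a_times) {
    if (any(b_times >= a + d1 & b_times <= a + d2)) C <- C + 1
  }
  n_a <- length(a_times)
  p0 <- 1 - (1 - length(b_times) / horizon)^(d2 - d1 + 1)
  sum(vapply(C:n_a, function(k) choose(n_a, k) * p0^k * (1 - p0)^(n_a - k),
             numeric(1)))
}
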