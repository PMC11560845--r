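# Independent oracles and fixture builders shared across test files.
# Oracles deliberately re-derive results from first principles and never
# call the implementation path they are checking.

# Brute-force re-implementation of the one-round recursion, written
# directly from the displayed formula with no shared code.
oracle_step <- function(p, g, e, p0) {
  den <- p * g + (1 - p) * e
  if (den == 0) return(0)
  (p * g * p0) / den
}

oracle_iterate <- function(p_init, g, e, p0, n_rounds) {
  out <- numeric(n_rounds + 1)
  out[1] <- p_init
  for (i in seq_len(n_rounds)) out[i + 1] <- oracle_step(out[i], g, e, p0)
  out
}

# Naive wash-out search by plain iteration with a generous cap; NA when
# the cap is reached without crossing (treated as "persists" by callers).
oracle_washout <- function(p_init, g, e, p0, threshold, cap = 10000) {
  p <- p_init
  if (p < threshold) return(0L)
  for (x in seq_len(cap)) {
    p_next <- oracle_step(p, g, e, p0)
    if (p_next < threshold) return(x)
    # numerically stuck at a fixed point at or above the threshold
    if (abs(p_next - p) <= 1e-15) return(NA_integer_)
    p <- p_next
  }
  NA_integer_
}

# Literal 2^n enumeration of sign assignments for the signed-rank test.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  W_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(W_all <= W_obs + 1e-9), mean(W_all >= W_obs - 1e-9)))
}

# One valid measurement row with overridable fields.
make_measurement <- function(...) {
  row <- data.frame(
    line_id = "L1", round = 1L,
    facs_analyzed = 100000, facs_positive = 10,
    wells_sorted_pos = 288, germinated_day1_pos = 15,
    germinated_day2_pos = 18,
    wells_sorted_neg = 96, germinated_day1_neg = 60,
    germinated_day2_neg = 63
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

random_params <- function() {
  transmission_params(g = runif(1), e = runif(1, 0.01, 1), p0 = runif(1))
}
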