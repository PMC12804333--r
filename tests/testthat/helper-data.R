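# Fixtures built in code: the two-subject toy dataset whose statistics are
# hand-computable, and generators for exchangeable null data.

toy_pair <- function() {
  survival_dataset(times = c(1, 2), status = c(1, 1), group = c(1, 2))
}

# k exchangeable groups of unit-rate exponential event times.
null_dataset <- function(n = 30, k = 2, event_prob = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- n * k
  status <- if (event_prob >= 1) rep(1L, N) else rbinom(N, 1, event_prob)
  survival_dataset(rexp(N), status, rep(seq_len(k), each = n))
}

# mirrors the package's per-contrast seed derivation
derive_seed_for_test <- function(master, index) {
  survMCTP:::derive_seed(master, index)
}

expect_step_equal <- function(est, grid, values, tol = 1e-12) {
  expect_equal(est$grid, grid, tolerance = tol)
  expect_equal(unname(est$values), values, tolerance = tol)
}
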