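test_that("joint covariance blocks follow the sharing structure", {
  d <- null_dataset(n = 20, k = 4, event_prob = 0.8, seed = 5)
  ws <- default_weights()
  # disjoint contrasts: zero off-diagonal block
  cs <- make_contrasts("custom", 4, pairs = rbind(c(1, 2), c(3, 4)))
  S <- joint_covariance(d, cs, ws)
  expect_equal(S[1:2, 3:4], matrix(0, 2, 2))

  # diagonal blocks bit-match the pairwise covariance
  tk <- make_contrasts("tukey", 4)
  St <- joint_covariance(d, tk, ws)
  for (i in seq_len(tk$q)) {
    idx <- (i - 1) * 2 + 1:2
    expect_identical(St[idx, idx], wlr_sigma(d, tk$pairs[i, ], ws))
  }

  # k = 2, single contrast: the joint matrix IS the pairwise covariance
  d2 <- null_dataset(n = 25, k = 2, event_prob = 0.7, seed = 6)
  expect_identical(joint_covariance(d2, make_contrasts("tukey", 2), ws),
                   wlr_sigma(d2, c(1, 2), ws))
})

test_that("plug-in and wild-bootstrap joint covariances agree on null data", {
  d <- null_dataset(n = 80, k = 3, event_prob = 0.8, seed = 11)
  cs <- make_contrasts("tukey", 3)
  Sp <- joint_covariance(d, cs)
  Sw <- joint_covariance(d, cs, method = "wild", B = 4000, seed = 5)
  expect_lt(max(abs(Sp - Sw)), 0.08)
  expect_lt(max(abs(diag(Sp) - diag(Sw)) / diag(Sp)), 0.1)
})

test_that("equicoordinate quantile matches closed forms", {
  expect_equal(equicoordinate_quantile(diag(1), 0.05), qnorm(0.975),
               tolerance = 1e-6)
  expect_equal(equicoordinate_quantile(diag(2), 0.05),
               qnorm((1 + sqrt(0.95)) / 2), tolerance = 1e-3)
  for (dim in c(2, 5)) {
    R1 <- matrix(1, dim, dim)
    expect_equal(equicoordinate_quantile(R1, 0.05), qnorm(0.975),
                 tolerance = 1e-3)
  }
  expect_error(equicoordinate_quantile(matrix(c(1, 0, 0, 2), 2), 0.05),
               "unit diagonal")
})

test_that("quantile shrinks as equicorrelation grows and obeys the Bonferroni sandwich", {
  eqc <- function(rho, dm) {
    R <- matrix(rho, dm, dm); diag(R) <- 1
    equicoordinate_quantile(R, 0.05)
  }
  cs <- vapply(c(0, 0.5, 0.9), eqc, numeric(1), dm = 4)
  expect_true(all(diff(cs) < 1e-3))  # non-increasing up to solver tolerance
  for (s in 1:3) {
    set.seed(s)
    A <- matrix(rnorm(16), 4)
    R <- cov2cor(crossprod(A) + diag(4))
    cv <- equicoordinate_quantile(R, 0.05)
    expect_gte(cv, qnorm(1 - 0.05 / 2) - 1e-3)
    expect_lte(cv, qnorm(1 - 0.05 / (2 * 4)) + 1e-3)
  }
})

test_that("maximum test reduces, rejects nothing on identical groups, drops dead coordinates", {
  d <- survival_dataset(rep(c(1, 2, 3, 5), 3), rep(c(1, 0, 1, 1), 3),
                        rep(1:3, each = 4))
  res <- multiweightedlr_test(d, make_contrasts("tukey", 3))
  expect_equal(res$t_max, 0)
  expect_false(res$global_reject)

  # single contrast, single weight: two-sided standardized log-rank at level alpha
  d2 <- null_dataset(n = 30, k = 2, event_prob = 0.8, seed = 13)
  res2 <- multiweightedlr_test(d2, make_contrasts("tukey", 2),
                               ws = list(fleming_harrington(0, 0)))
  v <- wlr_vector(d2, c(1, 2), list(fleming_harrington(0, 0)))
  tstd <- abs(v$stats) / sqrt(v$sigma[1, 1])
  expect_equal(res2$table$statistic, tstd)
  expect_equal(res2$adjustment$critical_value, qnorm(0.975), tolerance = 1e-6)
  expect_equal(res2$table$reject, tstd > qnorm(0.975))

  # a pair with no events at all: its coordinates are dropped with a warning
  set.seed(3)
  d3 <- survival_dataset(c(rexp(20), rexp(20), runif(10), runif(10)),
                         c(rep(1, 40), rep(0, 20)),
                         rep(1:4, times = c(20, 20, 10, 10)))
  expect_warning(res3 <- multiweightedlr_test(d3, make_contrasts("tukey", 4)),
                 "zero estimated variance")
  expect_equal(res3$global_reject, any(res3$table$reject))
})
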