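test_that("at k = 2 the pooled statistic coincides with the pairwise mdir", {
  d <- null_dataset(n = 30, k = 2, event_prob = 0.75, seed = 14)
  v <- wlr_vector(d, c(1, 2))
  cs <- casanova_statistic(d, c(1, 2))
  expect_identical(unname(cs$t_vector), unname(v$stats))
  expect_identical(cs$cov, v$sigma)
  expect_identical(cs$C, mdir_statistic(v))
})

test_that("toy data gives C = 1 and identical groups give C = 0", {
  expect_equal(casanova_statistic(toy_pair(), c(1, 2))$C, 1)

  d <- survival_dataset(c(1, 2, 4, 1, 2, 4, 3, 5, 6),
                        c(1, 1, 0, 1, 1, 0, 1, 1, 1),
                        rep(1:3, each = 3))
  cs <- casanova_statistic(d, c(1, 2))  # groups 1 and 2 share one multiset
  expect_equal(unname(cs$t_vector), c(0, 0))
  expect_equal(cs$C, 0)
})

test_that("wild-bootstrap Nelson-Aalen obeys its defining identities", {
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1))
  expect_equal(wild_bootstrap_na(d, 1, c(1, 1, 1))$values,
               nelson_aalen(counting_processes(d))$values)
  expect_equal(wild_bootstrap_na(d, 1, c(0, 0, 0))$values, rep(0, 3))

  # single event at t = 1 with Y = 3 and multiplier -1
  d2 <- survival_dataset(c(1, 2, 3), c(1, 0, 0), c(1, 1, 1))
  expect_equal(wild_bootstrap_na(d2, 1, c(-1, 9, 9))$values, rep(-1 / 3, 3))

  expect_error(wild_bootstrap_na(d, 1, c(1, 1)), "one multiplier per subject")

  # conditional mean zero: averaging draws on fixed data vanishes
  set.seed(8)
  d3 <- null_dataset(n = 25, k = 1, event_prob = 0.8, seed = 15)
  draws <- replicate(3000,
    wild_bootstrap_na(d3, 1, sample(c(-1, 1), 25, TRUE))$values[25])
  expect_lt(abs(mean(draws)), 4 * sd(draws) / sqrt(3000))

  # invariance under within-group relabeling with the multipliers attached
  perm <- sample(25)
  d4 <- survival_dataset(d3$times[perm], d3$status[perm], rep(1, 25))
  g <- rnorm(25)
  expect_equal(wild_bootstrap_na(d4, 1, g)$values,
               wild_bootstrap_na(d3, 1, g[order(perm)])$values)
})

test_that("multiCASANOVA decisions behave at the edges", {
  d <- survival_dataset(rep(c(1, 2, 3, 4), 3), rep(c(1, 1, 0, 1), 3),
                        rep(1:3, each = 4))
  res <- multicasanova_test(d, make_contrasts("tukey", 3), B = 50, seed = 1)
  expect_equal(res$C_max, 0)
  expect_false(res$global_reject)
  expect_true(all(res$table$p_adj > 0 & res$table$p_adj <= 1))

  # B = 1: the critical value is the single bootstrap draw
  d2 <- null_dataset(n = 15, k = 3, event_prob = 0.8, seed = 16)
  res2 <- multicasanova_test(d2, make_contrasts("tukey", 3), B = 1, seed = 2)
  expect_equal(res2$adjustment$bootstrap_quantile, res2$bootstrap_Cmax)

  expect_error(
    multicasanova_test(d2, make_contrasts("tukey", 3), multiplier = "cauchy"),
    "rademacher")

  # reproducibility under a fixed seed
  res3 <- multicasanova_test(d2, make_contrasts("tukey", 3), B = 100, seed = 9)
  res4 <- multicasanova_test(d2, make_contrasts("tukey", 3), B = 100, seed = 9)
  expect_identical(res3$table, res4$table)
  expect_equal(res3$global_reject, any(res3$table$reject))
})

test_that("Rademacher and centered-Poisson quantiles agree on large null samples", {
  d <- null_dataset(n = 100, k = 3, event_prob = 0.8, seed = 18)
  cs <- make_contrasts("tukey", 3)
  qr_ <- multicasanova_test(d, cs, multiplier = "rademacher", B = 2000,
                            seed = 3)$adjustment$bootstrap_quantile
  qp_ <- multicasanova_test(d, cs, multiplier = "poisson", B = 2000,
                            seed = 4)$adjustment$bootstrap_quantile
  expect_lt(abs(qr_ - qp_) / qr_, 0.2)
})
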