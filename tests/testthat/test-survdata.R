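test_that("counting processes count events and risk sets correctly", {
  d <- survival_dataset(c(1, 2), c(1, 1), c(1, 2))
  cp <- counting_processes(d)
  expect_equal(cp$grid, c(1, 2))
  expect_equal(cp$Y, matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(cp$dN, matrix(c(1L, 0L, 0L, 1L), 2))

  d2 <- survival_dataset(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1))
  cp2 <- counting_processes(d2)
  expect_equal(cp2$Y[, 1], c(3L, 2L, 1L))
  expect_equal(cp2$dN[, 1], c(1L, 1L, 1L))

  # censoring tied with an event: the censored record is still at risk at t
  d3 <- survival_dataset(c(1, 1, 2), c(1, 0, 1), c(1, 1, 1))
  cp3 <- counting_processes(d3)
  expect_equal(cp3$grid, c(1, 2))
  expect_equal(cp3$Y[, 1], c(3L, 1L))
  expect_equal(cp3$dN[, 1], c(1L, 1L))
})

test_that("counting process invariants hold on random data", {
  for (s in 1:5) {
    d <- null_dataset(n = 40, k = 3, event_prob = 0.7, seed = 100 + s)
    cp <- counting_processes(d)
    for (j in 1:3) {
      expect_true(all(diff(cp$Y[, j]) <= 0))
      expect_equal(cp$Y[1, j], d$n_j[j])  # grid covers every group's sample
      expect_equal(sum(cp$dN[, j]), sum(d$status[d$group == j]))
    }
  }
  expect_error(counting_processes(null_dataset(5, 2, seed = 1), groups = "zz"),
               "unknown group")
})

test_that("Nelson-Aalen matches hand summation and edge cases", {
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1))
  na <- nelson_aalen(counting_processes(d))
  expect_step_equal(na, c(1, 2, 3), c(1 / 3, 5 / 6, 11 / 6))

  cens <- survival_dataset(c(1, 2), c(0, 0), c(1, 1))
  expect_equal(nelson_aalen(counting_processes(cens))$values, c(0, 0))

  single <- survival_dataset(1, 1, 1)
  expect_equal(nelson_aalen(counting_processes(single))$values, 1)
})

test_that("Kaplan-Meier matches product-limit by hand", {
  d <- toy_pair()
  km <- kaplan_meier(counting_processes(d))
  expect_step_equal(km, c(1, 2), c(1 / 2, 0))
  Fhat <- kaplan_meier(counting_processes(d), one_minus = TRUE)
  expect_equal(step_left(Fhat, 1), 0)
  expect_equal(step_left(Fhat, 2), 1 / 2)

  cens <- survival_dataset(c(1, 2, 3), c(0, 0, 0), c(1, 1, 1))
  expect_equal(kaplan_meier(counting_processes(cens))$values, rep(1, 3))

  # all events at distinct times: S after the m-th event is (n-m)/n
  n <- 7
  d2 <- survival_dataset(seq_len(n), rep(1, n), rep(1, n))
  expect_equal(kaplan_meier(counting_processes(d2))$values, (n - 1:n) / n)
})

test_that("estimator monotonicity and rank invariance hold", {
  d <- null_dataset(n = 50, k = 2, event_prob = 0.6, seed = 9)
  cp <- counting_processes(d)
  expect_true(all(diff(nelson_aalen(cp, 1)$values) >= 0))
  km <- kaplan_meier(cp)$values
  expect_true(all(diff(km) <= 0) && all(km >= 0 & km <= 1))

  # a strictly increasing time transform leaves all rank statistics unchanged
  d_tr <- survival_dataset(exp(d$times), d$status, d$group)
  for (w in default_weights())
    expect_equal(wlr_statistic(d_tr, c(1, 2), w), wlr_statistic(d, c(1, 2), w))

  # no censoring, distinct times: 1 - S equals the empirical CDF
  d3 <- null_dataset(n = 40, k = 1, seed = 17)
  cp3 <- counting_processes(d3)
  Fhat <- kaplan_meier(cp3, one_minus = TRUE)
  expect_equal(Fhat$values, ecdf(d3$times)(cp3$grid))
})

test_that("dataset validation and the delimited reader work", {
  expect_error(survival_dataset(c(0, 1), c(1, 1), c(1, 2)), "positive")
  expect_error(survival_dataset(c(1, 2), c(1, 2), c(1, 2)), "status")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,status,group", "1.5,1,a", "2,0,b", "3,1,a"), path)
  d <- read_survival_data(path)
  expect_equal(d$k, 2)
  expect_equal(d$times, c(1.5, 2, 3))
  expect_identical(as.character(d$labels), c("a", "b"))

  flip <- read_survival_data(path, flip_status = TRUE)
  expect_equal(flip$status, 1L - d$status)

  writeLines(c("time,grp", "1,1"), path)
  expect_error(read_survival_data(path), "status")

  writeLines(c("time,status,group", "1,1,a", "-2,1,b"), path)
  expect_error(read_survival_data(path), "line")

  out <- withr::local_tempfile(fileext = ".csv")
  write_step_estimate(kaplan_meier(counting_processes(toy_pair())), out)
  tab <- read.csv(out)
  expect_equal(tab$value, c(0.5, 0))
})
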