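test_that("scenario presets carry the documented laws", {
  sc <- scenario("Prop")
  expect_equal(vapply(sc$laws, function(l) l$pars$rate, numeric(1)),
               c(1.2, 1.8, 2.3, 2.9))
  expect_equal(scenario("Cross")$laws[[1]]$pars,
               list(shape = 1.5, scale = 5))
  expect_equal(scenario("Mix")$laws[[3]]$pars,
               list(shape = 2.4, scale = 11.7))
  expect_error(scenario("custom"), "laws")
  expect_error(survival_law("gamma", shape = 1), "unknown distribution")
})

test_that("censoring calibration solves the uniform-censoring identity", {
  # closed form for the exponential law: P(C < T) = (1 - exp(-l u)) / (l u)
  u <- calibrate_censoring(survival_law("exponential", rate = 1.2), 0.3)
  expect_equal((1 - exp(-1.2 * u)) / (1.2 * u), 0.3, tolerance = 1e-6)
  expect_equal(u, 2.66, tolerance = 0.01)
  expect_equal(calibrate_censoring(survival_law("exponential", rate = 1), 0),
               Inf)

  # realized censoring proportion matches the target empirically
  set.seed(19)
  n <- 1e5
  tt <- rexp(n, 1.2)
  cc <- runif(n, 0, u)
  expect_lt(abs(mean(cc < tt) - 0.3), 0.01)

  # and through the sampler itself, per group
  sc <- scenario("Prop", n = 5000, censoring = 0.2)
  d <- sample_scenario(sc, seed = 20)
  for (j in 1:4)
    expect_lt(abs(mean(d$status[d$group == j] == 0) - 0.2), 0.025)
})

test_that("sampling is reproducible and censoring-free when target is 0", {
  sc <- scenario("NProp", n = 30)
  d1 <- sample_scenario(sc, seed = 21)
  d2 <- sample_scenario(sc, seed = 21)
  expect_identical(d1, d2)
  expect_true(all(d1$status == 1))
})

test_that("the truth oracle partitions contrasts by law equality", {
  laws <- list(survival_law("exponential", rate = 1),
               survival_law("exponential", rate = 1),
               survival_law("exponential", rate = 2))
  sc <- scenario("custom", laws = laws, n = 10)
  cs <- make_contrasts("tukey", 3)
  is_null <- survMCTP:::scenario_null_contrasts(sc, cs)
  expect_equal(is_null, c(TRUE, FALSE, FALSE))  # (1,2), (1,3), (2,3)

  # all identical laws: every contrast is null
  sc0 <- scenario("custom",
                  laws = rep(list(survival_law("weibull", 2, 3)), 3), n = 10)
  expect_true(all(survMCTP:::scenario_null_contrasts(sc0, cs)))
})

test_that("scenario hazard shapes are as advertised", {
  tgrid <- seq(0.05, 6, by = 0.05)
  prop <- scenario("Prop")$laws
  hr <- survMCTP:::law_hazard(prop[[2]], tgrid) /
        survMCTP:::law_hazard(prop[[1]], tgrid)
  expect_lt(diff(range(hr)), 1e-8)  # constant hazard ratio

  cross <- scenario("Cross")$laws
  for (i in 1:3) for (j in (i + 1):4) {
    dh <- survMCTP:::law_hazard(cross[[i]], tgrid) -
          survMCTP:::law_hazard(cross[[j]], tgrid)
    expect_true(min(dh) < 0 && max(dh) > 0)  # hazards intersect
  }
})

test_that("the Monte-Carlo harness reports rates, bands and survives edge cases", {
  expect_equal(round(100 * precision_band(0.05, 10000), 2),
               c(lower = 4.57, upper = 5.43))

  sc <- scenario("custom",
                 laws = list(survival_law("exponential", rate = 1),
                             survival_law("exponential", rate = 1),
                             survival_law("exponential", rate = 3)),
                 n = 30, contrasts = "dunnett")
  rep1 <- run_study(sc, c("adjusted_logrank", "multicasanova_rademacher"),
                    runs = 40, B = 50, master_seed = 7)
  expect_true(all(rep1$local_rates >= 0 & rep1$local_rates <= 1))
  expect_equal(rep1$is_null, c(TRUE, FALSE))
  expect_true(all(is.finite(rep1$fwer)))
  # identical master seed reproduces the report
  rep2 <- run_study(sc, c("adjusted_logrank", "multicasanova_rademacher"),
                    runs = 40, B = 50, master_seed = 7)
  expect_identical(rep1$fwer, rep2$fwer)
  expect_identical(rep1$local_rates, rep2$local_rates)
  tidy <- as.data.frame(rep1)
  expect_equal(nrow(tidy), 2 * (1 + 2))  # fwer row + 2 contrasts, per method

  # degenerate group sizes must not crash any method
  sc1 <- scenario("custom",
                  laws = list(survival_law("exponential", rate = 1),
                              survival_law("exponential", rate = 1)),
                  n = 1)
  rep3 <- suppressWarnings(
    run_study(sc1, c("adjusted_logrank", "multicasanova_rademacher"),
              runs = 3, B = 10, master_seed = 8))
  expect_true(all(rep3$local_rates %in% c(0, 1)))
})
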