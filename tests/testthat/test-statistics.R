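# Statistics layer: subject-table reproduction, oracle equivalence of
# Pearson/OLS/Welch, fit recovery, wall sampling.

test_that("subject-table correlations match the printed values", {
  tab <- table1_fixture()
  c1 <- pearson_test(tab$vLV, tab$FS)
  expect_equal(round(c1$r, 2), 0.77)
  expect_equal(round(c1$p, 3), 0.026)
  c2 <- pearson_test(tab$vWMH, tab$FS)
  expect_equal(round(c2$r, 2), 0.95)
  expect_lt(c2$p, 0.001)
})

test_that("subject-table summaries match the printed values", {
  s <- summarize_table1()
  expect_equal(round(s$vLV$mean, 1), 45.7)
  expect_equal(round(s$vLV$sd, 1), 16.2)
  expect_equal(s$vWMH$mean, 8.55)
  expect_equal(round(s$vWMH$sd, 1), 6.6)
  expect_equal(round(s$age$mean, 1), 73.4)
  expect_equal(round(s$age$sd, 1), 5.9)
  expect_equal(s$vWMH_male_mean, 9.35)       # prints as 9.4
  expect_equal(s$vWMH_female_mean, 7.75)     # prints as 7.8
  expect_equal(round(s$vWMH_male_female_ratio, 1), 1.2)
  expect_equal(s$vLV$range, c(30.2, 74.1))
  expect_equal(s$vWMH$range, c(1.1, 20.7))
})

test_that("pearson matches the brute-force formula on seeded inputs and
           is affinely invariant", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearson_test(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    got2 <- pearson_test(3 * x - 7, 0.1 * y + 2)
    expect_equal(got2$r, want$r, tolerance = 1e-12)
  }
  expect_equal(pearson_test(1:10, 2 * (1:10) + 1)$r, 1)
  expect_error(pearson_test(rep(1, 5), 1:5), "variance")
})

test_that("linear fit matches the closed-form OLS oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    x <- runif(n, 1, 10); y <- 2 * x - 3 + rnorm(n)
    got <- fit_linear(x, y)
    want <- ols_oracle(x, y)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  }
  exact <- fit_linear(1:6, 2 * (1:6) + 5)
  expect_equal(exact$r_squared, 1)
  const <- fit_linear(1:6, rep(3, 6))
  expect_equal(const$a, 0)
  expect_equal(const$r_squared, 0)
})

test_that("reciprocal fit recovers known coefficients", {
  r <- c(1, 1.5, 2, 3, 4, 6, 8)
  y <- 0.09 / r + 1.04
  f <- fit_reciprocal(r, y)
  expect_equal(f$a, 0.09, tolerance = 1e-10)
  expect_equal(f$b, 1.04, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # noisy recovery within generous confidence bounds (seeded)
  set.seed(43)
  reps <- replicate(50, {
    yn <- 0.09 / r + 1.04 + rnorm(length(r), sd = 0.002)
    fit_reciprocal(r, yn)$a
  })
  expect_equal(mean(reps), 0.09, tolerance = 0.01)
  expect_error(fit_reciprocal(c(-1, 2, 3), 1:3), "positive")
})

test_that("welch test matches the brute-force formula and behaves at the
           degenerate limits", {
  set.seed(44)
  for (rep in 1:100) {
    a <- rnorm(sample(5:50, 1), mean = 0.2, sd = 1.3)
    b <- rnorm(sample(5:50, 1))
    got <- welch_ttest(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  x <- c(1, 2, 3)
  same <- welch_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("a 2-sigma shift at the reference group sizes is detected with
           high power", {
  set.seed(45)
  hits <- replicate(200, {
    a <- rnorm(41, mean = 2)   # shifted group, delta = 2 sd
    b <- rnorm(199)
    welch_ttest(a, b)$p < 0.05
  })
  expect_gt(mean(hits), 0.99)
})

test_that("wall sampling is equidistant, interpolated, and labelled by
           adjacency", {
  run <- default_subject_run()
  ws <- run$wall_samples
  expect_equal(nrow(ws), 30)
  L <- run$wall$total_length
  expect_equal(diff(ws$arclength), rep(L / 30, 29), tolerance = 1e-9)
  # empty lesion mask: all points negative
  ws0 <- sample_wall_points(run$profile, rep(FALSE, nrow(run$profile)))
  expect_false(any(ws0$positive))
  # caps planted at the horns: positive points cluster near the peaks
  pos_s <- ws$arclength[ws$positive]
  expect_gte(length(pos_s), 2)
  pk_s <- run$horns$horns$arclength
  near_peak <- vapply(pos_s, function(s) {
    min(pmin(abs(s - pk_s), L - abs(s - pk_s)))
  }, numeric(1))
  expect_true(all(near_peak < 0.08 * L))
  # and stretch is significantly higher at lesion-positive points
  expect_lt(run$wall_test$p, 0.05)
  expect_gt(run$wall_test$mean_a, run$wall_test$mean_b)
})
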