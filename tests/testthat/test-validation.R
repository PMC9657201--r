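# Agreement statistics: worked examples frozen from the independent
# brute-force oracles, plus property checks.

test_that("lin_ccc matches its formula on worked examples", {
  expect_identical(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)),
               oracle_ccc(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-14)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
})

test_that("lin_ccc is symmetric, bounded by |r|, and equals r at matched moments", {
  set.seed(41)
  for (i in 1:40) {
    x <- rnorm(30, 10, 3)
    y <- 0.8 * x + rnorm(30, i %% 5, 2)
    expect_equal(lin_ccc(x, y), lin_ccc(y, x), tolerance = 1e-12)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  # equal means and variances: ccc == Pearson r (population-moment identity)
  x <- rnorm(200)
  y <- rev(x) # identical marginal moments
  expect_equal(lin_ccc(x, y), cor(x, y), tolerance = 1e-12)
})

test_that("lin_ccc rejects invalid input", {
  expect_error(lin_ccc(1:3, 1:4), class = "silfat_error")
  expect_error(lin_ccc(c(1, 2), c(1, 2)), class = "silfat_error")
  expect_error(lin_ccc(c(1, 1, 1), c(1, 1, 1)), class = "silfat_error")
})

test_that("bland_altman reproduces hand-computed fixtures", {
  ref <- c(10, 20, 30, 40)
  ba <- bland_altman(ref + 1, ref)
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_low, 1)
  expect_equal(ba$loa_high, 1)
  expect_equal(ba$proportional_bias_slope, 0)

  d <- c(1, -1, 1, -1)
  ba2 <- bland_altman(ref + d, ref)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba2$loa_high, 1.96 * 2 / sqrt(3), tolerance = 1e-12)

  set.seed(7)
  ref3 <- seq(5, 50, length.out = 50) + rnorm(50, 0, 0.1)
  ba3 <- bland_altman(1.1 * ref3, ref3)
  expect_gt(ba3$proportional_bias_slope, 0)
  expect_lt(ba3$proportional_bias_p, 0.05)
})

test_that("error_metrics implements both pure-error definitions", {
  ref <- c(20.8, 24.8, 22.8, 22.8)   # mean 22.8
  pred <- c(22.6, 22.6, 20.6, 24.6)  # mean 22.6
  em <- error_metrics(pred, ref)
  expect_equal(em$ape, 0.2, tolerance = 1e-12)
  expect_equal(em$percent_error, 100 * 0.2 / 22.8, tolerance = 1e-12)
  expect_equal(error_metrics(ref, ref)$ape, 0)
  expect_equal(error_metrics(ref + 1, ref, mode = "rmse")$ape, 1)
  expect_error(error_metrics(c(1, 2), c(0, 2)), class = "silfat_error")
})

test_that("linearity_test handles the identity line and rejections", {
  ref <- seq(8, 50, length.out = 20)
  lt <- linearity_test(ref, ref)
  expect_equal(lt$slope, 1, tolerance = 1e-12)
  expect_equal(lt$intercept, 0, tolerance = 1e-10)
  expect_equal(lt$see, 0, tolerance = 1e-10)
  expect_equal(lt$r2, 1)

  lt2 <- linearity_test(2 * ref, ref)
  expect_lt(lt2$slope_eq1_p, 0.01)

  set.seed(11)
  ref2 <- seq(8, 50, length.out = 200)
  keep <- replicate(100, {
    linearity_test(ref2 + rnorm(200, 0, 2.3), ref2)$slope_eq1_p > 0.05
  })
  expect_gte(mean(keep), 0.9)
})

test_that("paired_comparison matches the t-test and its type-I rate", {
  x <- c(1, 2, 3)
  pc <- paired_comparison(x, x)
  expect_equal(pc$mean_diff, 0)
  expect_true(pc$degenerate)
  expect_equal(pc$p, 1)

  set.seed(3)
  d <- rnorm(100, 1, 1)
  base <- rnorm(100, 20, 5)
  expect_lt(paired_comparison(base + d, base)$p, 1e-10)

  rej <- replicate(1000, paired_comparison(rnorm(50), rep(0, 50))$p < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("reproducibility computes TEM, CV and replicate agreement", {
  t1 <- c(10, 10.5, 11, 10.5)
  r0 <- reproducibility(t1, t1)
  expect_equal(r0$tem, 0)
  expect_equal(r0$cv_percent, 0)
  expect_equal(r0$ccc, 1)

  r1 <- reproducibility(t1, t1 - 1)  # grand mean 10, all diffs +1
  expect_equal(r1$tem, sqrt(4 / 8), tolerance = 1e-12)
  expect_equal(r1$cv_percent, 100 * sqrt(0.5) / 10, tolerance = 1e-12)
  expect_equal(r1$mean_diff, 1)
  expect_equal(r1$sd_diff, 0)
})

test_that("full_report is internally consistent and reorder-invariant", {
  set.seed(19)
  ref <- runif(40, 8, 50)
  pred <- ref + rnorm(40, 0.3, 2)
  rep1 <- full_report(pred, ref)
  expect_equal((rep1$loa_low + rep1$loa_high) / 2, rep1$bias, tolerance = 1e-12)
  expect_lte(abs(rep1$ccc), abs(sqrt(rep1$r2)) + 1e-12)
  o <- sample(40)
  rep2 <- full_report(pred[o], ref[o])
  expect_equal(unclass(rep1), unclass(rep2), tolerance = 1e-12)

  rep3 <- full_report(ref, ref)
  expect_equal(rep3$ape, 0)
  expect_equal(rep3$ccc, 1)
  expect_equal(rep3$r2, 1)
  expect_equal(rep3$bias, 0)
})
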