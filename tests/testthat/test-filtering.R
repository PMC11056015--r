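test_that("pearson_r matches hand-evaluated values and guards degeneracy", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # sum(dx dy) / sqrt(sum dx^2 sum dy^2) = 4 / sqrt(25)
  expect_equal(as.numeric(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))), 0.8)
  r <- pearson_r(c(2, 2, 2), c(1, 2, 3))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation t-test p-values match the t-distribution oracle", {
  expect_equal(corr_t_pvalue(0, 10), 1)
  expect_equal(corr_t_pvalue(1, 5), 0)
  # r = 0.8, n = 4: t = 0.8 sqrt(2 / 0.36), df = 2
  t_ <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(corr_t_pvalue(0.8, 4), 2 * stats::pt(-t_, 2))
  expect_equal(corr_t_pvalue(0.8, 4), 0.2, tolerance = 0.01)
  expect_error(corr_t_pvalue(0.5, 2), "n >= 3")
  # matches cor.test on random data
  set.seed(41)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(corr_t_pvalue(cor(x, y), 20),
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-evaluated step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.02, 0.04)), c(0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates p and is monotone in sorted order", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("a vacuous delta keeps the stage-1 tensor unchanged", {
  set.seed(43)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- matrix(rnorm(30 * 5), 30, 5)
  fit <- fit_pls2(x, y, 2)
  s1 <- filter_stage1(fit, x, y, delta = 1)
  expect_equal(s1$stage1_tensor, fit$coefficient_tensor)
})

test_that("a planted predictor-gene association survives both stages", {
  set.seed(44)
  n <- 100
  x <- zscore_columns(matrix(rnorm(n * 3), n, 3))
  colnames(x) <- c("A", "B", "C")
  y <- matrix(rnorm(n * 6, 0, 0.2), n, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  y[, "g2"] <- 2 * x[, "B"] + rnorm(n, 0, 0.1)
  fit <- fit_pls2(x, y, 3)
  fc <- filter_coefficients(fit, x, y, delta = 0.05)
  expect_gt(abs(fc$coefficients["B", "g2"]), 1)
  # noiseless linear target is retained too
  y2 <- y; y2[, "g3"] <- -1.5 * x[, "C"]
  fit2 <- fit_pls2(x, y2, 3)
  fc2 <- filter_coefficients(fit2, x, y2, delta = 0.05)
  expect_true(fc2$coefficients["C", "g3"] != 0)
})

test_that("filtering only zeroes entries, never alters retained values", {
  set.seed(45)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- matrix(rnorm(60 * 8), 60, 8)
  y[, 1] <- x %*% c(1, -1, 0.5) + rnorm(60, 0, 0.3)
  fit <- fit_pls2(x, y, 3)
  fc <- filter_coefficients(fit, x, y)
  kept <- fc$coefficients != 0
  w1 <- apply(fc$stage1_tensor, c(1, 2), sum)
  expect_equal(fc$coefficients[kept], w1[kept])
  # stage-1 zeroes stay zero after stage 2
  s1zero <- apply(fc$stage1_tensor, c(1, 2), function(v) all(v == 0))
  expect_true(all(fc$coefficients[s1zero] == 0))
  expect_true(all(fc$q_pair[!is.na(fc$q_pair)] >= 0 &
                  fc$q_pair[!is.na(fc$q_pair)] <= 1))
})

test_that("under the global null the retained fraction respects the FDR level", {
  set.seed(46)
  retained <- 0; tested <- 0
  for (rep in 1:30) {
    x <- matrix(rnorm(100 * 3), 100, 3)
    y <- matrix(rnorm(100 * 20), 100, 20)
    fit <- fit_pls2(x, y, 3)
    fc <- filter_coefficients(fit, x, y, delta = 0.05)
    retained <- retained + sum(fc$coefficients != 0)
    tested <- tested + length(fc$coefficients)
  }
  frac <- retained / tested
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / tested))
})

test_that("delta outside (0, 1] is rejected", {
  set.seed(47)
  x <- matrix(rnorm(30), 10, 3)
  y <- matrix(rnorm(20), 10, 2)
  fit <- fit_pls2(x, y, 2)
  expect_error(filter_stage1(fit, x, y, delta = 0), "delta")
  expect_error(filter_stage2(fit$coefficient_tensor, x, y, delta = 1.5),
               "delta")
})
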