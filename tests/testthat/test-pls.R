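test_that("a full-rank self-map is fit exactly", {
  set.seed(31)
  x <- matrix(rnorm(60), 20, 3)
  fit <- fit_pls2(x, x, ncomp = 3)
  expect_equal(unname(coef(fit)), diag(3), tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("full-component PLS equals the OLS normal-equations oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(60), 20, 3)
    y <- matrix(rnorm(100), 20, 5)
    fit <- fit_pls2(x, y, ncomp = 3)
    xc <- scale(x, scale = FALSE)
    yc <- scale(y, scale = FALSE)
    b_ols <- solve(crossprod(xc), crossprod(xc, yc))
    expect_lt(max(abs(coef(fit) - b_ols)), 1e-8)
  }
})

test_that("noise-free rank-1 data is reproduced by one component", {
  # with orthogonal predictors and the latent direction along one of them,
  # the first extracted component coincides with the generating score
  set.seed(32)
  x <- qr.Q(qr(scale(matrix(rnorm(80), 20, 4), scale = FALSE)))
  q <- rnorm(6)
  t_ <- x[, 1]
  y <- t_ %*% t(q)
  fit <- fit_pls2(x, y, ncomp = 1)
  expect_lt(max(abs(fitted(fit) - y)), 1e-8)
})

test_that("coefficient tensor slices sum to the coefficient matrix", {
  set.seed(33)
  for (i in 1:3) {
    x <- matrix(rnorm(25 * 4), 25, 4)
    y <- matrix(rnorm(25 * 7), 25, 7)
    fit <- fit_pls2(x, y, ncomp = i + 1)
    tot <- apply(component_coefficients(fit), c(1, 2), sum)
    expect_lt(max(abs(tot - coef(fit))), 1e-10)
  }
  fit1 <- fit_pls2(matrix(rnorm(40), 20, 2), matrix(rnorm(60), 20, 3), 1)
  expect_equal(unname(component_coefficients(fit1)[, , 1]),
               unname(coef(fit1)), tolerance = 1e-12)
})

test_that("x-scores of successive components are orthogonal", {
  set.seed(34)
  x <- matrix(rnorm(50 * 5), 50, 5)
  y <- matrix(rnorm(50 * 8), 50, 8)
  fit <- fit_pls2(x, y, ncomp = 4)
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
})

test_that("prediction is exact on training data and linear", {
  set.seed(35)
  x <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(80), 20, 4)
  fit <- fit_pls2(x, y, ncomp = 2)
  expect_equal(predict(fit, x), fitted(fit), tolerance = 1e-10)
  # centered all-zero row predicts the response means
  expect_equal(as.numeric(predict(fit, t(fit$x_center))),
               unname(fit$y_center), tolerance = 1e-10)
  # linear combination of training rows maps to the same combination
  comb <- 0.3 * x[1, ] + 0.7 * x[2, ]
  expect_equal(as.numeric(predict(fit, t(comb)) - fit$y_center),
               as.numeric(0.3 * (fitted(fit)[1, ] - fit$y_center) +
                          0.7 * (fitted(fit)[2, ] - fit$y_center)),
               tolerance = 1e-10)
  expect_error(predict(fit, matrix(0, 1, 5)), "columns")
  expect_error(fit_pls2(x, y, ncomp = 4), "ncomp")
})

test_that("cross-validation recovers the generating component count", {
  # one latent score drives both blocks; extra components only fit noise
  set.seed(36)
  n <- 80
  t_ <- rnorm(n)
  x <- t_ %*% t(rnorm(4)) + matrix(rnorm(n * 4, 0, 0.1), n, 4)
  y <- t_ %*% t(rnorm(6)) + matrix(rnorm(n * 6, 0, 0.1), n, 6)
  sel <- select_components_cv(x, y, c_max = 4, folds = 10, seed = 0)
  expect_equal(sel$ncomp, 1L)
  # pure noise: extra components only overfit, smallest wins
  set.seed(100)
  x0 <- matrix(rnorm(200 * 4), 200, 4)
  y0 <- matrix(rnorm(200 * 6), 200, 6)
  sel0 <- select_components_cv(x0, y0, c_max = 4, folds = 10, seed = 0)
  expect_equal(sel0$ncomp, 1L)
  # c_max = 1 short-circuits
  expect_equal(select_components_cv(x, y, c_max = 1)$ncomp, 1L)
  # too few cells reduces the fold count with a warning
  expect_warning(select_components_cv(x[1:8, ], y[1:8, ], c_max = 2,
                                      folds = 10, seed = 0), "folds")
})

test_that("out-of-fold error is invariant to cell order given the seed", {
  set.seed(37)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- matrix(rnorm(40 * 5), 40, 5)
  sel1 <- select_components_cv(x, y, c_max = 3, seed = 4)
  perm <- sample(40)
  sel2 <- select_components_cv(x[perm, ], y[perm, ], c_max = 3, seed = 4)
  expect_equal(sel1$ncomp, sel2$ncomp)
})
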