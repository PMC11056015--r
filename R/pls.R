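#' Multi-response partial least squares (NIPALS PLS2)
#'
#' Fits expression of a cell type's highly variable genes on its z-scored
#' neighbor-type scores by iterative latent-component extraction. Both
#' blocks are mean-centered inside the fit (a numerical no-op when the
#' inputs are already z-scored). For each component c the algorithm
#' extracts an x-weight vector, x-score t_c, x-loading p_c, y-loading q_c
#' and y-score l_c, deflating both blocks by t_c. The coefficient matrix is
#' `B = R Q'` with rotation `R = W (P'W)^{-1}`, and the per-component
#' coefficient tensor has slice c equal to `r_c q_c'`, so the slices sum to
#' `B` exactly. With as many components as the rank of the centered
#' predictor block, `B` equals the ordinary least squares solution.
#'
#' @param x Predictor matrix (cells x A neighbor-type scores).
#' @param y Response matrix (cells x H genes), or a vector for H = 1.
#' @param ncomp Number of components C, `1 <= C <= min(ncol(x), nrow(x)-1)`.
#' @param tol Convergence tolerance of the inner NIPALS loop.
#' @param max_iter Maximum inner iterations per component.
#' @return An object of class `pls2_fit` with elements `x_scores` (t),
#'   `y_scores` (l), `x_weights`, `x_loadings` (P), `y_loadings` (Q),
#'   `rotation`, `coefficients` (A x H), `coefficient_tensor`
#'   (A x H x C), `fitted`, `residuals`, `x_center`, `y_center`,
#'   `ncomp`.
#' @seealso [select_components_cv()], [component_coefficients()],
#'   [predict.pls2_fit()]
#' @export
fit_pls2 <- function(x, y, ncomp, tol = 1e-12, max_iter = 1000) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y disagree on row count")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  cmax <- min(ncol(x), n - 1L)
  if (ncomp < 1 || ncomp > cmax) {
    stop("ncomp must be in [1, ", cmax, "], got ", ncomp)
  }
  x_center <- colMeans(x)
  y_center <- colMeans(y)
  e <- sweep(x, 2, x_center)  # deflated X
  f <- sweep(y, 2, y_center)  # deflated Y
  if (all(abs(e) < .Machine$double.eps)) stop("zero-variance predictor block")

  A <- ncol(x); H <- ncol(y); C <- ncomp
  Tm <- matrix(0, n, C); L <- matrix(0, n, C)
  Wx <- matrix(0, A, C); P <- matrix(0, A, C); Q <- matrix(0, H, C)
  for (c in seq_len(C)) {
    u <- f[, which.max(col_vars(f)), drop = FALSE]
    if (all(abs(u) < 1e-300)) {
      stop("response block fully deflated before component ", c,
           "; reduce ncomp")
    }
    t_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(e, u) / drop(crossprod(u))
      nw <- sqrt(drop(crossprod(w)))
      if (nw < 1e-300) stop("degenerate x-weight at component ", c)
      w <- w / nw
      t <- e %*% w
      q <- crossprod(f, t) / drop(crossprod(t))
      u <- f %*% q / drop(crossprod(q))
      if (!is.null(t_old) &&
          sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    p <- crossprod(e, t) / drop(crossprod(t))
    Tm[, c] <- t; L[, c] <- u
    Wx[, c] <- w; P[, c] <- p; Q[, c] <- q
    e <- e - t %*% t(p)
    f <- f - t %*% t(q)
  }
  rotation <- Wx %*% solve(crossprod(P, Wx))
  coefficients <- rotation %*% t(Q)
  tensor <- array(0, dim = c(A, H, C))
  for (c in seq_len(C)) tensor[, , c] <- rotation[, c] %o% Q[, c]
  if (!is.null(colnames(x)) || !is.null(colnames(y))) {
    dimnames(coefficients) <- list(colnames(x), colnames(y))
    dimnames(tensor) <- list(colnames(x), colnames(y), NULL)
  }
  fitted <- sweep(sweep(x, 2, x_center) %*% coefficients, 2, y_center, "+")
  obj <- list(x_scores = Tm, y_scores = L, x_weights = Wx,
              x_loadings = P, y_loadings = Q, rotation = rotation,
              coefficients = coefficients, coefficient_tensor = tensor,
              fitted = fitted, residuals = y - fitted,
              x_center = x_center, y_center = y_center, ncomp = C)
  class(obj) <- "pls2_fit"
  obj
}

#' @export
print.pls2_fit <- function(x, ...) {
  cat("pls2_fit:", nrow(x$x_scores), "cells,", nrow(x$coefficients),
      "predictors ->", ncol(x$coefficients), "responses,",
      x$ncomp, "component(s)\n")
  invisible(x)
}

#' @export
coef.pls2_fit <- function(object, ...) object$coefficients

#' @export
fitted.pls2_fit <- function(object, ...) object$fitted

#' @export
residuals.pls2_fit <- function(object, ...) object$residuals

#' @export
summary.pls2_fit <- function(object, ...) {
  ss_res <- colSums(object$residuals^2)
  y <- object$fitted + object$residuals
  ss_tot <- colSums(sweep(y, 2, colMeans(y))^2)
  r2 <- 1 - ss_res / pmax(ss_tot, .Machine$double.eps)
  out <- list(ncomp = object$ncomp, r_squared = r2)
  class(out) <- "summary.pls2_fit"
  out
}

#' @export
print.summary.pls2_fit <- function(x, ...) {
  cat("PLS2 fit with", x$ncomp, "component(s)\n")
  cat("per-response R^2: median", format(stats::median(x$r_squared),
                                          digits = 4),
      "range [", format(min(x$r_squared), digits = 4), ",",
      format(max(x$r_squared), digits = 4), "]\n")
  invisible(x)
}

#' Predict responses from a fitted PLS2 model
#'
#' @param object A `pls2_fit`.
#' @param newdata Matrix with the same predictor columns as the training
#'   block.
#' @param ... Unused.
#' @return Predicted response matrix.
#' @export
predict.pls2_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; expected ",
         nrow(object$coefficients))
  }
  sweep(sweep(newdata, 2, object$x_center) %*% object$coefficients,
        2, object$y_center, "+")
}

#' Per-component coefficient decomposition
#'
#' Returns the A x H x C tensor whose slices sum exactly to
#' `coef(fit)` (telescoping identity of the PLS rotation).
#'
#' @param fit A `pls2_fit`.
#' @return Numeric array A x H x C.
#' @export
component_coefficients <- function(fit) {
  stopifnot(inherits(fit, "pls2_fit"))
  fit$coefficient_tensor
}

#' Select the number of PLS components by cross-validation
#'
#' Cells are shuffled with the given seed and split into contiguous folds
#' of near-equal size; for each candidate C the mean out-of-fold root mean
#' squared prediction error is computed, and the C minimizing it is
#' returned (ties go to the smallest C).
#'
#' @param x,y Predictor and response blocks as in [fit_pls2()].
#' @param c_max Largest candidate C (capped at what the fold sizes allow).
#' @param folds Number of folds (default 10; reduced to the number of
#'   cells with a warning if larger).
#' @param seed Seed of the fold shuffle (default 0).
#' @return List with `ncomp` (selected C) and `rmsep` (named vector of
#'   mean out-of-fold RMSEP per candidate C).
#' @export
select_components_cv <- function(x, y, c_max, folds = 10, seed = 0) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (c_max < 1) stop("c_max must be >= 1")
  if (n < folds) {
    warning("fewer cells (", n, ") than folds (", folds, "); using ",
            n, " folds")
    folds <- n
  }
  min_train <- n - ceiling(n / folds)
  c_max <- min(c_max, ncol(x), min_train - 1L)
  if (c_max < 1) stop("too few cells for cross-validation")
  if (c_max == 1) return(list(ncomp = 1L, rmsep = c(`1` = NA_real_)))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds),
                                       rep(0, folds - n %% folds))
  fold_id <- rep(seq_len(folds), times = sizes)
  fold_of <- integer(n)
  fold_of[perm] <- fold_id
  err <- matrix(0, folds, c_max)
  for (k in seq_len(folds)) {
    test <- which(fold_of == k)
    train <- setdiff(seq_len(n), test)
    fit <- fit_pls2(x[train, , drop = FALSE], y[train, , drop = FALSE],
                    ncomp = c_max)
    xc <- sweep(x[test, , drop = FALSE], 2, fit$x_center)
    for (C in seq_len(c_max)) {
      B <- fit$rotation[, seq_len(C), drop = FALSE] %*%
        t(fit$y_loadings[, seq_len(C), drop = FALSE])
      pred <- sweep(xc %*% B, 2, fit$y_center, "+")
      err[k, C] <- sqrt(mean((y[test, , drop = FALSE] - pred)^2))
    }
  }
  rmsep <- colMeans(err)
  names(rmsep) <- seq_len(c_max)
  list(ncomp = as.integer(which.min(rmsep)), rmsep = rmsep)
}
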