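#' Pearson correlation with a degenerate guard
#'
#' Standard Pearson correlation; if either vector has zero variance the
#' correlation is undefined and 0 is returned with attribute
#' `degenerate = TRUE` (treated as non-significant downstream).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  stats::cor(x, y)
}

#' Two-sided p-value of a Pearson correlation
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` referred to a Student t distribution
#' with n - 2 degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation.
#' @param n Sample size (>= 3).
#' @return p-value in \[0, 1\].
#' @export
corr_t_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3, got ", n)
  r <- as.numeric(r)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) m p_(j) / j`, clipped at 1 and
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Stage-1 coefficient filter (component-wise correlation test)
#'
#' For each component c, tests the Pearson correlation of every predictor
#' column with the x-score t_c and of every response column with the
#' y-score l_c; both p-value families (predictors x components, genes x
#' components) are BH-adjusted separately, and the per-component
#' coefficient `w[b, h, c]` is kept only when both `q[b, c] < delta` and
#' `q[h, c] < delta`, otherwise zeroed.
#'
#' @param fit A `pls2_fit`.
#' @param x,y The predictor and response blocks the fit was trained on.
#' @param delta FDR threshold in (0, 1\], default 0.05.
#' @return List with `stage1_tensor` (A x H x C), `q_predictor`
#'   (A x C), `q_gene` (H x C).
#' @export
filter_stage1 <- function(fit, x, y, delta = 0.05) {
  stopifnot(inherits(fit, "pls2_fit"))
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]")
  }
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); A <- ncol(x); H <- ncol(y); C <- fit$ncomp
  p_pred <- matrix(1, A, C)
  p_gene <- matrix(1, H, C)
  for (c in seq_len(C)) {
    t_c <- fit$x_scores[, c]
    l_c <- fit$y_scores[, c]
    for (b in seq_len(A)) {
      r <- pearson_r(x[, b], t_c)
      p_pred[b, c] <- if (isTRUE(attr(r, "degenerate"))) 1
                      else corr_t_pvalue(r, n)
    }
    for (h in seq_len(H)) {
      r <- pearson_r(y[, h], l_c)
      p_gene[h, c] <- if (isTRUE(attr(r, "degenerate"))) 1
                      else corr_t_pvalue(r, n)
    }
  }
  q_pred <- matrix(bh_adjust(as.vector(p_pred)), A, C)
  q_gene <- matrix(bh_adjust(as.vector(p_gene)), H, C)
  tensor <- fit$coefficient_tensor
  for (c in seq_len(C)) {
    mask <- outer(q_pred[, c] < delta, q_gene[, c] < delta, "&")
    tensor[, , c] <- tensor[, , c] * mask
  }
  rownames(q_pred) <- colnames(x)
  rownames(q_gene) <- colnames(y)
  list(stage1_tensor = tensor, q_predictor = q_pred, q_gene = q_gene)
}

#' Stage-2 coefficient filter (direct predictor-gene correlation test)
#'
#' Sums the stage-1 tensor over components; every surviving (predictor,
#' gene) pair is tested by the Pearson correlation between the neighbor
#' score column and the gene's expression, BH-adjusted over all tested
#' pairs within the cell type, and zeroed when `q >= delta`.
#'
#' @param stage1_tensor A x H x C tensor from [filter_stage1()].
#' @param x,y Predictor and response blocks.
#' @param delta FDR threshold in (0, 1\], default 0.05.
#' @return List with `coefficients` (A x H, the final filtered matrix)
#'   and `q_pair` (A x H, `NA` for untested pairs).
#' @export
filter_stage2 <- function(stage1_tensor, x, y, delta = 0.05) {
  if (!is.numeric(delta) || delta <= 0 || delta > 1) {
    stop("delta must lie in (0, 1]")
  }
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  w1 <- apply(stage1_tensor, c(1, 2), sum)
  q_pair <- matrix(NA_real_, nrow(w1), ncol(w1),
                   dimnames = dimnames(w1))
  tested <- which(w1 != 0, arr.ind = TRUE)
  if (nrow(tested) > 0) {
    p <- numeric(nrow(tested))
    for (i in seq_len(nrow(tested))) {
      r <- pearson_r(x[, tested[i, 1]], y[, tested[i, 2]])
      p[i] <- if (isTRUE(attr(r, "degenerate"))) 1 else corr_t_pvalue(r, n)
    }
    q <- bh_adjust(p)
    q_pair[tested] <- q
    drop_idx <- tested[q >= delta, , drop = FALSE]
    w1[drop_idx] <- 0
  }
  list(coefficients = w1, q_pair = q_pair)
}

#' Two-stage FDR filtering of PLS coefficients
#'
#' Applies [filter_stage1()] then [filter_stage2()] to one cell type's
#' fit. Entries zeroed at stage 1 stay zero; retained coefficients keep
#' their fitted values.
#'
#' @param fit A `pls2_fit` for one cell type.
#' @param x,y The blocks the fit was trained on (z-scored neighbor scores
#'   and z-scored HVG expression).
#' @param delta FDR threshold, default 0.05.
#' @param cell_type Optional cell type name recorded in the result.
#' @return Object of class `filtered_coefficients`: `cell_type`,
#'   `stage1_tensor`, `coefficients` (final A x H matrix w''),
#'   `q_predictor`, `q_gene`, `q_pair`, `delta`.
#' @export
filter_coefficients <- function(fit, x, y, delta = 0.05, cell_type = NA) {
  s1 <- filter_stage1(fit, x, y, delta = delta)
  s2 <- filter_stage2(s1$stage1_tensor, x, y, delta = delta)
  obj <- list(cell_type = cell_type,
              stage1_tensor = s1$stage1_tensor,
              coefficients = s2$coefficients,
              q_predictor = s1$q_predictor,
              q_gene = s1$q_gene,
              q_pair = s2$q_pair,
              delta = delta)
  class(obj) <- "filtered_coefficients"
  obj
}

#' @export
print.filtered_coefficients <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("filtered_coefficients",
      if (!is.na(x$cell_type)) paste0("[", x$cell_type, "]"), ":",
      nrow(x$coefficients), "neighbor types x", ncol(x$coefficients),
      "genes;", nz, "retained at delta =", x$delta, "\n")
  invisible(x)
}

#' Filtered coefficients as a long table
#'
#' @param x A `filtered_coefficients`.
#' @param keep_zero Include zeroed entries (default `FALSE`).
#' @return data.frame with columns `cell_type`, `neighbor_type`, `gene`,
#'   `coefficient`, `q_pair`.
#' @export
coefficients_table <- function(x, keep_zero = FALSE) {
  stopifnot(inherits(x, "filtered_coefficients"))
  idx <- if (keep_zero) which(is.finite(x$coefficients), arr.ind = TRUE)
         else which(x$coefficients != 0, arr.ind = TRUE)
  data.frame(cell_type = x$cell_type,
             neighbor_type = rownames(x$coefficients)[idx[, 1]],
             gene = colnames(x$coefficients)[idx[, 2]],
             coefficient = x$coefficients[idx],
             q_pair = x$q_pair[idx],
             stringsAsFactors = FALSE)
}
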