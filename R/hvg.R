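#' Rank highly variable genes by standardized variance
#'
#' Variance-stabilizing ranking of genes within one group of cells: a local
#' (loess) regression of log10 variance on log10 mean predicts each gene's
#' expected standard deviation; expression values are standardized by it,
#' clipped at sqrt(number of cells), and genes are ranked by the variance of
#' the clipped standardized values.
#'
#' @param expression Cells x genes numeric matrix (one cell population).
#'   Genes with zero total expression should be removed beforehand.
#' @param n_top Number of top genes to return (default 2000). If larger
#'   than the number of genes, all genes are returned with a warning.
#' @param loess_span Span of the mean-variance loess fit (default 0.3).
#' @return Character vector of gene ids ranked by decreasing standardized
#'   variance, length `min(n_top, ncol(expression))`.
#' @export
select_hvgs_vst <- function(expression, n_top = 2000, loess_span = 0.3) {
  if (!is.numeric(n_top) || n_top <= 0) stop("n_top must be positive")
  n <- nrow(expression)
  if (n < 10) stop("need at least 10 cells for HVG selection, got ", n)
  genes <- colnames(expression)
  if (is.null(genes)) stop("expression matrix has no gene ids (colnames)")
  mu <- colMeans(expression)
  v <- col_vars(expression)
  varying <- which(v > 0 & mu > 0)
  if (length(varying) < 3) {
    stop("fewer than 3 varying genes (", length(varying), ")")
  }
  fit <- stats::loess(log10(v[varying]) ~ log10(mu[varying]),
                      span = loess_span, degree = 2)
  sd_exp <- rep(NA_real_, length(v))
  sd_exp[varying] <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(n)
  std_var <- numeric(length(v))
  for (j in varying) {
    z <- (expression[, j] - mu[j]) / sd_exp[j]
    z <- pmin(pmax(z, -clip), clip)
    std_var[j] <- sum((z - mean(z))^2) / (n - 1)
  }
  if (n_top > length(genes)) {
    warning("n_top = ", n_top, " exceeds the ", length(genes),
            " available genes; returning all")
    n_top <- length(genes)
  }
  ord <- order(std_var, decreasing = TRUE)
  genes[ord][seq_len(min(n_top, length(genes)))]
}

col_vars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Z-score the columns of a matrix
#'
#' Centers each column and scales by the sample standard deviation.
#' Constant columns are mapped to all zeros.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape and dimnames.
#' @export
zscore_columns <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(col_vars(m))
  out <- sweep(m, 2, mu, "-")
  ok <- is.finite(s) & s > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2, s[ok], "/")
  out[, !ok] <- 0
  out
}

#' Split a dataset into per-cell-type HVG slices
#'
#' For each cell type: subsets its cells, drops genes with zero expression
#' across all of those cells, ranks the remaining genes with
#' [select_hvgs_vst()] and z-scores (sample sd) each retained HVG column
#' within the type.
#'
#' @param dataset A `spatial_dataset`.
#' @param n_top Number of HVGs per type (default 2000).
#' @param min_cells Types with fewer cells are skipped with a warning
#'   (default 10).
#' @param loess_span Passed to [select_hvgs_vst()].
#' @return Named list (one per retained type) of `cell_type_slice`
#'   objects: `cell_type`, `expression` (z-scored cells x HVGs),
#'   `hvg_ids`, `cell_index` (row indices into the parent dataset).
#' @export
split_by_cell_type <- function(dataset, n_top = 2000, min_cells = 10,
                               loess_span = 0.3) {
  validate_spatial_dataset(dataset)
  out <- list()
  for (a in levels(dataset$labels)) {
    idx <- which(dataset$labels == a)
    if (length(idx) < min_cells) {
      warning("cell type '", a, "' has ", length(idx), " cells (< ",
              min_cells, "); skipped")
      next
    }
    sub <- dataset$expression[idx, , drop = FALSE]
    nonzero <- colSums(sub != 0) > 0
    sub <- sub[, nonzero, drop = FALSE]
    hvgs <- suppressWarnings(
      select_hvgs_vst(sub, n_top = n_top, loess_span = loess_span))
    slice <- list(cell_type = a,
                  expression = zscore_columns(sub[, hvgs, drop = FALSE]),
                  hvg_ids = hvgs,
                  cell_index = idx)
    class(slice) <- "cell_type_slice"
    out[[a]] <- slice
  }
  if (length(out) == 0) {
    stop("no cell type has at least ", min_cells, " cells")
  }
  out
}

#' Mean HVG overlap ratio between cell types
#'
#' Mean over ordered pairs (i, j), i != j, of
#' `|H_i intersect H_j| / |H_i|` (mode `"ordered_fraction"`), or of
#' `|H_i intersect H_j| / min(|H_i|, |H_j|)` (mode `"min_fraction"`).
#'
#' @param hvg_sets List of at least two non-empty character vectors of
#'   gene ids, one per cell type.
#' @param mode Overlap definition; default `"ordered_fraction"`.
#' @return A number in \[0, 1\].
#' @export
hvg_overlap_ratio <- function(hvg_sets,
                              mode = c("ordered_fraction", "min_fraction")) {
  mode <- match.arg(mode)
  if (length(hvg_sets) < 2) stop("need at least 2 HVG sets")
  sets <- lapply(hvg_sets, unique)
  if (any(lengths(sets) == 0)) stop("empty HVG set")
  vals <- c()
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j) next
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- if (mode == "ordered_fraction") length(sets[[i]])
               else min(length(sets[[i]]), length(sets[[j]]))
      vals <- c(vals, inter / denom)
    }
  }
  mean(vals)
}
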