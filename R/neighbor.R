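#' Pairwise Euclidean distance matrix
#'
#' @param coordinates Z x 2 numeric matrix of finite coordinates.
#' @return Z x Z symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(coordinates) {
  if (nrow(coordinates) < 2) stop("need at least 2 cells")
  if (any(!is.finite(coordinates))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coordinates))
  dimnames(d) <- list(rownames(coordinates), rownames(coordinates))
  d
}

#' Minimum off-diagonal pairwise distance
#'
#' The normalization constant `dist0` of the neighbor score. Coincident
#' cells (zero minimum) are a hard error; enable a deterministic jitter
#' upstream (see [neighbor_score_matrix()]) if the data contain duplicated
#' coordinates.
#'
#' @param d Distance matrix from [pairwise_distances()].
#' @return Smallest off-diagonal distance (> 0).
#' @export
min_pairwise_distance <- function(d) {
  off <- d[upper.tri(d)]
  m <- min(off)
  if (m <= 0) {
    stop("coincident cells: minimum pairwise distance is 0; ",
         "enable jitter (neighbor_score_matrix(..., jitter = TRUE))")
  }
  m
}

#' Raw neighbor-cell-type scores
#'
#' For each cell c and cell type b, the sum over all other cells m of type
#' b of `log10(dist(c, m) / dist0)` (kernel `"log10_ratio"`, as printed; the
#' score grows with distance), or of `exp(-dist(c, m) / dist0)` (kernel
#' `"exp_decay"`). A type with no other cells contributes 0.
#'
#' @param labels Factor of cell type labels, one per cell.
#' @param d Distance matrix.
#' @param dist0 Positive normalization constant.
#' @param kernel `"log10_ratio"` (default) or `"exp_decay"`.
#' @return Z x A numeric matrix, columns in `levels(labels)` order.
#' @export
raw_neighbor_scores <- function(labels, d, dist0,
                                kernel = c("log10_ratio", "exp_decay")) {
  kernel <- match.arg(kernel)
  stopifnot(dist0 > 0, length(labels) == nrow(d))
  labels <- as.factor(labels)
  k <- if (kernel == "log10_ratio") {
    x <- d / dist0
    x[x <= 0] <- 1  # self-distances; zeroed below anyway
    log10(x)
  } else {
    exp(-d / dist0)
  }
  diag(k) <- 0
  membership <- stats::model.matrix(~ labels - 1)
  colnames(membership) <- levels(labels)
  out <- k %*% membership
  rownames(out) <- rownames(d)
  out
}

#' Neighbor-score matrix of a spatial dataset
#'
#' Computes the raw per-cell score of each neighbor cell type and its
#' column-wise z-score, the predictor block of the per-type regression.
#'
#' @param dataset A `spatial_dataset`.
#' @param kernel Passed to [raw_neighbor_scores()].
#' @param jitter If `TRUE`, coincident cells are displaced by a seeded
#'   uniform perturbation of at most `1e-6` times the bounding-box
#'   diagonal before distances are computed.
#' @param jitter_seed Seed of the jitter (default 0).
#' @return An object of class `neighbor_scores`: list with `raw`
#'   (Z x A), `zscored` (Z x A), `dist0`, `type_order`.
#' @export
neighbor_score_matrix <- function(dataset, kernel = "log10_ratio",
                                  jitter = FALSE, jitter_seed = 0) {
  validate_spatial_dataset(dataset)
  coords <- dataset$coordinates
  d <- pairwise_distances(coords)
  if (jitter && min(d[upper.tri(d)]) <= 0) {
    bbox <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
    if (bbox <= 0) bbox <- 1
    set.seed(jitter_seed)
    coords <- coords + matrix(stats::runif(length(coords), -5e-7, 5e-7) * bbox,
                              nrow(coords), 2)
    d <- pairwise_distances(coords)
  }
  dist0 <- min_pairwise_distance(d)
  raw <- raw_neighbor_scores(dataset$labels, d, dist0, kernel = kernel)
  obj <- list(raw = raw,
              zscored = zscore_columns(raw),
              dist0 = dist0,
              type_order = levels(dataset$labels))
  class(obj) <- "neighbor_scores"
  obj
}

#' @export
print.neighbor_scores <- function(x, ...) {
  cat("neighbor_scores:", nrow(x$raw), "cells x", ncol(x$raw),
      "cell types; dist0 =", format(x$dist0, digits = 6), "\n")
  invisible(x)
}
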