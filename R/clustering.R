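#' Mean silhouette width of a clustering
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own cluster's other members and `b` the smallest mean
#' distance to another cluster. Points in singleton clusters contribute 0,
#' as does the degenerate 0/0 case of coincident points.
#'
#' @param points Numeric matrix, one row per point.
#' @param assignments Integer/factor cluster labels, one per point; at
#'   least 2 non-empty clusters.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_mean <- function(points, assignments) {
  points <- as.matrix(points)
  assignments <- as.integer(as.factor(assignments))
  ks <- sort(unique(assignments))
  if (length(ks) < 2) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignments == assignments[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (k in ks) {
      if (k == assignments[i]) next
      b <- min(b, mean(d[i, assignments == k]))
    }
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Cluster a cell type's filtered HVG coefficient vectors
#'
#' Drops genes whose entire coefficient row is zero, then runs k-means
#' (seeded, `nstart` random restarts, Euclidean) on the genes x A
#' coefficient matrix for each k in `[k_min, min(k_max, n_genes - 1)]`,
#' choosing the k with maximal mean silhouette (ties to the smaller k).
#'
#' @param filtered A `filtered_coefficients` object, or a plain A x H
#'   coefficient matrix (neighbor types x genes).
#' @param k_min,k_max Search range for k (defaults 2 and 15).
#' @param seed Seed used before every k-means run (default 0).
#' @param restarts Random restarts per k (default 10).
#' @return Object of class `gene_clusters`: `cell_type`, `gene_ids`,
#'   `assignments` (1..k, named by gene), `k`, `silhouette_by_k`,
#'   `centers` (k x A).
#' @export
cluster_hvgs <- function(filtered, k_min = 2, k_max = 15, seed = 0,
                         restarts = 10) {
  cell_type <- NA
  if (inherits(filtered, "filtered_coefficients")) {
    cell_type <- filtered$cell_type
    coefs <- filtered$coefficients
  } else {
    coefs <- as.matrix(filtered)
  }
  pts <- t(coefs)                       # genes x neighbor types
  nonzero <- rowSums(pts != 0) > 0
  pts <- pts[nonzero, , drop = FALSE]
  n <- nrow(pts)
  if (n < k_min + 2) {
    stop("only ", n, " genes with a nonzero coefficient row; need at least ",
         k_min + 2)
  }
  n_distinct <- nrow(unique(pts))
  ks <- seq(k_min, min(k_max, n - 1, n_distinct))
  if (length(ks) == 0) stop("no admissible k in [", k_min, ", ", k_max, "]")
  sil <- rep(-Inf, length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(seed)
    km <- tryCatch(
      stats::kmeans(pts, centers = ks[i], nstart = restarts, iter.max = 100),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0)) next
    fits[[i]] <- km
    sil[i] <- silhouette_mean(pts, km$cluster)
  }
  if (all(!is.finite(sil))) stop("k-means failed for every candidate k")
  best <- which.max(sil)
  km <- fits[[best]]
  obj <- list(cell_type = cell_type,
              gene_ids = rownames(pts),
              assignments = stats::setNames(km$cluster, rownames(pts)),
              k = ks[best],
              silhouette_by_k = stats::setNames(sil, ks),
              centers = km$centers)
  class(obj) <- "gene_clusters"
  obj
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat("gene_clusters",
      if (!is.na(x$cell_type)) paste0("[", x$cell_type, "]"), ":",
      length(x$gene_ids), "genes in", x$k, "clusters (mean silhouette",
      format(max(x$silhouette_by_k), digits = 4), ")\n")
  invisible(x)
}

#' Cluster assignments as a table
#'
#' @param x A `gene_clusters`.
#' @return data.frame with columns `cell_type`, `gene`, `cluster`.
#' @export
clusters_table <- function(x) {
  stopifnot(inherits(x, "gene_clusters"))
  data.frame(cell_type = x$cell_type, gene = x$gene_ids,
             cluster = unname(x$assignments), stringsAsFactors = FALSE)
}
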