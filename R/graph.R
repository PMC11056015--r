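#' Cluster-level coefficient matrix
#'
#' Entry (m, b) is the mean filtered coefficient toward neighbor type b
#' over the genes of cluster m.
#'
#' @param filtered A `filtered_coefficients` for one cell type.
#' @param clusters The matching `gene_clusters`.
#' @return k x A numeric matrix (clusters x neighbor types).
#' @export
cluster_coefficient_matrix <- function(filtered, clusters) {
  stopifnot(inherits(filtered, "filtered_coefficients"),
            inherits(clusters, "gene_clusters"))
  coefs <- filtered$coefficients      # A x H
  genes <- clusters$gene_ids
  if (!all(genes %in% colnames(coefs))) {
    stop("cluster genes not found in the coefficient matrix")
  }
  k <- clusters$k
  out <- matrix(0, k, nrow(coefs),
                dimnames = list(NULL, rownames(coefs)))
  for (m in seq_len(k)) {
    members <- genes[clusters$assignments == m]
    if (length(members) == 0) stop("empty cluster ", m)
    out[m, ] <- rowMeans(coefs[, members, drop = FALSE])
  }
  out
}

#' Aggregate cluster coefficients into a cell-type interaction matrix
#'
#' For each receiver type a, the gene-cluster counts are standardized to
#' the minimum over all types (`k_min`): the `k_min` clusters with the
#' largest row L2 norms are kept, and
#' `w[a, b] = sqrt(sum over kept clusters m of entry(m, b)^2)`.
#' Semantically `w[a, b]` is the strength of neighbor type b's effect on
#' type a's genes, i.e. the directed edge b -> a.
#'
#' @param cluster_matrices Named list, one k_a x A matrix per receiver
#'   type (names = receiver types, in graph node order).
#' @param k_min Number of clusters kept per receiver; default the minimum
#'   k_a. Must not exceed any k_a.
#' @return A x A matrix, rows = receivers, columns = senders.
#' @export
aggregate_pair_weights <- function(cluster_matrices, k_min = NULL) {
  types <- names(cluster_matrices)
  if (is.null(types)) stop("cluster_matrices must be a named list")
  ks <- vapply(cluster_matrices, nrow, integer(1))
  if (is.null(k_min)) k_min <- min(ks)
  if (k_min < 1 || any(ks < k_min)) {
    stop("k_min = ", k_min, " exceeds a cell type's cluster count (min ",
         min(ks), ")")
  }
  A <- length(types)
  out <- matrix(0, A, A, dimnames = list(receiver = types, sender = types))
  for (a in types) {
    cm <- cluster_matrices[[a]]
    if (!identical(colnames(cm), types)) {
      cm <- cm[, types, drop = FALSE]
    }
    norms <- sqrt(rowSums(cm^2))
    kept <- order(norms, decreasing = TRUE)[seq_len(k_min)]
    out[a, ] <- sqrt(colSums(cm[kept, , drop = FALSE]^2))
  }
  attr(out, "k_min") <- k_min
  out
}

#' Threshold the aggregated matrix by its mean
#'
#' `mean_weight` is the mean of all off-diagonal entries; entries below it
#' are zeroed, and the diagonal (self-communication) is zeroed.
#'
#' @param aggregated A x A matrix from [aggregate_pair_weights()].
#' @return List with `thresholded` (A x A) and `mean_weight`.
#' @export
threshold_by_mean <- function(aggregated) {
  if (nrow(aggregated) < 2) stop("need at least 2 cell types")
  off <- aggregated[row(aggregated) != col(aggregated)]
  mean_weight <- mean(off)
  th <- aggregated
  th[th < mean_weight] <- 0
  diag(th) <- 0
  list(thresholded = th, mean_weight = mean_weight)
}

#' Path-attenuated communication matrix
#'
#' For every ordered pair of cell types, enumerates all simple directed
#' paths (no repeated nodes, at most `max_len` edges) through the
#' thresholded graph and sums each path's contribution
#' `sum over edge positions s of (weight(e_s) - mean_weight * 10^(1 - s))`,
#' so indirect communication is attenuated ten-fold per additional hop.
#' Because every surviving edge weight is at least `mean_weight`, all
#' contributions are nonnegative.
#'
#' @param thresholded A x A matrix (rows = receivers, columns = senders)
#'   with zero diagonal, as produced by [threshold_by_mean()].
#' @param mean_weight The thresholding constant.
#' @param max_len Maximum path length in edges (default A - 1).
#' @return A x A matrix `R`; `R[src, dst]` is the attenuated strength of
#'   communication from sender type `src` to receiver type `dst` (0 when
#'   no path exists).
#' @export
attenuate_paths <- function(thresholded, mean_weight, max_len = NULL) {
  A <- nrow(thresholded)
  types <- rownames(thresholded)
  if (is.null(types)) types <- paste0("T", seq_len(A))
  if (is.null(max_len)) max_len <- A - 1
  if (any(diag(thresholded) != 0)) stop("diagonal must be zero")
  # edge sender -> receiver carries thresholded[receiver, sender]
  adj <- t(thresholded)                 # adj[src, dst] = weight of src -> dst
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  R <- matrix(0, A, A, dimnames = list(types, types))
  for (src in seq_len(A)) {
    if (igraph::degree(g, src, mode = "out") == 0) next
    for (dst in seq_len(A)) {
      if (src == dst) next
      paths <- igraph::all_simple_paths(g, from = src, to = dst,
                                        mode = "out", cutoff = max_len)
      total <- 0
      for (p in paths) {
        v <- as.integer(p)
        w <- adj[cbind(v[-length(v)], v[-1])]
        s <- seq_along(w)
        total <- total + sum(w - mean_weight * 10^(1 - s))
      }
      R[src, dst] <- total
    }
  }
  R
}

#' Build the full cell-type communication graph
#'
#' Composes [cluster_coefficient_matrix()], [aggregate_pair_weights()],
#' [threshold_by_mean()] and [attenuate_paths()] over all cell types.
#'
#' @param filtered_list Named list of `filtered_coefficients`, one per
#'   cell type.
#' @param cluster_list Named list of matching `gene_clusters`.
#' @param k_min Override for the cluster-count standardization (default:
#'   minimum k over cell types).
#' @param max_len Maximum path length in edges (default A - 1).
#' @return Object of class `communication_graph`: `aggregated`,
#'   `mean_weight`, `thresholded`, `attenuated`, `max_path_len`,
#'   `k_min`, `type_order`.
#' @export
communication_graph <- function(filtered_list, cluster_list, k_min = NULL,
                                max_len = NULL) {
  types <- names(filtered_list)
  stopifnot(identical(types, names(cluster_list)))
  mats <- stats::setNames(lapply(types, function(a) {
    cluster_coefficient_matrix(filtered_list[[a]], cluster_list[[a]])
  }), types)
  aggregated <- aggregate_pair_weights(mats, k_min = k_min)
  th <- threshold_by_mean(aggregated)
  if (is.null(max_len)) max_len <- length(types) - 1
  attenuated <- attenuate_paths(th$thresholded, th$mean_weight,
                                max_len = max_len)
  obj <- list(aggregated = aggregated,
              mean_weight = th$mean_weight,
              thresholded = th$thresholded,
              attenuated = attenuated,
              max_path_len = max_len,
              k_min = attr(aggregated, "k_min"),
              type_order = types)
  class(obj) <- "communication_graph"
  obj
}

#' @export
print.communication_graph <- function(x, ...) {
  n_edges <- sum(x$thresholded != 0)
  cat("communication_graph:", length(x$type_order), "cell types,",
      n_edges, "edges above mean weight",
      format(x$mean_weight, digits = 6), "\n")
  invisible(x)
}

graph_edge_list <- function(m, receiver_rows = TRUE) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (receiver_rows) {
    data.frame(source = colnames(m)[idx[, 2]],
               target = rownames(m)[idx[, 1]],
               weight = m[idx], stringsAsFactors = FALSE)
  } else {
    data.frame(source = rownames(m)[idx[, 1]],
               target = colnames(m)[idx[, 2]],
               weight = m[idx], stringsAsFactors = FALSE)
  }
}

#' Export a communication graph to disk
#'
#' Writes the aggregated/thresholded/attenuated matrices as TSV and the
#' thresholded and attenuated graphs as edge-list CSV
#' (`source,target,weight`), GraphML and DOT.
#'
#' @param g A `communication_graph`.
#' @param out_dir Output directory (created if missing).
#' @param prefix File name prefix (default `"communication"`).
#' @return Invisibly, the paths written.
#' @export
export_graph <- function(g, out_dir, prefix = "communication") {
  stopifnot(inherits(g, "communication_graph"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("aggregated", "thresholded", "attenuated")) {
    f <- file.path(out_dir, paste0(prefix, "_", nm, ".tsv"))
    write_matrix_tsv(g[[nm]], f)
    paths <- c(paths, f)
  }
  edge_sets <- list(
    thresholded = graph_edge_list(g$thresholded, receiver_rows = TRUE),
    attenuated = graph_edge_list(g$attenuated, receiver_rows = FALSE))
  for (nm in names(edge_sets)) {
    edges <- edge_sets[[nm]]
    edges$weight <- signif(edges$weight, 6)
    f_csv <- file.path(out_dir, paste0(prefix, "_", nm, "_edges.csv"))
    utils::write.table(edges, f_csv, sep = ",", quote = FALSE,
                       row.names = FALSE)
    ig <- igraph::graph_from_data_frame(
      edges, directed = TRUE,
      vertices = data.frame(name = g$type_order))
    f_gml <- file.path(out_dir, paste0(prefix, "_", nm, ".graphml"))
    f_dot <- file.path(out_dir, paste0(prefix, "_", nm, ".dot"))
    igraph::write_graph(ig, f_gml, format = "graphml")
    igraph::write_graph(ig, f_dot, format = "dot")
    paths <- c(paths, f_csv, f_gml, f_dot)
  }
  invisible(paths)
}

#' Plot a communication graph
#'
#' Draws the thresholded directed graph with edge widths proportional to
#' weight.
#'
#' @param x A `communication_graph`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.communication_graph <- function(x, ...) {
  edges <- graph_edge_list(x$thresholded, receiver_rows = TRUE)
  ig <- igraph::graph_from_data_frame(
    edges, directed = TRUE, vertices = data.frame(name = x$type_order))
  w <- igraph::E(ig)$weight
  igraph::plot.igraph(ig, edge.width = if (length(w)) 1 + 3 * w / max(w)
                                       else 1, ...)
  invisible(x)
}
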