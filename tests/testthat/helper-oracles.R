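# Independent oracles and small fixture builders shared across tests.

# Naive neighbor scorer: double loop over cells, no matrix algebra.
brute_neighbor_scores <- function(labels, coords, dist0) {
  labels <- as.factor(labels)
  z <- nrow(coords)
  types <- levels(labels)
  out <- matrix(0, z, length(types), dimnames = list(NULL, types))
  for (c_ in seq_len(z)) {
    for (m in seq_len(z)) {
      if (m == c_) next
      d <- sqrt(sum((coords[c_, ] - coords[m, ])^2))
      b <- as.character(labels[m])
      out[c_, b] <- out[c_, b] + log10(d / dist0)
    }
  }
  out
}

# Naive exhaustive simple-path enumerator and attenuation, recursive.
brute_attenuated <- function(thresholded, mean_weight, max_len = NULL) {
  A <- nrow(thresholded)
  if (is.null(max_len)) max_len <- A - 1
  adj <- t(thresholded)   # adj[src, dst]
  total <- matrix(0, A, A)
  walk <- function(path) {
    cur <- path[length(path)]
    if (length(path) > 1) {
      w <- adj[cbind(path[-length(path)], path[-1])]
      s <- seq_along(w)
      total[path[1], cur] <<- total[path[1], cur] +
        sum(w - mean_weight * 10^(1 - s))
    }
    if (length(path) - 1 >= max_len) return()
    for (nxt in seq_len(A)) {
      if (adj[cur, nxt] > 0 && !(nxt %in% path)) walk(c(path, nxt))
    }
  }
  for (src in seq_len(A)) walk(src)
  dimnames(total) <- dimnames(thresholded)
  total
}

# Small aligned dataset: A/B types on a line, deterministic expression.
make_toy_dataset <- function(z = 24, n_genes = 8, seed = 42) {
  set.seed(seed)
  cells <- sprintf("c%d", seq_len(z))
  coords <- cbind(x = seq_len(z) + stats::runif(z, 0, 0.1),
                  y = stats::runif(z))
  rownames(coords) <- cells
  expr <- matrix(stats::rpois(z * n_genes, 5), z, n_genes,
                 dimnames = list(cells, sprintf("g%d", seq_len(n_genes))))
  labels <- stats::setNames(rep(c("A", "B"), length.out = z), cells)
  attr(labels, "types") <- c("A", "B")
  assemble_dataset(expr, coords, labels)
}
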