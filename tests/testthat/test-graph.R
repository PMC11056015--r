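make_filtered <- function(coefs, cell_type = "A") {
  obj <- list(cell_type = cell_type,
              stage1_tensor = array(coefs, c(nrow(coefs), ncol(coefs), 1)),
              coefficients = coefs,
              q_predictor = NULL, q_gene = NULL,
              q_pair = matrix(NA_real_, nrow(coefs), ncol(coefs)),
              delta = 0.05)
  class(obj) <- "filtered_coefficients"
  obj
}
make_clusters <- function(assignments, genes, k, cell_type = "A") {
  obj <- list(cell_type = cell_type, gene_ids = genes,
              assignments = stats::setNames(assignments, genes),
              k = k, silhouette_by_k = NULL, centers = NULL)
  class(obj) <- "gene_clusters"
  obj
}

test_that("cluster-level coefficients are per-cluster means", {
  coefs <- matrix(c(1, 3, 2, 6, 0, 0, 4, 2), nrow = 2,
                  dimnames = list(c("A", "B"), paste0("g", 1:4)))
  fc <- make_filtered(coefs)
  cl <- make_clusters(c(1, 1, 2, 2), paste0("g", 1:4), 2)
  cm <- cluster_coefficient_matrix(fc, cl)
  # cluster 1 = mean of g1, g2 rows; cluster 2 = mean of g3, g4
  expect_equal(unname(cm[1, ]), c((1 + 2) / 2, (3 + 6) / 2))
  expect_equal(unname(cm[2, ]), c((0 + 4) / 2, (0 + 2) / 2))
  # single-gene cluster is that gene verbatim
  cl3 <- make_clusters(c(1, 1, 1, 2), paste0("g", 1:4), 2)
  expect_equal(unname(cluster_coefficient_matrix(fc, cl3)[2, ]), c(4, 2))
})

test_that("pair aggregation is the L2 norm over the kept clusters", {
  m <- matrix(c(3, 4, 0, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  mats <- list(A = m, B = m)
  agg <- aggregate_pair_weights(mats, k_min = 2)
  expect_equal(unname(agg["A", "A"]), 5)   # sqrt(3^2 + 4^2)
  expect_equal(unname(agg["A", "B"]), 0)
  # k_min selection keeps the largest-norm clusters only
  m3 <- rbind(c(5, 0), c(0, 2), c(1, 0))
  colnames(m3) <- c("A", "B")
  agg2 <- aggregate_pair_weights(list(A = m3, B = m3), k_min = 2)
  expect_equal(unname(agg2["A", "A"]), 5)          # norm-1 cluster dropped
  expect_equal(unname(agg2["A", "B"]), 2)
  expect_error(aggregate_pair_weights(list(A = m, B = m3[1, , drop = FALSE]),
                                      k_min = 2), "k_min")
})

test_that("mean thresholding zeroes sub-mean entries and the diagonal", {
  agg <- matrix(c(9, 2, 4, 9), 2, 2, dimnames = rep(list(c("A", "B")), 2))
  th <- threshold_by_mean(agg)
  expect_equal(th$mean_weight, 3)          # mean of off-diagonal {2, 4}
  expect_equal(unname(th$thresholded),
               matrix(c(0, 0, 4, 0), 2, 2))
  # equal off-diagonals are all retained
  aggeq <- matrix(3, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  theq <- threshold_by_mean(aggeq)
  expect_equal(sum(theq$thresholded != 0), 6)
  zero <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  expect_equal(threshold_by_mean(zero)$mean_weight, 0)
})

test_that("path attenuation reproduces the worked 3-node example", {
  th <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  th["B", "A"] <- 5   # A -> B
  th["C", "A"] <- 4   # A -> C
  th["B", "C"] <- 6   # C -> B
  R <- attenuate_paths(th, mean_weight = 2)
  # direct: 5 - 2; via C: (4 - 2) + (6 - 0.2)
  expect_equal(R["A", "B"], 10.8)
  expect_equal(R["A", "C"], 2)
  expect_equal(R["C", "B"], 4)
  expect_equal(R["B", "A"], 0)             # no path
  # single edge exactly at the mean contributes 0
  th1 <- matrix(0, 2, 2, dimnames = rep(list(c("A", "B")), 2))
  th1["B", "A"] <- 2
  expect_equal(attenuate_paths(th1, 2)["A", "B"], 0)
})

test_that("attenuation equals the exhaustive enumerator on random graphs", {
  set.seed(61)
  for (rep in 1:20) {
    A <- sample(2:6, 1)
    agg <- matrix(runif(A * A, 0, 10), A, A,
                  dimnames = rep(list(paste0("T", 1:A)), 2))
    th <- threshold_by_mean(agg)
    R <- attenuate_paths(th$thresholded, th$mean_weight)
    R_oracle <- brute_attenuated(th$thresholded, th$mean_weight)
    expect_equal(R, R_oracle, tolerance = 1e-12)
    expect_true(all(R >= -1e-12))          # nonnegativity post-threshold
  }
})

test_that("attenuation terminates on denser graphs", {
  set.seed(62)
  agg <- matrix(runif(64, 0, 10), 8, 8,
                dimnames = rep(list(paste0("T", 1:8)), 2))
  th <- threshold_by_mean(agg)
  R <- attenuate_paths(th$thresholded, th$mean_weight)
  expect_true(all(is.finite(R)))
})

test_that("communication_graph composes the stages end to end", {
  set.seed(63)
  genes <- paste0("g", 1:12)
  types <- c("A", "B")
  fc <- list(); cl <- list()
  for (a in types) {
    coefs <- matrix(rnorm(2 * 12, sd = 2), 2, 12,
                    dimnames = list(types, genes))
    fc[[a]] <- make_filtered(coefs, a)
    cl[[a]] <- make_clusters(rep(1:3, each = 4), genes, 3, a)
  }
  g <- communication_graph(fc, cl)
  expect_s3_class(g, "communication_graph")
  expect_equal(g$k_min, 3)
  expect_equal(dim(g$attenuated), c(2, 2))
  expect_true(all(g$thresholded[g$thresholded != 0] >= g$mean_weight))
})
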