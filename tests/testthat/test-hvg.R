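test_that("vst ranking puts a high-variance gene first and is deterministic", {
  set.seed(11)
  n <- 50
  # Poisson-like genes over a realistic mean range; gene 1 is 100x
  # overdispersed relative to its mean
  lambda <- exp(runif(100, 0, 4))
  base <- sapply(lambda, function(l) rpois(n, l)) * 1.0
  colnames(base) <- sprintf("g%d", 1:100)
  base[, 1] <- pmax(rnorm(n, 20, sqrt(20) * 10), 0)
  ranked <- select_hvgs_vst(base, n_top = 10)
  expect_equal(ranked[1], "g1")
  expect_identical(ranked, select_hvgs_vst(base, n_top = 10))
})

test_that("a near-constant gene never outranks a gene with injected variance", {
  set.seed(12)
  n <- 40
  m <- matrix(rpois(n * 20, 5), n, 20, dimnames = list(NULL, sprintf("g%d", 1:20)))
  m[, "g3"] <- 5                      # constant
  m[1, "g3"] <- 5.001                 # barely varying so it stays in the fit
  m[, "g7"] <- rpois(n, 5) + rnorm(n, 0, 8)^2
  # narrow mean range makes the loess fit numerically fussy; that is the
  # point of the fixture, so its warnings are not of interest
  ranked <- suppressWarnings(select_hvgs_vst(m, n_top = 20))
  expect_lt(which(ranked == "g7"), which(ranked == "g3"))
})

test_that("n_top above the gene count warns and returns all genes", {
  set.seed(13)
  m <- matrix(rpois(300 * 30, 5) + runif(300 * 30), 300, 30,
              dimnames = list(NULL, sprintf("g%d", 1:30)))
  expect_warning(ranked <- select_hvgs_vst(m, n_top = 5000), "exceeds")
  expect_setequal(ranked, colnames(m))
  expect_error(select_hvgs_vst(m, n_top = 0), "positive")
})

test_that("per-type slices drop within-type all-zero genes and are z-scored", {
  set.seed(14)
  z <- 30
  cells <- sprintf("c%d", 1:z)
  expr <- matrix(rpois(z * 12, 4) + runif(z * 12), z, 12,
                 dimnames = list(cells, sprintf("g%d", 1:12)))
  labels <- stats::setNames(rep(c("A", "B"), each = z / 2), cells)
  attr(labels, "types") <- c("A", "B")
  expr[labels == "A", "g5"] <- 0      # expressed only in B
  coords <- cbind(x = seq_len(z), y = rep(0, z))
  rownames(coords) <- cells
  ds <- assemble_dataset(expr, coords, labels)
  slices <- split_by_cell_type(ds, n_top = 2000)
  expect_false("g5" %in% slices$A$hvg_ids)
  expect_true("g5" %in% slices$B$hvg_ids)
  for (s in slices) {
    expect_lt(max(abs(colMeans(s$expression))), 1e-9)
    sds <- apply(s$expression, 2, sd)
    expect_lt(max(abs(sds - 1)), 1e-9)
  }
})

test_that("z-scoring maps [1,2,3] to [-1,0,1] and zeroes constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_columns(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
})

test_that("HVG overlap ratio matches hand-computed cases", {
  expect_equal(hvg_overlap_ratio(list(c("a", "b"), c("a", "b"))), 1)
  expect_equal(hvg_overlap_ratio(list(c("a", "b"), c("c", "d"))), 0)
  expect_equal(hvg_overlap_ratio(list(c("a", "b"), c("b", "c"))), 0.5)
  # asymmetric sizes under the ordered-fraction definition:
  # |H1∩H2|/|H1| = 1/3, |H2∩H1|/|H2| = 1/1 -> mean 2/3
  expect_equal(hvg_overlap_ratio(list(c("a", "b", "c"), "a")), 2 / 3)
  expect_error(hvg_overlap_ratio(list(character(0), "a")), "empty")
  expect_error(hvg_overlap_ratio(list(c("a"))), "at least 2")
})

test_that("overlap ratio is invariant to relabeling and order for equal sizes", {
  sets <- list(c("a", "b", "c"), c("b", "c", "d"), c("x", "y", "c"))
  relabel <- lapply(sets, function(s) paste0("gene_", s))
  expect_equal(hvg_overlap_ratio(sets), hvg_overlap_ratio(relabel))
  expect_equal(hvg_overlap_ratio(sets), hvg_overlap_ratio(rev(sets)))
})
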