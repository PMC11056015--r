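test_that("keyword labeling follows the strong/weak criterion", {
  ann <- c(GPR1 = "G-protein coupled receptor activity",
           SIG1 = "signal transduction",
           MET1 = "carbohydrate metabolism",
           ADH1 = "involved in cell-cell adhesion",
           ADH2 = "involved in cell–cell adhesion",  # en-dash variant
           ADH3 = "involved in cell cell adhesion",
           EMPTY = "")
  tab <- label_genes_by_keywords(ann)
  lab <- stats::setNames(tab$label, tab$gene)
  expect_equal(unname(lab[c("GPR1", "SIG1", "MET1")]), c(1, 0, 0))
  expect_match(tab$strong_tags[tab$gene == "GPR1"], "receptor")
  expect_match(tab$weak_tags[tab$gene == "SIG1"], "signal transduction")
  # dash/space variants of cell-cell adhesion are equivalent
  expect_equal(unname(lab[c("ADH1", "ADH2", "ADH3")]), c(1, 1, 1))
  expect_equal(unname(lab["EMPTY"]), 0)
  # label == 1 iff a strong tag matched
  expect_equal(tab$label, as.integer(nzchar(tab$strong_tags)))
})

test_that("labeling is idempotent and keyword-order invariant", {
  ann <- data.frame(gene = c("a", "b"),
                    annotation_text = c("ligand binding pathway", "Pathway"))
  t1 <- label_genes_by_keywords(ann)
  t2 <- label_genes_by_keywords(ann, strong_list = rev(strong_keywords_default()))
  expect_equal(t1$label, t2$label)
  expect_identical(t1, label_genes_by_keywords(ann))
})

test_that("gene features have length A + 3 with sensible summaries", {
  ds <- make_toy_dataset()
  coefs <- matrix(0, 2, 4,
                  dimnames = list(c("A", "B"), paste0("g", 1:4)))
  coefs["A", "g2"] <- 1.5
  fc <- list(A = structure(list(cell_type = "A", coefficients = coefs),
                           class = "filtered_coefficients"))
  feat <- build_gene_features(ds, fc, paste0("g", 1:4))
  expect_equal(dim(feat), c(4, 2 + 3))
  expect_equal(feat["g2", "coef_A"], 1.5)
  expect_equal(unname(feat["g1", c("coef_A", "coef_B")]), c(0, 0))
  expect_equal(feat["g3", "mean_expr"], mean(ds$expression[, "g3"]))
  expect_error(build_gene_features(ds, fc, "missing_gene"), "absent")
  # a gene expressed nowhere: mean 0, dropout 1
  ds0 <- ds
  ds0$expression[, "g4"] <- 0
  f0 <- build_gene_features(ds0, fc, "g4")
  expect_equal(unname(f0[1, c("mean_expr", "dropout")]), c(0, 1))
})

test_that("the MLP separates well-separated classes and not permuted labels", {
  set.seed(71)
  n <- 400
  centers <- rep(c(0, 4), each = n / 2)   # 4 sd apart
  feat <- cbind(rnorm(n, centers, 1), rnorm(n, centers, 1))
  lab <- rep(c(0, 1), each = n / 2)
  rep_sep <- train_eval_mlp(feat, lab, folds = 10, seed = 0,
                            hidden_units = 16)
  expect_gte(rep_sep$mean[["accuracy"]], 0.95)
  expect_gte(rep_sep$mean[["auroc"]], 0.95)
  set.seed(0)
  lab_perm <- sample(lab)
  rep_null <- train_eval_mlp(feat, lab_perm, folds = 10, seed = 0,
                             hidden_units = 16)
  expect_lt(abs(rep_null$mean[["accuracy"]] - 0.5), 3 * sqrt(0.25 / n))
  expect_error(train_eval_mlp(feat[1:5, ], lab[1:5], folds = 10), "folds")
  expect_error(train_eval_mlp(feat, rep(1, n)), "both classes")
})

test_that("classifier metrics are reproducible for a fixed seed", {
  set.seed(72)
  feat <- matrix(rnorm(200), 50, 4)
  lab <- rep(c(0, 1), 25)
  r1 <- train_eval_mlp(feat, lab, folds = 5, seed = 9, hidden_units = 8)
  r2 <- train_eval_mlp(feat, lab, folds = 5, seed = 9, hidden_units = 8)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_true(all(unlist(r1$per_fold[, -1]) >= 0 &
                  unlist(r1$per_fold[, -1]) <= 1, na.rm = TRUE))
})
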