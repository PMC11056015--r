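#' Default keyword lists for communication-related gene labeling
#'
#' Strong keywords mark direct participation in cell communication
#' (receptors, ligands, adhesion, intercellular interaction); weak
#' keywords mark broader involvement (pathways, regulation, signal
#' transduction). A gene is labeled positive iff any strong keyword
#' matches its annotation text.
#'
#' @format Character vectors.
#' @name keyword_lists
NULL

#' @rdname keyword_lists
#' @export
strong_keywords_default <- function() {
  c("receptor", "ligand", "receptors", "ligands",
    "cell–cell adhesion", "intercellular interaction")
}

#' @rdname keyword_lists
#' @export
weak_keywords_default <- function() {
  c("surfaces of many cells and extracellular matrices",
    "Participates in cellular", "Pathway", "regulation",
    "signal transduction")
}

normalize_annotation <- function(s) {
  s <- tolower(s)
  s <- gsub("[–—]", "-", s)
  # hyphen, en-dash and space between "cell" tokens are equivalent
  gsub("cell[ -]+cell", "cell-cell", s)
}

#' Label genes as communication-related by keyword matching
#'
#' Case-insensitive fixed-substring matching of each keyword against each
#' gene's annotation text. Hyphen, en-dash and space between "cell"
#' tokens are treated as equivalent. A missing or empty annotation gives
#' label 0.
#'
#' @param annotations Named character vector (names = gene ids, values =
#'   annotation text), or a data.frame with columns `gene`,
#'   `annotation_text`.
#' @param strong_list,weak_list Keyword vectors; defaults
#'   [strong_keywords_default()] / [weak_keywords_default()].
#' @return data.frame of class `gene_label_table` with columns `gene`,
#'   `strong_tags`, `weak_tags` (comma-separated matches) and `label`
#'   (1 iff any strong tag).
#' @export
label_genes_by_keywords <- function(annotations,
                                    strong_list = strong_keywords_default(),
                                    weak_list = weak_keywords_default()) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "annotation_text") %in% names(annotations)))
    ann <- stats::setNames(as.character(annotations$annotation_text),
                           annotations$gene)
  } else {
    ann <- annotations
  }
  if (is.null(names(ann))) stop("annotations must be named by gene")
  ann[is.na(ann)] <- ""
  txt <- normalize_annotation(ann)
  strong_n <- normalize_annotation(strong_list)
  weak_n <- normalize_annotation(weak_list)
  match_tags <- function(text, keys, keys_n) {
    hits <- vapply(keys_n, function(k) grepl(k, text, fixed = TRUE),
                   logical(1))
    paste(keys[hits], collapse = ",")
  }
  strong_tags <- vapply(txt, match_tags, character(1),
                        keys = strong_list, keys_n = strong_n)
  weak_tags <- vapply(txt, match_tags, character(1),
                      keys = weak_list, keys_n = weak_n)
  out <- data.frame(gene = names(ann),
                    strong_tags = unname(strong_tags),
                    weak_tags = unname(weak_tags),
                    label = as.integer(nzchar(strong_tags)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_label_table", class(out))
  out
}

#' Build per-gene classifier features
#'
#' For each gene: its filtered coefficient toward each neighbor type,
#' averaged over the cell types in which the gene is an HVG (0 where it is
#' an HVG nowhere), plus three expression summaries over all cells: mean
#' expression, log1p variance and dropout fraction. Feature length A + 3.
#'
#' @param dataset A `spatial_dataset`.
#' @param filtered_list Named list of `filtered_coefficients` per cell
#'   type.
#' @param gene_set Genes to featurize (must exist in the dataset).
#' @return Numeric matrix, genes x (A + 3).
#' @export
build_gene_features <- function(dataset, filtered_list, gene_set) {
  validate_spatial_dataset(dataset)
  missing_genes <- setdiff(gene_set, dataset$gene_ids)
  if (length(missing_genes)) {
    stop("gene(s) absent from dataset: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  types <- levels(dataset$labels)
  A <- length(types)
  feat <- matrix(0, length(gene_set), A + 3,
                 dimnames = list(gene_set,
                                 c(paste0("coef_", types),
                                   "mean_expr", "log_var", "dropout")))
  for (g in gene_set) {
    acc <- matrix(0, 0, A)
    for (fc in filtered_list) {
      if (g %in% colnames(fc$coefficients)) {
        row <- fc$coefficients[types, g]
        acc <- rbind(acc, row)
      }
    }
    if (nrow(acc) > 0) feat[g, seq_len(A)] <- colMeans(acc)
    x <- dataset$expression[, g]
    feat[g, "mean_expr"] <- mean(x)
    feat[g, "log_var"] <- log1p(stats::var(x))
    feat[g, "dropout"] <- mean(x == 0)
  }
  feat
}

#' Train and evaluate an MLP gene classifier
#'
#' Stratified seeded k-fold cross-validation of a single-hidden-layer
#' multilayer perceptron (`nnet`, 64 hidden units by default, weight
#' decay, at most 500 epochs). Reports accuracy, precision, recall, F1
#' and AUROC per fold and their means.
#'
#' @param features Numeric matrix, genes x features.
#' @param labels 0/1 vector, one per gene; both classes must be present.
#' @param folds Number of folds (default 10); must not exceed the number
#'   of genes.
#' @param seed Seed controlling fold assignment and weight
#'   initialization (default 0).
#' @param hidden_units Hidden layer size (default 64).
#' @param maxit Maximum training epochs (default 500).
#' @param decay L2 weight decay (default 1e-3).
#' @return Object of class `classifier_report`: `folds`, `per_fold`
#'   (data.frame of metrics), `mean` (named vector), `seed`,
#'   `architecture`.
#' @export
train_eval_mlp <- function(features, labels, folds = 10, seed = 0,
                           hidden_units = 64, maxit = 500, decay = 1e-3) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels and features disagree on length")
  if (folds > n) stop("folds (", folds, ") exceeds number of genes (", n, ")")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  fold_of <- integer(n)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold_of[idx] <- rep(seq_len(folds), length.out = length(idx))
  }
  # standardize features on the training folds
  metrics <- data.frame(fold = seq_len(folds), accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, auroc = NA_real_)
  for (k in seq_len(folds)) {
    test <- which(fold_of == k)
    train <- setdiff(seq_len(n), test)
    mu <- colMeans(features[train, , drop = FALSE])
    sd_ <- apply(features[train, , drop = FALSE], 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
    xs <- sweep(sweep(features, 2, mu), 2, sd_, "/")
    set.seed(seed + k)
    fit <- nnet::nnet(x = xs[train, , drop = FALSE], y = labels[train],
                      size = hidden_units, decay = decay, maxit = maxit,
                      entropy = TRUE, trace = FALSE,
                      MaxNWts = 100000)
    prob <- as.numeric(stats::predict(fit, xs[test, , drop = FALSE]))
    pred <- as.integer(prob > 0.5)
    truth <- labels[test]
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    metrics$accuracy[k] <- mean(pred == truth)
    metrics$precision[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    metrics$recall[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    pr <- metrics$precision[k] + metrics$recall[k]
    metrics$f1[k] <- if (pr == 0) 0 else
      2 * metrics$precision[k] * metrics$recall[k] / pr
    metrics$auroc[k] <- if (length(unique(truth)) < 2) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
  }
  means <- colMeans(metrics[, -1], na.rm = TRUE)
  obj <- list(folds = folds, per_fold = metrics, mean = means, seed = seed,
              architecture = paste0("nnet MLP: ", ncol(features),
                                    " inputs -> ", hidden_units,
                                    " logistic hidden units -> 1 ",
                                    "(entropy loss, decay ", decay,
                                    ", maxit ", maxit, ")"))
  class(obj) <- "classifier_report"
  obj
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$folds, "folds; mean accuracy",
      format(x$mean["accuracy"], digits = 4), "AUROC",
      format(x$mean["auroc"], digits = 4), "\n")
  invisible(x)
}
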