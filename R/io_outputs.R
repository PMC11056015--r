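write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), signif(unclass(m), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(rownames(m))) df$id <- seq_len(nrow(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write analysis results to disk
#'
#' Dispatches on the result type: coefficient matrices and cluster
#' assignments become TSV tables with a header row, communication graphs
#' are exported via [export_graph()], classifier reports become JSON.
#' Floats are written with 6 significant digits.
#'
#' @param object A `filtered_coefficients`, `gene_clusters`,
#'   `communication_graph`, `classifier_report`, matrix or data.frame.
#' @param out_dir Output directory (created if missing).
#' @param name Base file name (defaults to a class-derived name).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(object, out_dir, name = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  UseMethod("write_outputs")
}

#' @export
write_outputs.filtered_coefficients <- function(object, out_dir,
                                                name = NULL) {
  if (is.null(name)) {
    name <- paste0("coefficients",
                   if (!is.na(object$cell_type))
                     paste0("_", object$cell_type))
  }
  f1 <- file.path(out_dir, paste0(name, "_matrix.tsv"))
  write_matrix_tsv(object$coefficients, f1)
  tab <- coefficients_table(object)
  tab$coefficient <- signif(tab$coefficient, 6)
  tab$q_pair <- signif(tab$q_pair, 6)
  f2 <- file.path(out_dir, paste0(name, "_table.tsv"))
  utils::write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' @export
write_outputs.gene_clusters <- function(object, out_dir, name = NULL) {
  if (is.null(name)) {
    name <- paste0("clusters",
                   if (!is.na(object$cell_type))
                     paste0("_", object$cell_type))
  }
  f <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(clusters_table(object), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(f)
}

#' @export
write_outputs.communication_graph <- function(object, out_dir,
                                              name = "communication") {
  export_graph(object, out_dir, prefix = name)
}

#' @export
write_outputs.classifier_report <- function(object, out_dir,
                                            name = "classifier_report") {
  f <- file.path(out_dir, paste0(name, ".json"))
  out <- list(folds = object$folds,
              seed = object$seed,
              architecture = object$architecture,
              per_fold = object$per_fold,
              mean = as.list(signif(object$mean, 6)))
  jsonlite::write_json(out, f, auto_unbox = TRUE, digits = 6,
                       dataframe = "columns", pretty = TRUE)
  invisible(f)
}

#' @export
write_outputs.matrix <- function(object, out_dir, name = "matrix") {
  f <- file.path(out_dir, paste0(name, ".tsv"))
  write_matrix_tsv(object, f)
  invisible(f)
}

#' @export
write_outputs.data.frame <- function(object, out_dir, name = "table") {
  f <- file.path(out_dir, paste0(name, ".tsv"))
  num <- vapply(object, is.numeric, logical(1))
  object[num] <- lapply(object[num], signif, 6)
  utils::write.table(object, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(f)
}
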