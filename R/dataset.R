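#' Read a cells x genes expression matrix
#'
#' Reads a Matrix Market triplet file with companion row/column name files,
#' or a dense CSV/TSV with gene names in the header and cell ids in the
#' first column. The returned matrix is always oriented cells x genes with
#' `rownames` = cell ids and `colnames` = gene ids.
#'
#' @param path Path to the `.mtx`, `.csv` or `.tsv` file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`. Defaults to the file
#'   extension.
#' @param orientation Orientation of the file on disk. Defaults to
#'   `"genes_x_cells"` for MTX (the common single-cell dialect) and
#'   `"cells_x_genes"` for delimited text.
#' @param row_names,col_names For MTX only: paths to plain-text files with
#'   one name per matrix row / column. Default to `genes.tsv` /
#'   `barcodes.tsv` (or swapped for `cells_x_genes`) next to the matrix.
#' @return A dense numeric matrix, cells x genes, with dimnames.
#' @export
load_expression <- function(path, format = NULL, orientation = NULL,
                            row_names = NULL, col_names = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot infer format from extension of ", path))
  }
  format <- match.arg(format, c("mtx", "csv", "tsv"))
  if (is.null(orientation)) {
    orientation <- if (format == "mtx") "genes_x_cells" else "cells_x_genes"
  }
  orientation <- match.arg(orientation, c("cells_x_genes", "genes_x_cells"))

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dirn <- dirname(path)
    if (is.null(row_names)) {
      row_names <- file.path(dirn, if (orientation == "genes_x_cells")
        "genes.tsv" else "barcodes.tsv")
    }
    if (is.null(col_names)) {
      col_names <- file.path(dirn, if (orientation == "genes_x_cells")
        "barcodes.tsv" else "genes.tsv")
    }
    for (f in c(row_names, col_names)) {
      if (!file.exists(f)) stop("companion name file not found: ", f)
    }
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    rn <- rn[nzchar(rn)]; cn <- cn[nzchar(cn)]
    # name files may carry extra tab-separated columns (id, symbol, ...)
    rn <- vapply(strsplit(rn, "\t", fixed = TRUE), `[[`, character(1), 1L)
    cn <- vapply(strsplit(cn, "\t", fixed = TRUE), `[[`, character(1), 1L)
    if (length(rn) != nrow(m)) {
      stop("MTX declares ", nrow(m), " rows but name file '", row_names,
           "' has ", length(rn), " names")
    }
    if (length(cn) != ncol(m)) {
      stop("MTX declares ", ncol(m), " columns but name file '", col_names,
           "' has ", length(cn), " names")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in expression table ", path)
  }
  if (orientation == "genes_x_cells") m <- t(m)
  if (anyNA(m)) stop("missing values in expression matrix ", path)
  if (any(m < 0)) stop("negative expression values in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate cell ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids in ", path)
  m
}

#' Read per-cell spatial coordinates
#'
#' @param path TSV/CSV with columns `cell_id`, `x`, `y`.
#' @return A Z x 2 numeric matrix with rownames = cell ids and columns
#'   `x`, `y`.
#' @export
load_coordinates <- function(path) {
  df <- read_delim_auto(path)
  need <- c("cell_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coordinates file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id in coordinates: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)])[1:3], collapse = ", "))
  }
  for (col in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", col, " coordinate at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (cell_id ", df$cell_id[bad[1]], ")")
    }
    df[[col]] <- v
  }
  m <- cbind(x = df$x, y = df$y)
  rownames(m) <- as.character(df$cell_id)
  m
}

#' Read per-cell type labels
#'
#' @param path TSV/CSV with columns `cell_id`, `cell_type`.
#' @return A named character vector of labels (names = cell ids) with an
#'   attribute `types`: unique types in first-appearance order.
#' @export
load_labels <- function(path) {
  df <- read_delim_auto(path)
  need <- c("cell_id", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("labels file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("labels file is empty: ", path)
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id in labels: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)])[1:3], collapse = ", "))
  }
  lab <- as.character(df$cell_type)
  if (any(is.na(lab) | !nzchar(lab))) {
    stop("empty cell_type at row(s) ",
         paste(utils::head(which(is.na(lab) | !nzchar(lab)), 5), collapse = ", "))
  }
  names(lab) <- as.character(df$cell_id)
  attr(lab, "types") <- unique(lab)
  lab
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("file is empty: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    quote = "\"", comment.char = "")
}

#' Assemble an aligned spatial expression dataset
#'
#' Joins expression, coordinates and labels by cell id. The canonical cell
#' order is the expression order; coordinates and labels are reordered to
#' match.
#'
#' @param expression Cells x genes numeric matrix with dimnames
#'   (see [load_expression()]).
#' @param coordinates Z x 2 matrix keyed by rowname (see
#'   [load_coordinates()]).
#' @param labels Named character vector (see [load_labels()]).
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expression`, `coordinates`, `labels` (factor, levels in
#'   first-appearance order over the canonical cell order), `cell_ids`,
#'   `gene_ids`.
#' @export
assemble_dataset <- function(expression, coordinates, labels) {
  cells <- rownames(expression)
  if (is.null(cells)) stop("expression matrix has no cell ids (rownames)")
  id_sets <- list(expression = cells, coordinates = rownames(coordinates),
                  labels = names(labels))
  all_ids <- unique(unlist(id_sets))
  for (nm in names(id_sets)) {
    diff <- c(setdiff(all_ids, id_sets[[nm]]), setdiff(id_sets[[nm]], all_ids))
    if (length(diff)) {
      stop("cell id mismatch for ", nm, ": ",
           paste(utils::head(diff, 10), collapse = ", "))
    }
  }
  coordinates <- coordinates[cells, , drop = FALSE]
  labels <- labels[cells]
  types <- unique(unname(labels))
  if (length(types) < 2) {
    stop("at least 2 cell types are required, found ", length(types))
  }
  obj <- list(expression = expression,
              coordinates = coordinates,
              labels = factor(unname(labels), levels = types),
              cell_ids = cells,
              gene_ids = colnames(expression))
  class(obj) <- "spatial_dataset"
  validate_spatial_dataset(obj)
  obj
}

validate_spatial_dataset <- function(x) {
  stopifnot(inherits(x, "spatial_dataset"))
  z <- nrow(x$expression)
  if (nrow(x$coordinates) != z || length(x$labels) != z) {
    stop("expression, coordinates and labels disagree on cell count")
  }
  if (anyDuplicated(x$cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(x$gene_ids)) stop("duplicate gene ids")
  if (any(!is.finite(x$coordinates))) stop("non-finite coordinates")
  invisible(x)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$expression), "cells x",
      ncol(x$expression), "genes,", nlevels(x$labels), "cell types\n")
  cat("  types:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expression)

#' Write expression, coordinates and labels to disk
#'
#' Writes the dataset in the same plain-text formats [load_expression()],
#' [load_coordinates()] and [load_labels()] read: an MTX triplet with
#' `genes.tsv`/`barcodes.tsv`, `coordinates.tsv` and `labels.tsv`.
#'
#' @param dataset A `spatial_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(out_dir, "expression.mtx")
  Matrix::writeMM(Matrix::Matrix(t(dataset$expression), sparse = TRUE), mtx)
  writeLines(dataset$gene_ids, file.path(out_dir, "genes.tsv"))
  writeLines(dataset$cell_ids, file.path(out_dir, "barcodes.tsv"))
  co <- data.frame(cell_id = dataset$cell_ids,
                   x = dataset$coordinates[, 1],
                   y = dataset$coordinates[, 2])
  utils::write.table(co, file.path(out_dir, "coordinates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  la <- data.frame(cell_id = dataset$cell_ids,
                   cell_type = as.character(dataset$labels))
  utils::write.table(la, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(out_dir, c("expression.mtx", "genes.tsv",
                                 "barcodes.tsv", "coordinates.tsv",
                                 "labels.tsv")))
}
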