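#' Assemble and validate a single-cell-resolution spatial dataset
#'
#' Bundles the three inputs of the analysis — a cells-by-genes expression
#' matrix, 2-D spatial coordinates and a cell-type label per cell — into a
#' validated container. All downstream steps consume this object.
#'
#' @param expression Numeric matrix, N cells x G genes. Raw or normalized
#'   counts (non-negative) when `scale = "counts"`; any real values when
#'   `scale = "processed"` (e.g. simulated data already on the log/z scale).
#'   Sparse matrices from the Matrix package are densified.
#' @param coordinates Numeric matrix or data frame, N x 2, same length unit on
#'   both axes. All values must be finite.
#' @param labels Character or factor vector of length N giving the cell type
#'   of each cell.
#' @param gene_ids,cell_ids Unique identifiers; default to the dimnames of
#'   `expression`.
#' @param scale Either `"counts"` (default; non-negativity enforced) or
#'   `"processed"`.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expression` (N x G matrix), `coordinates` (N x 2 matrix), `labels`
#'   (factor of length N), and `scale`. Rows of all components are aligned
#'   and named by `cell_ids`.
#' @export
spatial_dataset <- function(expression, coordinates, labels,
                            gene_ids = colnames(expression),
                            cell_ids = rownames(expression),
                            scale = c("counts", "processed")) {
  scale <- match.arg(scale)
  if (inherits(expression, "Matrix")) expression <- as.matrix(expression)
  expression <- as.matrix(expression)
  coordinates <- as.matrix(coordinates)
  storage.mode(expression) <- "double"
  storage.mode(coordinates) <- "double"

  n <- nrow(expression)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expression)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)

  if (nrow(coordinates) != n || length(labels) != n) {
    .stopf("row counts disagree: expression %d, coordinates %d, labels %d",
           n, nrow(coordinates), length(labels))
  }
  if (ncol(coordinates) != 2) .stopf("coordinates must have exactly 2 columns")
  if (length(cell_ids) != n || anyDuplicated(cell_ids)) {
    .stopf("cell_ids must be unique and of length %d", n)
  }
  if (length(gene_ids) != ncol(expression) || anyDuplicated(gene_ids)) {
    .stopf("gene_ids must be unique and of length %d", ncol(expression))
  }
  if (!all(is.finite(coordinates))) .stopf("coordinates contain non-finite values")
  if (anyNA(expression)) .stopf("expression contains missing values")
  if (scale == "counts" && any(expression < 0)) {
    .stopf("negative expression values are not allowed for scale = \"counts\"")
  }
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 1) .stopf("at least one cell type is required")

  dimnames(expression) <- list(cell_ids, gene_ids)
  dimnames(coordinates) <- list(cell_ids, c("x", "y"))
  names(labels) <- cell_ids

  structure(
    list(expression = expression, coordinates = coordinates,
         labels = labels, scale = scale),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes, %d cell types (%s scale)\n",
              nrow(x$expression), ncol(x$expression), nlevels(x$labels), x$scale))
  tab <- table(x$labels)
  cat("  cells per type:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a spatial dataset from standard on-disk formats
#'
#' Expression is read either from a dense delimited table (header row of gene
#' ids, first column `cell_id`) or from a MatrixMarket sparse matrix with
#' sidecar id files (one id per line). Coordinates and labels are delimited
#' tables with headers `cell_id,x,y` and `cell_id,cell_type`. The three files
#' are joined on `cell_id`; row order may differ between files.
#'
#' @param expr_path Path to the expression table (CSV/TSV) or `.mtx` file.
#' @param coord_path,label_path Paths to the coordinate and label tables.
#' @param format `"csv"` (dense delimited; tabs auto-detected) or `"mtx"`.
#' @param genes_path,cells_path Sidecar id files, required for `format = "mtx"`.
#' @param cells_as For MTX input, whether cells are the `"rows"` or `"cols"`
#'   of the sparse matrix.
#' @param scale Passed on to [spatial_dataset()].
#' @return A validated [spatial_dataset()].
#' @export
read_spatial_dataset <- function(expr_path, coord_path, label_path,
                                 format = c("csv", "mtx"),
                                 genes_path = NULL, cells_path = NULL,
                                 cells_as = c("rows", "cols"),
                                 scale = "counts") {
  format <- match.arg(format)
  cells_as <- match.arg(cells_as)
  for (p in c(expr_path, coord_path, label_path)) {
    if (!file.exists(p)) .stopf("input file not found: %s", p)
  }

  if (format == "csv") {
    tab <- utils::read.table(expr_path, header = TRUE, sep = .detect_sep(expr_path),
                             check.names = FALSE, stringsAsFactors = FALSE)
    cell_ids <- as.character(tab[[1]])
    expr <- as.matrix(tab[, -1, drop = FALSE])
    rownames(expr) <- cell_ids
  } else {
    if (is.null(genes_path) || is.null(cells_path)) {
      .stopf("format = \"mtx\" requires genes_path and cells_path sidecar files")
    }
    m <- as.matrix(Matrix::readMM(expr_path))
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    if (cells_as == "cols") m <- t(m)
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids)) {
      .stopf("MTX dimensions (%d x %d as cells x genes) do not match sidecars (%d cells, %d genes)",
             nrow(m), ncol(m), length(cell_ids), length(gene_ids))
    }
    expr <- m
    dimnames(expr) <- list(cell_ids, gene_ids)
  }

  coords <- utils::read.table(coord_path, header = TRUE, sep = .detect_sep(coord_path),
                              check.names = FALSE, stringsAsFactors = FALSE)
  labs <- utils::read.table(label_path, header = TRUE, sep = .detect_sep(label_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  .require_cols(coords, c("cell_id", "x", "y"), coord_path)
  .require_cols(labs, c("cell_id", "cell_type"), label_path)

  ids <- rownames(expr)
  .check_id_match(ids, as.character(coords$cell_id), "coordinate")
  .check_id_match(ids, as.character(labs$cell_id), "label")
  coords <- coords[match(ids, coords$cell_id), , drop = FALSE]
  labs <- labs[match(ids, labs$cell_id), , drop = FALSE]

  spatial_dataset(expr,
                  cbind(x = as.numeric(coords$x), y = as.numeric(coords$y)),
                  labs$cell_type, scale = scale)
}

#' Write a spatial dataset to disk
#'
#' Inverse of [read_spatial_dataset()]: writes the expression matrix (dense
#' CSV or MatrixMarket with id sidecars), `coordinates.csv` and `labels.csv`
#' into `dir`.
#'
#' @param ds A [spatial_dataset()].
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"mtx"` for the expression matrix.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_spatial_dataset <- function(ds, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(coords = file.path(dir, "coordinates.csv"),
             labels = file.path(dir, "labels.csv"))
  utils::write.csv(data.frame(cell_id = rownames(ds$coordinates),
                              x = ds$coordinates[, 1], y = ds$coordinates[, 2]),
                   paths[["coords"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cell_id = names(ds$labels),
                              cell_type = as.character(ds$labels)),
                   paths[["labels"]], row.names = FALSE, quote = FALSE)
  if (format == "csv") {
    paths[["expr"]] <- file.path(dir, "expression.csv")
    df <- data.frame(cell_id = rownames(ds$expression), ds$expression,
                     check.names = FALSE)
    utils::write.csv(df, paths[["expr"]], row.names = FALSE, quote = FALSE)
  } else {
    paths[["expr"]] <- file.path(dir, "expression.mtx")
    paths[["genes"]] <- file.path(dir, "genes.txt")
    paths[["cells"]] <- file.path(dir, "cells.txt")
    Matrix::writeMM(Matrix::Matrix(ds$expression, sparse = TRUE), paths[["expr"]])
    writeLines(colnames(ds$expression), paths[["genes"]])
    writeLines(rownames(ds$expression), paths[["cells"]])
  }
  invisible(paths)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) .stopf("%s is missing required column(s): %s",
                           path, paste(miss, collapse = ", "))
}

.check_id_match <- function(expr_ids, other_ids, what) {
  if (anyDuplicated(other_ids)) {
    .stopf("duplicated cell ids in %s table: %s", what,
           paste(utils::head(unique(other_ids[duplicated(other_ids)]), 5), collapse = ", "))
  }
  missing_in_other <- setdiff(expr_ids, other_ids)
  extra_in_other <- setdiff(other_ids, expr_ids)
  if (length(missing_in_other) || length(extra_in_other)) {
    .stopf(paste0("cell ids do not match between expression and %s table; ",
                  "missing from %s table: [%s]; not in expression: [%s]"),
           what, what,
           paste(utils::head(missing_in_other, 5), collapse = ", "),
           paste(utils::head(extra_in_other, 5), collapse = ", "))
  }
}
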