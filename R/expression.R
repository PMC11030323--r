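#' Construct a validated expression matrix
#'
#' The package's central single-cell container: a cells x genes numeric
#' matrix (sparse or dense) with aligned per-cell metadata. Values are either
#' raw counts or library-size-normalized log1p values; the `normalized` flag
#' records which, and downstream stages consume log space unless stated.
#'
#' @param values cells x genes numeric matrix (base matrix or `Matrix`
#'   sparse matrix).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param cell_meta data.frame with one row per cell; must contain columns
#'   `patient_id` and `category`; `histology` and `cluster_id` are optional.
#' @param normalized logical; `FALSE` for raw counts (values must then be
#'   non-negative), `TRUE` for log1p-normalized values.
#' @return an object of class `"ExpressionMatrix"`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, cell_meta,
                              normalized = FALSE) {
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  if (anyDuplicated(gene_ids)) .fail("expression_matrix: duplicate gene IDs")
  if (anyDuplicated(cell_ids)) .fail("expression_matrix: duplicate cell IDs")
  if (nrow(values) != length(cell_ids)) {
    .fail("expression_matrix: %d rows but %d cell IDs", nrow(values), length(cell_ids))
  }
  if (ncol(values) != length(gene_ids)) {
    .fail("expression_matrix: %d columns but %d gene IDs", ncol(values), length(gene_ids))
  }
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != length(cell_ids)) {
    .fail("expression_matrix: cell_meta rows must align 1:1 with cell_ids")
  }
  req <- c("patient_id", "category")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss)) .fail("expression_matrix: cell_meta missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!normalized && min(values) < 0) {
    .fail("expression_matrix: negative values in a matrix flagged as counts")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  rownames(cell_meta) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta, normalized = normalized),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%s)\n",
              length(x$cell_ids), length(x$gene_ids),
              if (x$normalized) "log1p-normalized" else "raw counts"))
  cat(sprintf("  patients: %d  categories: %s\n",
              length(unique(x$cell_meta$patient_id)),
              paste(unique(x$cell_meta$category), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# internal: dense numeric copy of the values (rows = cells)
.dense <- function(expr) as.matrix(expr$values)

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to the median total count of the dataset, then applies
#' log1p. A no-op (with a warning) on matrices already flagged normalized.
#'
#' @param expr an `ExpressionMatrix` of raw counts.
#' @return an `ExpressionMatrix` with `normalized = TRUE`.
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$normalized) {
    warning("normalize_expression: matrix already normalized; returning unchanged")
    return(expr)
  }
  totals <- Matrix::rowSums(expr$values)
  if (any(totals <= 0)) .fail("normalize_expression: %d cell(s) with zero total counts",
                              sum(totals <= 0))
  target <- stats::median(totals)
  vals <- expr$values * (target / totals)
  vals <- log1p(vals)
  expression_matrix(vals, expr$gene_ids, expr$cell_ids, expr$cell_meta,
                    normalized = TRUE)
}

# ---- readers / writers ------------------------------------------------------

.read_ids <- function(path) {
  ids <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  trimws(as.character(ids))
}

.read_meta <- function(path, cell_ids) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  meta <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if ("cell_id" %in% names(meta)) {
    if (!setequal(meta$cell_id, cell_ids)) {
      .fail("metadata file %s: cell_id column does not match the cell sidecar", path)
    }
    meta <- meta[match(cell_ids, meta$cell_id), , drop = FALSE]
  } else if (nrow(meta) != length(cell_ids)) {
    .fail("metadata file %s: %d rows for %d cells", path, nrow(meta), length(cell_ids))
  }
  meta
}

#' Read an expression matrix from Matrix Market + sidecar files
#'
#' Follows the 10x convention of storing the sparse matrix as genes x cells
#' but auto-detects orientation from the sidecar lengths and always returns
#' the internal cells x genes orientation. A dimension that matches neither
#' sidecar is an error naming the offending file.
#'
#' @param matrix_path `.mtx` Matrix Market file.
#' @param genes_path TSV whose first column is gene IDs.
#' @param cells_path TSV whose first column is cell barcodes/IDs.
#' @param meta_path CSV/TSV of per-cell metadata (columns `patient_id`,
#'   `category`, optional `cell_id` used for ordering).
#' @param normalized logical flag passed through to [expression_matrix()].
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(matrix_path, genes_path, cells_path, meta_path,
                            normalized = FALSE) {
  m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
  genes <- .read_ids(genes_path)
  cells <- .read_ids(cells_path)
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)                      # stored genes x cells (10x convention)
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    # already cells x genes
  } else if (nrow(m) != length(genes) && ncol(m) != length(cells) &&
             nrow(m) != length(cells)) {
    .fail("read_expression: neither sidecar matches matrix dims %dx%d (genes file: %s, cells file: %s)",
          nrow(m), ncol(m), genes_path, cells_path)
  } else if (ncol(m) != length(cells) && nrow(m) == length(genes)) {
    .fail("read_expression: cells sidecar %s has %d entries for matrix with %d columns",
          cells_path, length(cells), ncol(m))
  } else {
    .fail("read_expression: genes sidecar %s has %d entries for matrix dims %dx%d",
          genes_path, length(genes), nrow(m), ncol(m))
  }
  meta <- .read_meta(meta_path, cells)
  expression_matrix(m, genes, cells, meta, normalized = normalized)
}

#' Write an expression matrix as Matrix Market + sidecars
#'
#' Emits `matrix.mtx` (genes x cells), `genes.tsv`, `cells.tsv` and
#' `meta.csv` under `dir`. Round-trips losslessly through
#' [read_expression()].
#'
#' @param expr an `ExpressionMatrix`.
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv", "meta.csv"))
  Matrix::writeMM(methods::as(Matrix::t(Matrix::Matrix(expr$values, sparse = TRUE)),
                              "generalMatrix"), paths[1])
  writeLines(expr$gene_ids, paths[2])
  writeLines(expr$cell_ids, paths[3])
  meta <- cbind(cell_id = expr$cell_ids, expr$cell_meta)
  utils::write.csv(meta, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a dense CSV expression matrix
#'
#' Fallback format: rows are cells (first column = cell ID), header names
#' the genes.
#'
#' @inheritParams read_expression
#' @param csv_path dense CSV file.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_csv <- function(csv_path, meta_path, normalized = FALSE) {
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  cells <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  meta <- .read_meta(meta_path, cells)
  expression_matrix(vals, colnames(vals), cells, meta, normalized = normalized)
}

#' Write a dense CSV expression matrix
#'
#' @param expr an `ExpressionMatrix`.
#' @param csv_path output CSV path.
#' @return invisibly, `csv_path`.
#' @export
write_expression_csv <- function(expr, csv_path) {
  df <- data.frame(cell_id = expr$cell_ids, .dense(expr), check.names = FALSE)
  colnames(df) <- c("cell_id", expr$gene_ids)
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}
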