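#' Single-cell count bundle
#'
#' The universal container used throughout the pipeline: a sparse non-negative
#' integer count matrix (cells x genes) together with a cell-metadata tibble
#' and a gene-metadata tibble. Cell metadata must carry at least `cell_id`;
#' the QC, metric and annotation stages additionally expect `batch` and
#' `donor` columns. Gene metadata must carry `symbol`, and the CNV stages
#' require `chromosome` and `start` (1-based) as well.
#'
#' @param counts sparse or dense cells x genes matrix of non-negative counts.
#'   Row names are cell ids, column names gene symbols.
#' @param cells tibble of per-cell metadata with a `cell_id` column matching
#'   `rownames(counts)`.
#' @param genes tibble of per-gene metadata with a `symbol` column matching
#'   `colnames(counts)`.
#'
#' @return An object of class `cell_bundle`: a list with elements `counts`
#'   (a `dgCMatrix`), `cells`, and `genes`.
#' @export
cell_bundle <- function(counts, cells, genes) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  cells <- tibble::as_tibble(cells)
  genes <- tibble::as_tibble(genes)
  if (!"cell_id" %in% names(cells)) abort("cell metadata must have a `cell_id` column")
  if (!"symbol" %in% names(genes)) abort("gene metadata must have a `symbol` column")
  if (nrow(cells) != nrow(counts)) {
    abort(sprintf("counts has %d rows but cell metadata %d", nrow(counts), nrow(cells)))
  }
  if (nrow(genes) != ncol(counts)) {
    abort(sprintf("counts has %d columns but gene metadata %d", ncol(counts), nrow(genes)))
  }
  if (anyDuplicated(cells$cell_id)) abort("duplicate cell_id in cell metadata")
  rownames(counts) <- cells$cell_id
  colnames(counts) <- genes$symbol
  if (length(counts@x) > 0 && min(counts@x) < 0) abort("counts must be non-negative")
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "cell_bundle")
}

#' @export
print.cell_bundle <- function(x, ...) {
  cat(sprintf("<cell_bundle> %d cells x %d genes\n", n_cells(x), n_genes(x)))
  cat("  cell metadata: ", paste(names(x$cells), collapse = ", "), "\n")
  cat("  gene metadata: ", paste(names(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cell_bundle <- function(x) dim(x$counts)

#' Number of cells / genes in a bundle
#' @param bundle a [cell_bundle()]
#' @return integer count
#' @export
n_cells <- function(bundle) nrow(bundle$counts)

#' @rdname n_cells
#' @export
n_genes <- function(bundle) ncol(bundle$counts)

#' Subset a bundle by cell and/or gene index
#'
#' @param bundle a [cell_bundle()]
#' @param cells logical/integer/character index over cells (optional)
#' @param genes logical/integer/character index over genes (optional)
#' @return the subset `cell_bundle`
#' @export
bundle_subset <- function(bundle, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(n_cells(bundle)) else cells
  gi <- if (is.null(genes)) seq_len(n_genes(bundle)) else genes
  if (is.character(ci)) ci <- match(ci, bundle$cells$cell_id)
  if (is.character(gi)) gi <- match(gi, bundle$genes$symbol)
  cell_bundle(bundle$counts[ci, gi, drop = FALSE],
              bundle$cells[ci, , drop = FALSE],
              bundle$genes[gi, , drop = FALSE])
}

# internal: fetch a required metadata column or abort with a useful message
bundle_cell_col <- function(bundle, col) {
  if (!col %in% names(bundle$cells)) {
    abort(sprintf("cell metadata lacks required column `%s`", col))
  }
  bundle$cells[[col]]
}
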