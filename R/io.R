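#' Read and write cell bundles on disk
#'
#' The on-disk layout mirrors the 10x-style triplet plus cell metadata:
#' `matrix.mtx` (Matrix Market, genes as columns of the logical cells x genes
#' orientation are stored transposed as genes x cells, the 10x convention),
#' `barcodes.tsv` (cell ids), `features.tsv` (gene metadata; `symbol` always,
#' `chromosome` and `start` when available), and `cell_metadata.tsv`.
#' Writing then reading reproduces counts and metadata exactly.
#'
#' @param bundle a [cell_bundle()].
#' @param dir directory to write into / read from.
#' @return `write_bundle()` the directory path invisibly; `read_bundle()` a
#'   [cell_bundle()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(bundle$counts), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(cell_id = bundle$cells$cell_id),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(bundle$genes, file.path(dir, "features.tsv"))
  readr::write_tsv(bundle$cells, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  need <- c("matrix.mtx", "barcodes.tsv", "features.tsv", "cell_metadata.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("bundle directory %s lacks: %s", dir, paste(missing, collapse = ", ")))
  }
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "cell_id",
                              show_col_types = FALSE)
  genes <- readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"), show_col_types = FALSE)
  if (nrow(barcodes) != nrow(m) || nrow(genes) != ncol(m)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d cells x %d genes but barcodes=%d, features=%d",
      nrow(m), ncol(m), nrow(barcodes), nrow(genes)))
  }
  if (!identical(cells$cell_id, barcodes$cell_id)) {
    abort("cell_metadata.tsv cell ids do not match barcodes.tsv")
  }
  cell_bundle(m, cells, genes)
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then member gene symbols.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `read_gmt()` a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene-set name in %s: %s", path, nm[duplicated(nm)][1]))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a bulk survival cohort
#'
#' Layout: `expression.tsv` (samples x genes, first column `sample_id`) and
#' `clinical.tsv` (`sample_id`, `time`, `event`, `age`).
#'
#' @param cohort a `survival_cohort` (see [simulate_bulk_cohort()]).
#' @param dir directory.
#' @return `read_survival_cohort()` a `survival_cohort`.
#' @export
write_survival_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- tibble::as_tibble(cohort$expression, rownames = "sample_id")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' @rdname write_survival_cohort
#' @export
read_survival_cohort <- function(dir) {
  expr <- readr::read_tsv(file.path(dir, "expression.tsv"), show_col_types = FALSE)
  clin <- readr::read_tsv(file.path(dir, "clinical.tsv"), show_col_types = FALSE)
  m <- as.matrix(expr[, -1])
  rownames(m) <- expr$sample_id
  if (!identical(clin$sample_id, expr$sample_id)) {
    abort("clinical.tsv sample ids do not match expression.tsv")
  }
  structure(list(expression = m, samples = clin), class = "survival_cohort")
}

#' Run the full characterization pipeline on a bundle
#'
#' Thin end-to-end driver chaining the pipeline stages on a single bundle:
#' QC filtering, normalization, HVG selection, PCA, baseline per-batch
#' centering with batch-metric evaluation of the raw vs centered embeddings,
#' graph clustering, compartment annotation, donor-entropy filtering, CNV
#' smoothing and malignancy classification (non-epithelial cells as
#' reference), per-compartment diversity, and differential abundance on the
#' grade contrast. Intended for synthetic or desk-scale data; each stage is
#' also exported individually.
#'
#' @param bundle a [cell_bundle()] with `batch` and `donor` metadata.
#' @param seed seed forwarded to the stochastic stages.
#' @param n_hvg,d,k tuning for HVG count, PCA dimension, kNN size.
#' @param resolution Louvain resolution.
#' @return named list of stage outputs.
#' @export
run_atlas_pipeline <- function(bundle, seed = 1L, n_hvg = 300, d = 10, k = 15,
                               resolution = 0.5) {
  qc <- mad_outlier_filter(bundle, nmads = 3)
  norm <- lognormalize(qc$bundle)
  hvg <- select_hvg(norm, n = n_hvg)
  emb <- pca_embed(norm, hvg, d = d)
  batch <- bundle_cell_col(qc$bundle, "batch")
  centered <- baseline_batch_center(emb, batch)
  metrics <- rank_integrations(list(raw = emb, centered = centered), batch, seed = seed)
  clusters <- graph_cluster(centered, k = k, resolution = resolution, seed = seed)
  comp <- marker_compartments(qc$bundle, clusters, compartment_markers())
  entropy <- donor_entropy_filter(clusters, bundle_cell_col(qc$bundle, "donor"))
  ref <- which(comp$cell_compartment != "epithelial")
  cnv <- cnv_smooth(qc$bundle, reference_cells = ref, window = 21)
  mal <- malignancy_score(cnv)
  flags <- classify_malignant(
    scores = mal, dataset = batch,
    is_epithelial = comp$cell_compartment == "epithelial", seed = seed)
  comp_tab <- composition_table(qc$bundle$cells %>%
                                  mutate(cell_type = comp$cell_compartment))
  div <- ctds(comp_tab)
  list(bundle = qc$bundle, qc_report = qc$report, normalized = norm, hvg = hvg,
       embedding = centered, metrics = metrics, clusters = clusters,
       compartments = comp, donor_entropy = entropy, cnv = cnv,
       malignancy = flags, diversity = div)
}
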