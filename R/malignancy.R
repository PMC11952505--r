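#' Expression-derived copy-number smoothing
#'
#' A lite, non-HMM estimator of copy-number deviation from expression:
#' per gene, the relative log expression of each query cell against the mean
#' of a reference (non-malignant) cell set, smoothed by a moving average of
#' `window` genes along genomic order within each chromosome (never across
#' chromosome boundaries), then median-centered per cell. Genes whose mean
#' raw count across the reference is below `cutoff` are excluded. The output
#' is in the deviation convention: 0 = copy-neutral, positive = gain.
#'
#' @param bundle a [cell_bundle()] whose gene metadata has `chromosome` and
#'   `start`.
#' @param reference_cells index (integer/logical/character) of reference
#'   cells; non-empty.
#' @param window odd moving-average width >= 3 (default 101, reduced with a
#'   warning on chromosomes with fewer genes).
#' @param cutoff reference mean-count threshold below which genes are dropped.
#' @return a `cnv_matrix`: list with `scores` (cells x retained genes,
#'   genomic order), `genes` (ordered gene tibble), `convention`
#'   (`"deviation"`), `window`, and `reference_cells` ids.
#' @export
cnv_smooth <- function(bundle, reference_cells, window = 101, cutoff = 0.1) {
  if (!all(c("chromosome", "start") %in% names(bundle$genes))) {
    abort("gene metadata must have `chromosome` and `start` for CNV smoothing")
  }
  if (window < 3 || window %% 2 == 0) abort("window must be odd and >= 3")
  if (is.logical(reference_cells)) reference_cells <- which(reference_cells)
  if (is.character(reference_cells)) {
    reference_cells <- match(reference_cells, bundle$cells$cell_id)
  }
  if (length(reference_cells) == 0) abort("reference cell set is empty")

  genes <- bundle$genes %>% mutate(.idx = dplyr::row_number())
  chr_levels <- unique(genes$chromosome)  # natural file order = genomic order
  genes <- genes %>%
    arrange(match(.data$chromosome, chr_levels), .data$start)

  ref_mean_count <- Matrix::colSums(bundle$counts[reference_cells, , drop = FALSE]) /
    length(reference_cells)
  keep <- ref_mean_count[genes$.idx] >= cutoff
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0) abort("no gene passes the reference expression cutoff")

  norm <- as.matrix(lognormalize(bundle))[, genes$.idx, drop = FALSE]
  rel <- sweep(norm, 2, colMeans(norm[reference_cells, , drop = FALSE]), `-`)

  smoothed <- matrix(0, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  half <- (window - 1) / 2
  for (ch in unique(genes$chromosome)) {
    cols <- which(genes$chromosome == ch)
    w <- window
    if (length(cols) < window) {
      w <- max(3, length(cols) - (1 - length(cols) %% 2))  # largest odd <= length
      warn(sprintf("chromosome %s has %d genes < window %d; using %d",
                   ch, length(cols), window, w))
    }
    h <- (w - 1) / 2
    block <- rel[, cols, drop = FALSE]
    cs <- cbind(0, t(apply(block, 1, cumsum)))
    for (j in seq_along(cols)) {
      lo <- max(1, j - h); hi <- min(length(cols), j + h)
      smoothed[, cols[j]] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
    }
  }
  smoothed <- smoothed - apply(smoothed, 1, median)
  structure(list(scores = smoothed,
                 genes = genes %>% select(-".idx"),
                 convention = "deviation", window = window,
                 reference_cells = bundle$cells$cell_id[reference_cells]),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> %d cells x %d genes (%s convention, window %d)\n",
              nrow(x$scores), ncol(x$scores), x$convention, x$window))
  invisible(x)
}

#' Per-cell malignancy score
#'
#' The mean absolute copy-number deviation over retained genes,
#' `sum(|CNV score|) / n_genes`: cells with widespread inferred gains or
#' losses score high, copy-neutral cells near 0. Ratio-convention inputs
#' (neutral at 1) are converted to deviations first.
#'
#' @param cnv a `cnv_matrix` from [cnv_smooth()], or a plain cells x genes
#'   matrix of deviations.
#' @return tibble: `cell_id`, `malignancy_score` (>= 0).
#' @export
malignancy_score <- function(cnv) {
  if (inherits(cnv, "cnv_matrix")) {
    m <- cnv$scores
    if (cnv$convention == "ratio") m <- m - 1
  } else {
    m <- as.matrix(cnv)
  }
  if (ncol(m) == 0) abort("zero retained genes")
  tibble::tibble(cell_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                 malignancy_score = unname(rowMeans(abs(m))))
}

#' Negative-control interval classification of malignant cells
#'
#' Per dataset, a fixed number of non-epithelial cells are sampled as
#' negative controls and the equal-tailed `interval_mass` quantile interval
#' of their malignancy scores is taken (default the 90% interval, 5th-95th
#' percentiles); epithelial cells whose score falls outside their dataset's
#' interval are flagged malignant. Intervals and control ids are recorded
#' for audit.
#'
#' @param scores per-cell malignancy scores: the tibble from
#'   [malignancy_score()] or a numeric vector.
#' @param dataset per-cell dataset/batch labels.
#' @param is_epithelial per-cell logical; non-epithelial cells form the
#'   control pool.
#' @param interval_mass central probability mass of the control interval.
#' @param n_controls controls sampled per dataset (default 100); if fewer are
#'   available all are used with a warning.
#' @param seed RNG seed for control sampling.
#' @return list: `cells` (tibble: cell_id, dataset, score, epithelial,
#'   malignant) and `intervals` (tibble: dataset, low, high, n_controls,
#'   control_ids list-column).
#' @export
classify_malignant <- function(scores, dataset, is_epithelial,
                               interval_mass = 0.9, n_controls = 100,
                               seed = 1L) {
  if (is.data.frame(scores)) {
    ids <- scores$cell_id
    scores <- scores$malignancy_score
  } else {
    ids <- names(scores) %||% as.character(seq_along(scores))
  }
  stopifnot(length(dataset) == length(scores),
            length(is_epithelial) == length(scores),
            interval_mass > 0, interval_mass < 1)
  set.seed(as.integer(seed))
  tail_p <- (1 - interval_mass) / 2
  malignant <- rep(NA, length(scores))
  ints <- list()
  for (ds in unique(dataset)) {
    in_ds <- dataset == ds
    pool <- which(in_ds & !is_epithelial)
    if (length(pool) == 0) {
      warn(sprintf("dataset %s has no non-epithelial control cells; skipped", ds))
      next
    }
    if (length(pool) < n_controls) {
      warn(sprintf("dataset %s: only %d controls available (requested %d); using all",
                   ds, length(pool), n_controls))
      ctrl <- pool
    } else {
      ctrl <- sample(pool, n_controls)
    }
    int <- quantile(scores[ctrl], c(tail_p, 1 - tail_p), names = FALSE)
    epi <- which(in_ds & is_epithelial)
    malignant[epi] <- scores[epi] < int[1] | scores[epi] > int[2]
    ints[[length(ints) + 1]] <- tibble::tibble(
      dataset = ds, low = int[1], high = int[2], n_controls = length(ctrl),
      control_ids = list(ids[ctrl]))
  }
  list(cells = tibble::tibble(cell_id = ids, dataset = dataset,
                              score = scores, epithelial = is_epithelial,
                              malignant = malignant),
       intervals = bind_rows(ints))
}
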