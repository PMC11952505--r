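#' Adaptive per-batch MAD outlier filtering
#'
#' Removes low-quality cells using adaptive thresholds computed independently
#' within each batch, instead of manual cutoffs. Three per-cell metrics are
#' used: mitochondrial fraction (genes whose symbol starts with `MT-`), the
#' number of genes detected, and total counts. A cell is removed iff any
#' metric falls outside `median +/- nmads * MAD` for its batch, where counts
#' and detected genes are assessed on the log1p scale (two-sided) and the
#' mitochondrial fraction on the raw scale (upper side only). The MAD uses
#' the 1.4826 normal-consistency constant; a metric with MAD = 0 filters
#' nothing (degenerate spread must not remove everything).
#'
#' @param bundle a [cell_bundle()] with a `batch` cell-metadata column.
#' @param nmads number of MADs defining the inlier band (default 3).
#' @param skip if `TRUE` (for pre-filtered inputs) no cell is removed but the
#'   report is still produced.
#' @return list with `bundle` (filtered), `thresholds` (tibble: batch,
#'   metric, lower, upper), and `report` (tibble: batch, metric, n_removed;
#'   plus per-batch totals).
#' @export
mad_outlier_filter <- function(bundle, nmads = 3, skip = FALSE) {
  batch <- bundle_cell_col(bundle, "batch")
  counts <- bundle$counts
  mito_genes <- grepl("^MT-", bundle$genes$symbol)
  total <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito_frac <- if (any(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE]) / pmax(total, 1)
  } else rep(0, n_cells(bundle))

  metrics <- list(total_counts = log1p(total),
                  n_genes_detected = log1p(detected),
                  mito_fraction = mito_frac)
  one_sided <- c(total_counts = FALSE, n_genes_detected = FALSE, mito_fraction = TRUE)

  keep <- rep(TRUE, n_cells(bundle))
  thr_rows <- list(); rep_rows <- list()
  for (b in unique(batch)) {
    in_b <- which(batch == b)
    if (length(in_b) < 10) {
      warn(sprintf("batch %s has %d cells (< 10); passed through unfiltered",
                   b, length(in_b)))
      for (m in names(metrics)) {
        thr_rows[[length(thr_rows) + 1]] <- tibble::tibble(
          batch = b, metric = m, lower = -Inf, upper = Inf)
        rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
          batch = b, metric = m, n_removed = 0L)
      }
      next
    }
    for (m in names(metrics)) {
      x <- metrics[[m]][in_b]
      md <- median(x)
      madv <- mad(x, constant = 1.4826)
      if (madv == 0) {
        lo <- -Inf; hi <- Inf
      } else {
        hi <- md + nmads * madv
        lo <- if (one_sided[[m]]) -Inf else md - nmads * madv
      }
      out <- metrics[[m]][in_b] < lo | metrics[[m]][in_b] > hi
      if (!skip) keep[in_b[out]] <- FALSE
      thr_rows[[length(thr_rows) + 1]] <- tibble::tibble(
        batch = b, metric = m, lower = lo, upper = hi)
      rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
        batch = b, metric = m, n_removed = sum(out))
    }
  }
  list(bundle = bundle_subset(bundle, cells = keep),
       thresholds = bind_rows(thr_rows),
       report = bind_rows(rep_rows))
}

#' kNN-based doublet scoring
#'
#' A light artificial-doublet scorer: synthetic doublets are formed by
#' averaging the raw counts of random cell pairs; real and artificial cells
#' are jointly log-normalized and embedded by PCA, and each real cell's score
#' is the fraction of artificial doublets among its `k` nearest neighbors.
#'
#' @param bundle a [cell_bundle()] with at least 2 cells.
#' @param k neighborhood size; must be `< n_cells`.
#' @param n_artificial_ratio artificial doublets per real cell (default 1).
#' @param d PCA dimensionality for the joint embedding.
#' @param seed RNG seed for pair sampling.
#' @return tibble with `cell_id` and `doublet_score` in `[0, 1]`.
#' @export
doublet_score_lite <- function(bundle, k = 10, n_artificial_ratio = 1,
                               d = 10, seed = 1L) {
  n <- n_cells(bundle)
  if (n < 2) abort("need at least 2 cells")
  if (k >= n) abort(sprintf("k = %d must be smaller than n_cells = %d", k, n))
  set.seed(as.integer(seed))
  n_art <- max(1L, round(n_artificial_ratio * n))
  p1 <- sample.int(n, n_art, replace = TRUE)
  p2 <- sample.int(n, n_art, replace = TRUE)
  art <- (bundle$counts[p1, , drop = FALSE] + bundle$counts[p2, , drop = FALSE]) / 2
  joint <- rbind(bundle$counts, art)
  tot <- Matrix::rowSums(joint)
  tot[tot == 0] <- 1
  norm <- as(Matrix::Diagonal(x = 1e4 / tot) %*% joint, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  norm <- as.matrix(norm)
  d <- min(d, ncol(norm), nrow(norm) - 1)
  pc <- prcomp(norm, rank. = d, center = TRUE, scale. = FALSE)$x
  nn <- RANN::nn2(pc, pc[seq_len(n), , drop = FALSE], k = k + 1)$nn.idx
  score <- vapply(seq_len(n), function(i) {
    nb <- setdiff(nn[i, ], i)[seq_len(k)]
    mean(nb > n)
  }, numeric(1))
  tibble::tibble(cell_id = bundle$cells$cell_id, doublet_score = score)
}

#' Total-count log-normalization
#'
#' `log1p(count / cell_total * scale)` per cell; zeros map to zeros, so the
#' result stays sparse. Scale defaults to 10,000.
#'
#' @param bundle a [cell_bundle()]; cells with zero total counts are an error.
#' @param scale library-size target.
#' @return a sparse normalized matrix (cells x genes) with dimnames.
#' @export
lognormalize <- function(bundle, scale = 1e4) {
  tot <- Matrix::rowSums(bundle$counts)
  if (any(tot == 0)) {
    abort(sprintf("all-zero cell(s): %s",
                  paste(head(bundle$cells$cell_id[tot == 0], 5), collapse = ", ")))
  }
  m <- Matrix::Diagonal(x = scale / tot) %*% bundle$counts
  m <- as(m, "CsparseMatrix")
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(bundle$counts)
  m
}

#' Highly variable gene selection
#'
#' Ranks genes by standardized variance: the variance of log-normalized
#' expression divided by a loess mean-variance trend, so highly expressed
#' genes do not dominate. Ties break deterministically by gene symbol.
#'
#' @param normalized sparse/dense normalized matrix (cells x genes) with gene
#'   symbols as column names.
#' @param n number of genes to return (`0 < n <= n_genes`).
#' @return character vector of `n` gene symbols, most variable first.
#' @export
select_hvg <- function(normalized, n) {
  if (n <= 0) abort("n must be positive")
  if (n > ncol(normalized)) abort("n exceeds the number of genes")
  mu <- Matrix::colSums(normalized) / nrow(normalized)
  ex2 <- Matrix::colSums(normalized^2) / nrow(normalized)
  v <- pmax(ex2 - mu^2, 0) * nrow(normalized) / max(1, nrow(normalized) - 1)
  std_var <- v
  pos <- which(mu > 0 & v > 0)
  if (length(pos) >= 10) {
    fit <- try(stats::loess(log(v[pos]) ~ log(mu[pos]), span = 0.5, degree = 2),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      trend <- exp(stats::fitted(fit))
      std_var[pos] <- v[pos] / trend
    }
  }
  std_var[v == 0] <- -Inf  # constant genes rank strictly last
  sym <- colnames(normalized)
  ord <- order(-std_var, sym)
  sym[ord][seq_len(n)]
}

#' Pseudo-bulk aggregation
#'
#' Sums raw counts per group (typically per donor/tumor), yielding one
#' pseudo-bulk profile per group. Column sums are conserved exactly.
#'
#' @param bundle a [cell_bundle()].
#' @param group_key cell-metadata column to aggregate over.
#' @return dense groups x genes matrix of summed counts.
#' @export
pseudobulk_aggregate <- function(bundle, group_key = "donor") {
  g <- bundle_cell_col(bundle, group_key)
  if (any(is.na(g))) abort(sprintf("`%s` missing for some cells", group_key))
  groups <- unique(g)
  if (length(groups) == 0) abort("empty group set")
  ind <- Matrix::sparseMatrix(i = match(g, groups), j = seq_along(g), x = 1,
                              dims = c(length(groups), length(g)))
  out <- as.matrix(ind %*% bundle$counts)
  rownames(out) <- groups
  colnames(out) <- bundle$genes$symbol
  out
}
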