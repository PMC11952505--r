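#' PCA embedding of normalized expression
#'
#' Centered, truncated principal-component scores on the highly variable gene
#' submatrix. A fixed sign convention (the largest-magnitude loading of each
#' component is made positive) makes repeated runs identical.
#'
#' @param normalized normalized matrix (cells x genes) with gene symbols as
#'   column names (see [lognormalize()]).
#' @param hvg character vector of genes to use (see [select_hvg()]).
#' @param d number of components; `0 < d <= min(n_cells, n_hvg)`.
#' @return cells x d score matrix with cell ids as row names.
#' @export
pca_embed <- function(normalized, hvg, d = 20) {
  if (d <= 0) abort("d must be positive")
  hvg <- intersect(hvg, colnames(normalized))
  if (length(hvg) == 0) abort("no hvg genes present in the matrix")
  if (d > min(nrow(normalized), length(hvg))) {
    abort("d exceeds min(n_cells, n_hvg)")
  }
  x <- as.matrix(normalized[, hvg, drop = FALSE])
  pc <- prcomp(x, rank. = d, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(d), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- rownames(normalized)
  scores
}

#' Baseline batch correction: per-batch centering
#'
#' Subtracts the batch mean in embedding space. This is the package's
#' built-in baseline corrector; any externally produced embedding can be
#' scored by the batch metrics in the same way. A single-batch input is
#' simply mean-centered.
#'
#' @param embedding cells x d matrix.
#' @param batch per-cell batch labels.
#' @return centered embedding of the same shape.
#' @export
baseline_batch_center <- function(embedding, batch) {
  stopifnot(nrow(embedding) == length(batch))
  for (b in unique(batch)) {
    i <- batch == b
    embedding[i, ] <- sweep(embedding[i, , drop = FALSE], 2,
                            colMeans(embedding[i, , drop = FALSE]), `-`)
  }
  embedding
}

#' Batch-mixing silhouette score
#'
#' `1 - |silhouette|` of the batch labels, averaged over cells: 1 means
#' batches are perfectly mixed, 0 means they form tight separate clusters.
#'
#' @param embedding cells x d matrix.
#' @param batch per-cell batch labels (>= 2 batches).
#' @return scalar in `[0, 1]`.
#' @export
batch_asw <- function(embedding, batch) {
  batch <- as.character(batch)
  tab <- table(batch)
  if (length(tab) < 2) abort("batch_asw requires >= 2 batches")
  if (any(tab == 1)) {
    drop <- names(tab)[tab == 1]
    warn(sprintf("excluding singleton batch(es): %s", paste(drop, collapse = ", ")))
    keep <- !batch %in% drop
    embedding <- embedding[keep, , drop = FALSE]
    batch <- batch[keep]
    if (length(unique(batch)) < 2) abort("fewer than 2 batches after exclusion")
  }
  sil <- cluster::silhouette(as.integer(factor(batch)), dist(embedding))
  mean(1 - abs(sil[, "sil_width"]))
}

#' k-nearest-neighbor batch effect test (kBET)
#'
#' For a sample of cells, a chi-square goodness-of-fit test compares the
#' batch composition of each cell's k nearest neighbors with the global
#' batch proportions; the acceptance rate is the fraction of tested cells
#' with p >= alpha. Well-mixed data accepts about `1 - alpha` of the tests;
#' batch-separated data accepts none.
#'
#' @param embedding cells x d matrix.
#' @param batch per-cell batch labels (>= 2 batches).
#' @param k neighborhood size; default the smaller of 50 and 10% of cells.
#'   Automatically increased (with a warning) if any expected batch count in
#'   a neighborhood falls below 1.
#' @param alpha test level.
#' @param n_test number of cells to test (sampled without replacement when
#'   fewer than `n_test` cells exist, all are used).
#' @param seed RNG seed for the cell sample.
#' @return scalar acceptance rate in `[0, 1]`.
#' @export
kbet <- function(embedding, batch, k = NULL, alpha = 0.05, n_test = 500,
                 seed = 1L) {
  n <- nrow(embedding)
  batch <- as.character(batch)
  props <- table(batch) / n
  if (length(props) < 2 || any(props >= 1)) {
    abort("kbet requires >= 2 batches with non-degenerate proportions")
  }
  if (is.null(k)) k <- min(50, floor(0.1 * n))
  if (k >= n) abort("k must be smaller than n_cells")
  if (min(k * props) < 1) {
    k_new <- min(n - 1, ceiling(1 / min(props)))
    warn(sprintf("expected count < 1 at k = %d; increasing k to %d", k, k_new))
    k <- k_new
  }
  set.seed(as.integer(seed))
  test_cells <- sample.int(n, min(n_test, n))
  nn <- RANN::nn2(embedding, embedding[test_cells, , drop = FALSE], k = k + 1)$nn.idx
  lv <- names(props)
  expd <- k * as.numeric(props)
  pvals <- vapply(seq_along(test_cells), function(i) {
    nb <- setdiff(nn[i, ], test_cells[i])[seq_len(k)]
    obs <- tabulate(match(batch[nb], lv), nbins = length(lv))
    stat <- sum((obs - expd)^2 / expd)
    pchisq(stat, df = length(lv) - 1, lower.tail = FALSE)
  }, numeric(1))
  mean(pvals >= alpha)
}

#' Integration local inverse Simpson's index (iLISI)
#'
#' Per cell, neighbor weights are Gaussian with the bandwidth tuned by binary
#' search so the neighborhood entropy matches the target perplexity; the
#' index is `1 / sum_b p_b^2` over the weighted batch probabilities. It runs
#' from 1 (all neighbors one batch) to the number of batches (perfect
#' mixing).
#'
#' @param embedding cells x d matrix.
#' @param batch per-cell batch labels (>= 2 batches).
#' @param perplexity effective neighborhood size; must be `< n_cells`.
#' @return list with `values` (per-cell iLISI) and `mean`.
#' @export
ilisi <- function(embedding, batch, perplexity = 30) {
  n <- nrow(embedding)
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) abort("ilisi requires >= 2 batches")
  if (perplexity >= n) abort("perplexity must be smaller than n_cells")
  k <- min(n - 1, max(15, ceiling(3 * perplexity)))
  nn <- RANN::nn2(embedding, embedding, k = k + 1)
  lv <- unique(batch)
  target <- log(perplexity)
  values <- vapply(seq_len(n), function(i) {
    self <- which(nn$nn.idx[i, ] == i)[1]
    idx <- if (is.na(self)) nn$nn.idx[i, -(k + 1)] else nn$nn.idx[i, -self]
    d2 <- if (is.na(self)) nn$nn.dists[i, -(k + 1)]^2 else nn$nn.dists[i, -self]^2
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(w * d2) / sw
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    w <- exp(-beta * d2)
    if (sum(w) == 0) w <- rep(1, length(d2))
    p <- vapply(lv, function(b) sum(w[batch[idx] == b]), numeric(1)) / sum(w)
    1 / sum(p^2)
  }, numeric(1))
  list(values = values, mean = mean(values))
}

#' Score and rank candidate embeddings by batch mixing
#'
#' Computes the three batch-correction metrics ([batch_asw()], [kbet()],
#' [ilisi()]) for each candidate embedding and aggregates them into a rank
#' (mean of per-metric ranks; all metrics are oriented higher = better
#' mixed). Used to choose the best integration, mirroring metric-based
#' selection among integration tools.
#'
#' @param embeddings named list of cells x d matrices over the same cells.
#' @param batch per-cell batch labels.
#' @param perplexity,k,alpha,n_test,seed forwarded to the metrics.
#' @return tibble: `embedding`, `batch_asw_score`, `kbet_acceptance`,
#'   `ilisi_mean`, `aggregate_rank` (1 = best).
#' @export
rank_integrations <- function(embeddings, batch, perplexity = 30, k = NULL,
                              alpha = 0.05, n_test = 500, seed = 1L) {
  stopifnot(is.list(embeddings), length(names(embeddings)) == length(embeddings))
  res <- purrr::imap(embeddings, function(e, nm) {
    tibble::tibble(embedding = nm,
                   batch_asw_score = batch_asw(e, batch),
                   kbet_acceptance = kbet(e, batch, k = k, alpha = alpha,
                                          n_test = n_test, seed = seed),
                   ilisi_mean = ilisi(e, batch, perplexity = perplexity)$mean)
  }) %>% bind_rows()
  ranks <- cbind(rank(-res$batch_asw_score), rank(-res$kbet_acceptance),
                 rank(-res$ilisi_mean))
  res$aggregate_rank <- rowMeans(ranks)
  res %>% arrange(.data$aggregate_rank)
}
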