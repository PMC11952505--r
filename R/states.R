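#' Rank-based per-cell gene-set activity (AUCell-style)
#'
#' Per cell, genes are ranked by decreasing expression (ties broken randomly
#' under a fixed seed) and the score is the area under the recovery curve of
#' set members within the top `top_fraction` of the ranking, normalized by
#' the maximal attainable area so scores lie in `[0, 1]`: 1 means all set
#' genes sit at the very top of the cell's ranking, 0 means none are in the
#' top fraction. Invariant to monotone transforms of expression.
#'
#' @param x a [cell_bundle()] (raw counts are ranked) or a cells x genes
#'   matrix with gene symbols as column names.
#' @param sets named list of gene-symbol vectors.
#' @param top_fraction fraction of the ranking considered (default 0.05).
#' @param seed RNG seed for tie-breaking.
#' @return tibble: `cell_id` plus one score column per set. Sets with no
#'   measured member give an NA column and a warning.
#' @export
aucell_score <- function(x, sets, top_fraction = 0.05, seed = 1L) {
  m <- if (inherits(x, "cell_bundle")) as.matrix(x$counts) else as.matrix(x)
  stopifnot(length(names(sets)) == length(sets))
  measured <- lapply(sets, intersect, colnames(m))
  if (any(lengths(measured) == 0)) {
    warn(sprintf("gene set(s) with no measured member: %s",
                 paste(names(sets)[lengths(measured) == 0], collapse = ", ")))
  }
  n_gene <- ncol(m)
  max_rank <- max(1L, ceiling(top_fraction * n_gene))
  set.seed(as.integer(seed))
  set_idx <- lapply(measured, match, colnames(m))
  scores <- matrix(NA_real_, nrow(m), length(sets),
                   dimnames = list(rownames(m), names(sets)))
  for (i in seq_len(nrow(m))) {
    r <- rank(-m[i, ], ties.method = "random")
    for (s in seq_along(sets)) {
      idx <- set_idx[[s]]
      if (length(idx) == 0) next
      pos <- r[idx]
      pos <- pos[pos <= max_rank]
      auc <- sum(max_rank - pos + 1)
      kmax <- min(length(idx), max_rank)
      max_auc <- sum(max_rank - seq_len(kmax) + 1)
      scores[i, s] <- auc / max_auc
    }
  }
  bind_cols(tibble::tibble(cell_id = rownames(m) %||% as.character(seq_len(nrow(m)))),
            tibble::as_tibble(scores))
}

#' Single-sample gene-set projection (ssGSEA-style)
#'
#' Per sample, a weighted Kolmogorov-Smirnov running-sum statistic over the
#' expression ranking: walking down the genes ordered by decreasing
#' expression, set members step the in-set CDF up by their rank weight
#' `|r - (n+1)/2|^tau` (centered absolute ranks, so the statistic is exactly
#' antisymmetric under reversal of the expression ordering) and non-members
#' step the out-set CDF up by `1/(n - |set|)`; the score is the mean
#' difference of the two CDFs along the walk. Monotone in a joint up-shift
#' of the set genes and invariant to monotone transforms of expression.
#'
#' @param expression samples x genes matrix with gene symbols as column
#'   names (bulk cohort orientation).
#' @param sets named list of gene-symbol vectors.
#' @param tau rank-weight exponent (default 0.25).
#' @return tibble: `sample_id` plus one score column per set; constant
#'   sample profiles give NA with a warning.
#' @export
ssgsea_project <- function(expression, sets, tau = 0.25) {
  m <- as.matrix(expression)
  stopifnot(length(names(sets)) == length(sets))
  measured <- lapply(sets, intersect, colnames(m))
  if (any(lengths(measured) == 0)) {
    abort(sprintf("gene set(s) with no measured member: %s",
                  paste(names(sets)[lengths(measured) == 0], collapse = ", ")))
  }
  n <- ncol(m)
  scores <- matrix(NA_real_, nrow(m), length(sets),
                   dimnames = list(rownames(m), names(sets)))
  flagged <- character()
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (sd(x) == 0) {
      flagged <- c(flagged, rownames(m)[i] %||% as.character(i))
      next
    }
    r <- rank(x)  # ascending ranks, average ties
    w <- abs(r - (n + 1) / 2)^tau
    ord <- order(-x, colnames(m))  # decreasing expression, symbol tie-break
    for (s in seq_along(sets)) {
      in_set <- colnames(m) %in% measured[[s]]
      is_in <- in_set[ord]
      wo <- w[ord]
      step_in <- ifelse(is_in, wo, 0)
      sum_in <- sum(step_in)
      p_in <- cumsum(step_in) / ifelse(sum_in > 0, sum_in, 1)
      p_out <- cumsum(!is_in) / max(1, n - sum(in_set))
      scores[i, s] <- mean(p_in - p_out)
    }
  }
  if (length(flagged) > 0) {
    warn(sprintf("constant profile(s), scores undefined: %s",
                 paste(head(flagged, 5), collapse = ", ")))
  }
  bind_cols(tibble::tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m)))),
            tibble::as_tibble(scores))
}
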