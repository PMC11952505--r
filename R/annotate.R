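#' Shared-nearest-neighbor graph clustering
#'
#' Builds a kNN graph in embedding space, re-weights edges by the Jaccard
#' overlap of neighborhoods (shared nearest neighbors), and partitions cells
#' with Louvain modularity optimization at the given resolution.
#' Deterministic given the seed.
#'
#' @param embedding cells x d matrix.
#' @param k neighborhood size (`0 < k < n_cells`).
#' @param resolution Louvain resolution; higher yields more clusters.
#' @param seed RNG seed.
#' @param prune discard SNN edges with Jaccard weight below this (default 1/15).
#' @return integer vector of cluster labels (1-based).
#' @export
graph_cluster <- function(embedding, k = 20, resolution = 0.1, seed = 1L,
                          prune = 1 / 15) {
  n <- nrow(embedding)
  if (k <= 0) abort("k must be positive")
  if (k >= n) abort("k must be smaller than n_cells")
  nn <- RANN::nn2(embedding, embedding, k = k + 1)$nn.idx
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- adj %*% Matrix::t(adj)  # shared neighbor counts (self included)
  shared <- as(shared, "TsparseMatrix")
  jac <- shared@x / (2 * (k + 1) - shared@x)
  keep <- jac >= prune & shared@i < shared@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = shared@i[keep] + 1, to = shared@j[keep] + 1,
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Cluster-level compartment assignment from canonical markers
#'
#' Scores each cell for each marker panel as the mean z-scored normalized
#' expression of the panel genes, averages scores within clusters, and
#' assigns each cluster the argmax compartment. Cells inherit their
#' cluster's compartment. Ties break deterministically in panel order and
#' are flagged.
#'
#' @param bundle a [cell_bundle()].
#' @param clusters per-cell cluster labels.
#' @param panels named list of marker gene vectors (default
#'   [compartment_markers()]).
#' @return list: `clusters` (tibble: cluster, per-panel score, compartment,
#'   tie flag) and `cell_compartment` (per-cell character vector).
#' @export
marker_compartments <- function(bundle, clusters, panels = compartment_markers()) {
  norm <- lognormalize(bundle)
  present <- lapply(panels, intersect, colnames(norm))
  if (all(lengths(present) == 0)) abort("no panel gene present in the data")
  if (any(lengths(present) == 0)) {
    warn(sprintf("panels with no measured genes: %s",
                 paste(names(panels)[lengths(present) == 0], collapse = ", ")))
    present <- present[lengths(present) > 0]
  }
  cell_scores <- vapply(present, function(gs) {
    x <- as.matrix(norm[, gs, drop = FALSE])
    z <- scale(x)
    z[is.nan(z) | is.na(z)] <- 0  # constant genes carry no signal
    rowMeans(z)
  }, numeric(nrow(norm)))
  agg <- stats::aggregate(cell_scores, by = list(cluster = clusters), FUN = mean)
  score_mat <- as.matrix(agg[, -1, drop = FALSE])
  best <- apply(score_mat, 1, which.max)  # which.max: first max = panel-order tie-break
  tie <- apply(score_mat, 1, function(r) sum(r == max(r)) > 1)
  cl_tbl <- tibble::as_tibble(agg) %>%
    mutate(compartment = names(present)[best], tie = tie)
  list(clusters = cl_tbl,
       cell_compartment = cl_tbl$compartment[match(clusters, cl_tbl$cluster)])
}

#' Consensus relabeling across annotation sources
#'
#' Majority vote per cell over the available (non-missing) annotation
#' sources, with the cluster-level compartment as tie-breaker (then
#' lexicographic order). Cells lacking a label in the designated original
#' source are "newly annotated"; cells whose final label differs from their
#' original label are "relabeled". Idempotent: feeding the final labels back
#' as the sole source changes nothing.
#'
#' @param votes tibble with `cell_id`, one column per source (NA = no label),
#'   and optionally `cluster_compartment` used as tie-breaker.
#' @param sources character vector of the source column names.
#' @param original name of the source treated as the pre-existing annotation.
#' @return list: `labels` (tibble: cell_id, final, relabeled, newly_annotated),
#'   `n_relabeled`, `n_newly_annotated`.
#' @export
consensus_relabel <- function(votes, sources, original = sources[1]) {
  stopifnot(all(sources %in% names(votes)), original %in% sources)
  tie_break <- if ("cluster_compartment" %in% names(votes)) {
    votes$cluster_compartment
  } else rep(NA_character_, nrow(votes))
  final <- vapply(seq_len(nrow(votes)), function(i) {
    lab <- unlist(votes[i, sources], use.names = FALSE)
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) return(NA_character_)
    tab <- table(lab)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1 && !is.na(tie_break[i]) && tie_break[i] %in% winners) {
      return(tie_break[i])
    }
    sort(winners)[1]
  }, character(1))
  orig <- votes[[original]]
  newly <- is.na(orig) & !is.na(final)
  relab <- !is.na(orig) & !is.na(final) & final != orig
  list(labels = tibble::tibble(cell_id = votes$cell_id, final = final,
                               relabeled = relab, newly_annotated = newly),
       n_relabeled = sum(relab), n_newly_annotated = sum(newly))
}

#' Donor-entropy filtering of clusters
#'
#' Flags donor-specific clusters — those mostly consisting of cells from
#' individual donors, indicative of patient-specific clonal expansion rather
#' than shared programs. Per cluster the normalized Shannon entropy of donor
#' proportions is `H / ln(D)` with `D` the number of observed donors (0 by
#' convention when `D < 2`); clusters below the threshold are flagged for
#' exclusion from the taxonomy input.
#'
#' @param clusters per-cell cluster labels.
#' @param donors per-cell donor labels.
#' @param threshold normalized-entropy cutoff (default 0.3).
#' @return tibble: `cluster`, `n_cells`, `n_donors`, `entropy`,
#'   `donor_specific`.
#' @export
donor_entropy_filter <- function(clusters, donors, threshold = 0.3) {
  stopifnot(length(clusters) == length(donors))
  tibble::tibble(cluster = clusters, donor = donors) %>%
    group_by(.data$cluster) %>%
    summarise(n_cells = dplyr::n(),
              n_donors = dplyr::n_distinct(.data$donor),
              entropy = {
                p <- table(.data$donor) / dplyr::n()
                d <- sum(p > 0)
                if (d < 2) 0 else -sum(p[p > 0] * log(p[p > 0])) / log(d)
              },
              .groups = "drop") %>%
    mutate(donor_specific = .data$entropy < threshold) %>%
    arrange(.data$cluster)
}

# internal: tie-corrected rank-sum z for group membership, vectorized over a
# dense matrix (cells x genes). Positive z = higher expression in the group.
ranksum_z <- function(x, in_group) {
  n <- nrow(x); n1 <- sum(in_group); n2 <- n - n1
  if (n1 == 0 || n2 == 0) return(rep(NA_real_, ncol(x)))
  ranks <- apply(x, 2, rank)
  w <- colSums(ranks[in_group, , drop = FALSE])
  ew <- n1 * (n + 1) / 2
  tie_term <- apply(x, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  vw <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (w - ew) / sqrt(pmax(vw, .Machine$double.eps))
  z[vw == 0] <- 0
  z
}

#' Batch-stratified cluster markers
#'
#' One-vs-rest differential expression per cluster with batch as a stratum:
#' a tie-corrected rank-sum statistic is computed within each batch and the
#' per-batch standardized statistics are combined by inverse-variance
#' weighting, so genes shifted only between batches are not called. The
#' effect size is the log2 fold-change of mean normalized expression;
#' p-values are BH-adjusted within each cluster.
#'
#' @param bundle a [cell_bundle()] with a `batch` column.
#' @param clusters per-cell cluster labels (>= 2 clusters).
#' @param min_cells clusters with fewer cells are skipped with a warning.
#' @return tibble: `cluster`, `gene`, `z`, `log2_fc`, `p`, `q`, ranked within
#'   cluster by decreasing z.
#' @export
stratified_markers <- function(bundle, clusters, min_cells = 2) {
  if (length(unique(clusters)) < 2) abort("need >= 2 clusters")
  batch <- bundle_cell_col(bundle, "batch")
  norm <- as.matrix(lognormalize(bundle))
  out <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    if (sum(in_cl) < min_cells) {
      warn(sprintf("cluster %s has < %d cells; skipped", cl, min_cells))
      next
    }
    zs <- list(); ws <- list()
    for (b in unique(batch)) {
      in_b <- batch == b
      n1 <- sum(in_cl & in_b); n2 <- sum(!in_cl & in_b)
      if (n1 == 0 || n2 == 0) next
      zs[[b]] <- ranksum_z(norm[in_b, , drop = FALSE], in_cl[in_b])
      ws[[b]] <- sqrt(n1 * n2 / (n1 + n2 + 1))
    }
    if (length(zs) == 0) next
    zm <- do.call(rbind, zs)
    wv <- unlist(ws)
    z <- colSums(zm * wv) / sqrt(sum(wv^2))
    mu1 <- colMeans(norm[in_cl, , drop = FALSE])
    mu0 <- colMeans(norm[!in_cl, , drop = FALSE])
    lfc <- log2((mu1 + 1e-9) / (mu0 + 1e-9))
    p <- 2 * pnorm(-abs(z))
    out[[length(out) + 1]] <- tibble::tibble(
      cluster = cl, gene = colnames(norm), z = unname(z),
      log2_fc = unname(lfc), p = unname(p),
      q = unname(p.adjust(p, "BH"))) %>%
      arrange(desc(.data$z))
  }
  bind_rows(out)
}

#' Nearest-centroid labeling (pseudo-bulk molecular subtyping)
#'
#' Assigns each query profile the label of the reference centroid with the
#' highest Spearman correlation over shared genes. Rank-based, so invariant
#' to monotone transforms of the query. With the PAM50-style centroids of
#' breast-cancer subtypes this acts as a generic pseudo-bulk subtyper.
#'
#' @param query samples x genes matrix (e.g. [pseudobulk_aggregate()] rows),
#'   or a single named numeric vector.
#' @param panel labels x genes matrix of reference centroid profiles.
#' @param min_shared minimum number of shared genes (default 5).
#' @return tibble: `sample`, `label` (`"unassigned"` for constant profiles),
#'   `correlation`, plus one correlation column per centroid.
#' @export
nearest_centroid_label <- function(query, panel, min_shared = 5) {
  if (is.null(dim(query))) query <- matrix(query, 1, dimnames = list("query", names(query)))
  shared <- intersect(colnames(query), colnames(panel))
  if (length(shared) < min_shared) {
    abort(sprintf("only %d shared genes (need >= %d)", length(shared), min_shared))
  }
  q <- query[, shared, drop = FALSE]
  p <- panel[, shared, drop = FALSE]
  cors <- matrix(NA_real_, nrow(q), nrow(p),
                 dimnames = list(rownames(q), rownames(p)))
  for (i in seq_len(nrow(q))) {
    if (sd(q[i, ]) == 0) next
    cors[i, ] <- apply(p, 1, function(cent) {
      if (sd(cent) == 0) return(NA_real_)
      cor(q[i, ], cent, method = "spearman")
    })
  }
  label <- apply(cors, 1, function(r) {
    if (all(is.na(r))) "unassigned" else rownames(p)[which.max(r)]
  })
  best <- apply(cors, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  bind_cols(tibble::tibble(sample = rownames(q), label = unname(label),
                           correlation = unname(best)),
            tibble::as_tibble(cors))
}
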