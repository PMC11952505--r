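#' Bootstrap-stabilized recursive bipartition of clusters
#'
#' Learns a binary tree over clusters: at each node the member clusters'
#' mean embeddings are split by 2-means, repeated over `n_boots` bootstrap
#' resamples of cells (per-cluster resampling, cluster sizes square-root
#' downsampled); the modal bipartition is taken as the node's split and its
#' stability is the fraction of resamples agreeing with it. Recursion stops
#' at singleton clusters, so leaves partition the input cluster set and each
#' internal node has exactly two children.
#'
#' @param embedding cells x d matrix (an integrated embedding).
#' @param clusters per-cell cluster labels (>= 2 distinct clusters; apply
#'   [donor_entropy_filter()] first to drop donor-specific clusters).
#' @param n_boots bootstrap resamples per node (default 400; smaller values
#'   trade stability resolution for speed).
#' @param seed RNG seed.
#' @return a `cluster_taxonomy`: list with `nodes`, a tibble holding per
#'   node: `node_id`, `parent`, `depth` (root = 1), `is_leaf`, member
#'   `clusters` (list-column), `left`/`right` child ids, and bootstrap
#'   `stability` (NA at leaves).
#' @export
recursive_bipartition <- function(embedding, clusters, n_boots = 400, seed = 1L) {
  ids <- sort(unique(clusters))
  if (length(ids) < 2) abort("need >= 2 clusters after filtering")
  set.seed(as.integer(seed))
  cell_idx <- split(seq_along(clusters), clusters)

  centroid_of <- function(idx_list) {
    t(vapply(idx_list, function(ix) colMeans(embedding[ix, , drop = FALSE]),
             numeric(ncol(embedding))))
  }
  split_2means <- function(cent) {
    if (nrow(unique(cent)) < 2) return(sample(1:2, nrow(cent), replace = TRUE))
    if (nrow(cent) == 2) return(1:2)  # kmeans needs n > k
    stats::kmeans(cent, centers = 2, nstart = 5)$cluster
  }
  canonical_key <- function(members, side) {
    # side containing the lexicographically smallest member labels the split
    a <- members[side == side[1]]
    paste(sort(as.character(a)), collapse = "|")
  }

  rows <- list()
  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; next_id }

  build <- function(members, parent, depth) {
    id <- new_id()
    if (length(members) == 1) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        node_id = id, parent = parent, depth = depth, is_leaf = TRUE,
        clusters = list(members), left = NA_integer_, right = NA_integer_,
        stability = NA_real_)
      return(id)
    }
    keys <- character(n_boots)
    sides_by_key <- list()
    for (b in seq_len(n_boots)) {
      boot_idx <- lapply(members, function(cl) {
        ix <- cell_idx[[as.character(cl)]]
        sample(ix, max(2, ceiling(sqrt(length(ix)))), replace = TRUE)
      })
      side <- split_2means(centroid_of(boot_idx))
      if (length(unique(side)) < 2) side[1] <- 3 - side[2]
      k <- canonical_key(members, side)
      keys[b] <- k
      if (is.null(sides_by_key[[k]])) sides_by_key[[k]] <- side
    }
    tab <- table(keys)
    modal <- names(tab)[which.max(tab)]
    stability <- max(tab) / n_boots
    side <- sides_by_key[[modal]]
    left_members <- members[side == side[1]]
    right_members <- members[side != side[1]]
    left_id <- build(left_members, id, depth + 1)
    right_id <- build(right_members, id, depth + 1)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node_id = id, parent = parent, depth = depth, is_leaf = FALSE,
      clusters = list(members), left = left_id, right = right_id,
      stability = stability)
    id
  }
  build(ids, NA_integer_, 1L)
  nodes <- bind_rows(rows) %>% arrange(.data$node_id)
  structure(list(nodes = nodes), class = "cluster_taxonomy")
}

#' @export
print.cluster_taxonomy <- function(x, ...) {
  n_leaf <- sum(x$nodes$is_leaf)
  cat(sprintf("<cluster_taxonomy> %d clusters, %d internal nodes\n",
              n_leaf, sum(!x$nodes$is_leaf)))
  cat(" ", taxonomy_to_newick(x), "\n")
  invisible(x)
}

#' Serialize a taxonomy to Newick
#'
#' Internal nodes carry their bootstrap stability as node labels; extra
#' per-node annotations (e.g. hazard directions) can be supplied as a named
#' character vector over node ids.
#'
#' @param taxonomy a `cluster_taxonomy`.
#' @param annotations optional named character vector keyed by node id.
#' @return Newick string.
#' @export
taxonomy_to_newick <- function(taxonomy, annotations = NULL) {
  nd <- taxonomy$nodes
  lab <- function(id) {
    r <- nd[nd$node_id == id, ]
    ann <- if (!is.null(annotations) && as.character(id) %in% names(annotations)) {
      annotations[[as.character(id)]]
    } else ""
    if (r$is_leaf) {
      paste0(r$clusters[[1]], ann)
    } else {
      paste0("(", lab(r$left), ",", lab(r$right), ")",
             format(r$stability, digits = 3), ann)
    }
  }
  root <- nd$node_id[is.na(nd$parent)]
  paste0(lab(root), ";")
}

#' Per-node gene signatures
#'
#' At each internal node, cells of the left clade are compared with cells of
#' the right clade using the batch-stratified rank-sum of
#' [stratified_markers()]; genes passing the q-value cutoff are stored as
#' the node signature with their direction (`left`/`right` = higher in that
#' clade). Leaves carry no signature.
#'
#' @param bundle a [cell_bundle()] with a `batch` column, same cells (and
#'   order) as the clustering the taxonomy was built from.
#' @param taxonomy a `cluster_taxonomy`.
#' @param clusters per-cell cluster labels.
#' @param q_cutoff BH-adjusted p cutoff (default 0.05).
#' @param top_n cap per direction per node (default 25).
#' @return tibble: `node_id`, `gene`, `z`, `q`, `direction`.
#' @export
node_signatures <- function(bundle, taxonomy, clusters, q_cutoff = 0.05,
                            top_n = 25) {
  batch <- bundle_cell_col(bundle, "batch")
  norm <- as.matrix(lognormalize(bundle))
  nd <- taxonomy$nodes
  out <- list()
  for (i in which(!nd$is_leaf)) {
    left_cl <- nd$clusters[[match(nd$left[i], nd$node_id)]]
    right_cl <- nd$clusters[[match(nd$right[i], nd$node_id)]]
    in_node <- clusters %in% c(left_cl, right_cl)
    in_left <- clusters[in_node] %in% left_cl
    zs <- list(); ws <- list()
    for (b in unique(batch[in_node])) {
      sel <- batch[in_node] == b
      n1 <- sum(in_left & sel); n2 <- sum(!in_left & sel)
      if (n1 == 0 || n2 == 0) next
      zs[[b]] <- ranksum_z(norm[in_node, , drop = FALSE][sel, , drop = FALSE],
                           in_left[sel])
      ws[[b]] <- sqrt(n1 * n2 / (n1 + n2 + 1))
    }
    if (length(zs) == 0) next
    z <- colSums(do.call(rbind, zs) * unlist(ws)) / sqrt(sum(unlist(ws)^2))
    q <- p.adjust(2 * pnorm(-abs(z)), "BH")
    tbl <- tibble::tibble(node_id = nd$node_id[i], gene = colnames(norm),
                          z = z, q = q,
                          direction = ifelse(z > 0, "left", "right")) %>%
      filter(.data$q < q_cutoff) %>%
      group_by(.data$direction) %>%
      arrange(desc(abs(.data$z)), .by_group = TRUE) %>%
      slice_head(n = top_n) %>%
      ungroup()
    if (nrow(tbl) == 0) {
      warn(sprintf("node %d: empty signature", nd$node_id[i]))
    }
    out[[length(out) + 1]] <- tbl
  }
  bind_rows(out)
}

#' Random-forest discriminative factors per taxonomy level
#'
#' At each internal node of the requested depth, a random forest is trained
#' to separate the two clades from cells' continuous scores and encoded
#' metadata, and the `top_k` features by Gini impurity importance are
#' returned, each annotated with the clade whose feature mean is higher.
#' Forests use 500 trees, sqrt-features per split and class-balanced
#' sampling.
#'
#' @param features cells x features numeric matrix or data frame (gene-set
#'   activities, age, encoded grade/subtype, ...).
#' @param taxonomy a `cluster_taxonomy`.
#' @param clusters per-cell cluster labels aligned with `features` rows.
#' @param level tree depth to analyse (root = 1).
#' @param top_k features to report per node (default 5).
#' @param seed RNG seed.
#' @param min_cells nodes with a clade smaller than this are skipped with a
#'   warning (default 20).
#' @param ntree forest size.
#' @return tibble: `node_id`, `rank`, `feature`, `importance`,
#'   `importance_share`, `higher_in` (`left`/`right`).
#' @export
rf_discriminative_factors <- function(features, taxonomy, clusters, level = 1,
                                      top_k = 5, seed = 1L, min_cells = 20,
                                      ntree = 500) {
  x <- as.data.frame(features)
  stopifnot(nrow(x) == length(clusters))
  nd <- taxonomy$nodes
  at_level <- nd[!nd$is_leaf & nd$depth == level, ]
  if (nrow(at_level) == 0) abort(sprintf("no internal node at level %d", level))
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(nrow(at_level))) {
    left_cl <- nd$clusters[[match(at_level$left[i], nd$node_id)]]
    right_cl <- nd$clusters[[match(at_level$right[i], nd$node_id)]]
    lab <- ifelse(clusters %in% left_cl, "left",
                  ifelse(clusters %in% right_cl, "right", NA))
    sel <- !is.na(lab)
    if (min(table(lab[sel])) < min_cells) {
      warn(sprintf("node %d: clade with < %d cells; skipped",
                   at_level$node_id[i], min_cells))
      next
    }
    y <- factor(lab[sel], levels = c("left", "right"))
    nmin <- min(table(y))
    rf <- randomForest::randomForest(
      x = x[sel, , drop = FALSE], y = y, ntree = ntree, importance = TRUE,
      strata = y, sampsize = c(nmin, nmin))
    imp <- randomForest::importance(rf, type = 2)[, 1]
    ord <- order(-imp)
    top <- head(ord, top_k)
    means_left <- colMeans(x[sel, , drop = FALSE][y == "left", , drop = FALSE])
    means_right <- colMeans(x[sel, , drop = FALSE][y == "right", , drop = FALSE])
    out[[length(out) + 1]] <- tibble::tibble(
      node_id = at_level$node_id[i],
      rank = seq_along(top),
      feature = names(imp)[top],
      importance = unname(imp[top]),
      importance_share = unname(imp[top] / sum(imp)),
      higher_in = unname(ifelse(means_left[top] >= means_right[top],
                                "left", "right")))
  }
  bind_rows(out)
}
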