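# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# default-scale synthetic atlas (1200 singlets + 60 doublets)
default_sim <- function() {
  if (is.null(.fixture_cache$sim)) .fixture_cache$sim <- simulate_atlas(sim_config())
  .fixture_cache$sim
}

# small, fast atlas for loops over seeds
small_config <- function(seed = 1L, ...) {
  sim_config(n_batches = 3, donors_per_batch = 2, cells_per_donor = 60,
             n_genes = 400, seed = seed, ...)
}

# QC'd default sim with embedding, clusters and aligned truth
default_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    sim <- default_sim()
    qc <- mad_outlier_filter(sim$bundle)
    bb <- qc$bundle
    truth <- sim$truth$cells[match(bb$cells$cell_id, sim$truth$cells$cell_id), ]
    norm <- lognormalize(bb)
    hvg <- select_hvg(norm, 300)
    emb <- pca_embed(norm, hvg, d = 10)
    centered <- baseline_batch_center(emb, bb$cells$batch)
    .fixture_cache$pipe <- list(sim = sim, bundle = bb, truth = truth,
                                norm = norm, hvg = hvg, emb = emb,
                                centered = centered)
  }
  .fixture_cache$pipe
}

# a tiny bundle built by hand: counts matrix + minimal metadata
toy_bundle <- function(counts, batch = NULL, donor = NULL) {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%03d", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  cells <- tibble::tibble(cell_id = rownames(counts),
                          batch = batch %||% rep("b1", n),
                          donor = donor %||% rep("d1", n))
  genes <- tibble::tibble(symbol = colnames(counts),
                          chromosome = rep("chr1", ncol(counts)),
                          start = seq_len(ncol(counts)) * 1000L)
  cell_bundle(counts, cells, genes)
}

# Gaussian-blob embedding with a planted 2x2 cluster hierarchy:
# two super-groups `sep` apart, two clusters `sep/ratio` apart inside each
hierarchy_embedding <- function(n_per = 80, d = 5, sep = 10, ratio = 2,
                                seed = 1L) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(0, sep / ratio),
                   c(sep, 0), c(sep, sep / ratio))
  emb <- do.call(rbind, lapply(1:4, function(i) {
    m <- matrix(rnorm(n_per * d), n_per, d)
    m[, 1] <- m[, 1] + centers[i, 1]
    m[, 2] <- m[, 2] + centers[i, 2]
    m
  }))
  list(embedding = emb,
       clusters = rep(c("A1", "A2", "B1", "B2"), each = n_per))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
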