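#' Configuration for the synthetic atlas generator
#'
#' Describes the statistical structure of a simulated multi-dataset tumor
#' atlas: batches (datasets) with additive log-scale batch effects, donors
#' nested in batches, three compartments (epithelial / immune / stromal) with
#' canonical marker genes, planted cell types organised in a two-level
#' hierarchy, copy-number gain/loss segments in malignant epithelial cells,
#' composition shifts tied to donor covariates, and a stated doublet fraction.
#'
#' Defaults are desk-scale: 3 batches x 4 donors x 100 cells (1200 singlets),
#' 600 genes over 5 chromosomes, batch effect SD 0.5 on the log-mean, a
#' 50-gene 2x gain on chromosome 3 in malignant cells, 5% doublets, and a
#' 2-fold enrichment of T cells with high tumor grade.
#'
#' @param n_batches number of datasets/batches.
#' @param donors_per_batch donors nested within each batch.
#' @param cells_per_donor singlet cells per donor.
#' @param n_genes total genes; must be at least 160 to hold the marker and
#'   type-signature panels.
#' @param compartment_fractions named probabilities over
#'   `c("epithelial","immune","stromal")`; must sum to 1.
#' @param batch_effect_sd SD of the gene-wise additive shift on the log mean,
#'   drawn independently per batch x gene.
#' @param cnv_segments list of segments, each
#'   `list(chromosome=, start=, length=, fold_change=)` where `start` is the
#'   gene index within the chromosome and `fold_change > 0` multiplies the
#'   expected expression of malignant cells.
#' @param composition_effects tibble with columns `cell_type`, `covariate`
#'   (currently `"grade"`: effect applies to grade-3 donors), `lfc`
#'   (log fold-change on the within-compartment type weight).
#' @param hierarchy_spec named list of two super-groups over the malignant
#'   epithelial types (the planted two-level taxonomy).
#' @param doublet_fraction fraction of synthetic doublets added on top of the
#'   singlets (averaged random pairs, resampled).
#' @param malignant_types,normal_epithelial character vectors naming the
#'   planted epithelial types.
#' @param seed integer RNG seed; the generator is fully deterministic given it.
#'
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_batches = 3,
                       donors_per_batch = 4,
                       cells_per_donor = 100,
                       n_genes = 600,
                       compartment_fractions = c(epithelial = 0.5, immune = 0.3, stromal = 0.2),
                       batch_effect_sd = 0.5,
                       cnv_segments = list(list(chromosome = "chr3", start = 11, length = 50,
                                                fold_change = 2)),
                       composition_effects = tibble::tibble(cell_type = "Imm.T",
                                                            covariate = "grade",
                                                            lfc = log(2)),
                       hierarchy_spec = list(MalA = c("Mal.1", "Mal.2"),
                                             MalB = c("Mal.3", "Mal.4")),
                       doublet_fraction = 0.05,
                       malignant_types = c("Mal.1", "Mal.2", "Mal.3", "Mal.4"),
                       normal_epithelial = "Epi.Normal",
                       seed = 1L) {
  stopifnot(n_batches >= 1, donors_per_batch >= 1, cells_per_donor >= 1)
  if (abs(sum(compartment_fractions) - 1) > 1e-8) {
    abort("compartment_fractions must sum to 1")
  }
  if (!setequal(names(compartment_fractions), c("epithelial", "immune", "stromal"))) {
    abort("compartment_fractions must be named epithelial/immune/stromal")
  }
  for (seg in cnv_segments) {
    if (seg$fold_change <= 0) abort("cnv fold-changes must be > 0")
  }
  if (n_genes < 160) {
    abort("n_genes must be at least 160 to accommodate the marker panels")
  }
  if (doublet_fraction < 0 || doublet_fraction >= 1) abort("doublet_fraction must be in [0,1)")
  structure(list(n_batches = n_batches, donors_per_batch = donors_per_batch,
                 cells_per_donor = cells_per_donor, n_genes = n_genes,
                 compartment_fractions = compartment_fractions,
                 batch_effect_sd = batch_effect_sd, cnv_segments = cnv_segments,
                 composition_effects = composition_effects,
                 hierarchy_spec = hierarchy_spec,
                 doublet_fraction = doublet_fraction,
                 malignant_types = malignant_types,
                 normal_epithelial = normal_epithelial,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Canonical compartment marker panels
#'
#' The three marker panels used both by the generator (which up-shifts them in
#' their compartment) and by [marker_compartments()].
#'
#' @return named list of character vectors.
#' @export
compartment_markers <- function() {
  list(epithelial = c("EPCAM", "KRT8", "KRT18"),
       immune     = c("PTPRC", "CD3D", "CD3E", "CD68"),
       stromal    = c("COL1A1", "COL1A2", "ENG"))
}

# internal: planted cell types per compartment with base within-compartment weights
synth_type_table <- function(config) {
  mal <- config$malignant_types
  epi <- c(config$normal_epithelial, mal)
  tibble::tibble(
    cell_type   = c(epi, "Imm.T", "Imm.Mac", "Str.Fib", "Str.Endo"),
    compartment = c(rep("epithelial", length(epi)), "immune", "immune", "stromal", "stromal"),
    base_weight = c(0.3, rep(0.7 / length(mal), length(mal)), 0.6, 0.4, 0.6, 0.4),
    malignant   = c(FALSE, rep(TRUE, length(mal)), FALSE, FALSE, FALSE, FALSE)
  )
}

# internal: gene metadata frame with marker + signature gene layout
synth_gene_table <- function(config) {
  n <- config$n_genes
  markers <- unlist(compartment_markers(), use.names = FALSE)
  symbols <- c(markers, sprintf("GENE%04d", seq_len(n - length(markers))))
  n_chr <- 5L
  per_chr <- ceiling(n / n_chr)
  chrom <- rep(sprintf("chr%d", seq_len(n_chr)), each = per_chr)[seq_len(n)]
  start <- integer(n)
  for (ch in unique(chrom)) start[chrom == ch] <- seq_len(sum(chrom == ch)) * 10000L
  tibble::tibble(symbol = symbols, chromosome = chrom, start = start)
}

#' Simulate a synthetic multi-dataset tumor atlas
#'
#' Draws counts from a negative-binomial hierarchy: gene baseline log-means
#' are log-normal, compartment markers and planted type/super-group signature
#' genes are up-shifted on the log scale, batch shifts are added to the log
#' mean before sampling, per-cell sequencing depth is log-normal, and
#' malignant cells carry the configured copy-number fold-changes. A stated
#' fraction of cells are synthetic doublets: the expected profiles of two
#' random singlets are averaged and counts resampled.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a [cell_bundle()]) and `truth`, a list holding
#'   per-cell ground truth (`cells`: compartment, type, malignant and doublet
#'   flags), the per-gene CNV table (`cnv_genes`), the planted type signature
#'   gene sets (`type_signatures`), and the echoed composition effects.
#' @export
simulate_atlas <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- synth_gene_table(config)
  types <- synth_type_table(config)
  n_gene <- nrow(genes)
  markers <- compartment_markers()

  # baseline gene log-means and dispersions
  log_mu <- rnorm(n_gene, mean = log(0.3), sd = 1)
  size_g <- rlnorm(n_gene, meanlog = log(10), sdlog = 0.5)  # NB size (1/dispersion)

  # compartment marker up-shift (+2 on log scale in own compartment)
  comp_shift <- matrix(0, n_gene, 3, dimnames = list(genes$symbol, names(markers)))
  for (cp in names(markers)) comp_shift[markers[[cp]], cp] <- 2

  # planted type and super-group signature genes: 10 genes each, +1.5 shift,
  # drawn from a reserved block so they never overlap markers or CNV segments
  reserved <- which(genes$chromosome %in% c("chr1", "chr2"))
  reserved <- setdiff(reserved, match(unlist(markers), genes$symbol))
  sig_blocks <- split(reserved[seq_len(10 * (nrow(types) + length(config$hierarchy_spec)))],
                      rep(seq_len(nrow(types) + length(config$hierarchy_spec)), each = 10))
  type_shift <- matrix(0, n_gene, nrow(types), dimnames = list(genes$symbol, types$cell_type))
  type_signatures <- list()
  for (i in seq_len(nrow(types))) {
    idx <- sig_blocks[[i]]
    type_shift[idx, i] <- 1.5
    type_signatures[[types$cell_type[i]]] <- genes$symbol[idx]
  }
  for (j in seq_along(config$hierarchy_spec)) {
    idx <- sig_blocks[[nrow(types) + j]]
    grp <- config$hierarchy_spec[[j]]
    type_shift[idx, grp] <- type_shift[idx, grp] + 1.5
    type_signatures[[names(config$hierarchy_spec)[j]]] <- genes$symbol[idx]
  }

  # CNV fold-change vector (log scale) applied to malignant cells
  cnv_lfc <- numeric(n_gene)
  for (seg in config$cnv_segments) {
    on_chr <- which(genes$chromosome == seg$chromosome)
    if (seg$start + seg$length - 1 > length(on_chr)) {
      abort(sprintf("cnv segment exceeds %s (%d genes)", seg$chromosome, length(on_chr)))
    }
    cnv_lfc[on_chr[seg$start:(seg$start + seg$length - 1)]] <- log(seg$fold_change)
  }

  # batch x gene additive shifts on the log mean
  batches <- sprintf("batch%d", seq_len(config$n_batches))
  batch_shift <- matrix(rnorm(config$n_batches * n_gene, 0, config$batch_effect_sd),
                        nrow = config$n_batches, dimnames = list(batches, genes$symbol))

  # donors and their covariates
  donors <- tidyr::expand_grid(batch = batches, d = seq_len(config$donors_per_batch)) %>%
    mutate(donor = sprintf("%s_donor%d", .data$batch, .data$d),
           age = round(rnorm(dplyr::n(), 58, 12)),
           grade = sample(1:3, dplyr::n(), replace = TRUE),
           subtype = sample(c("LumA", "LumB", "Her2", "Normal_like", "Basal"),
                            dplyr::n(), replace = TRUE)) %>%
    select(-"d")

  # assign cells: compartment then type, with composition effects on type weights
  cell_rows <- purrr::pmap(donors, function(batch, donor, age, grade, subtype) {
    n <- config$cells_per_donor
    comp <- sample(names(config$compartment_fractions), n, replace = TRUE,
                   prob = config$compartment_fractions)
    w <- types$base_weight
    ce <- config$composition_effects
    if (nrow(ce) > 0) {
      for (r in seq_len(nrow(ce))) {
        hit <- types$cell_type == ce$cell_type[r]
        if (ce$covariate[r] == "grade" && grade == 3) w[hit] <- w[hit] * exp(ce$lfc[r])
      }
    }
    type <- vapply(comp, function(cp) {
      pool <- types$compartment == cp
      sample(types$cell_type[pool], 1, prob = w[pool])
    }, character(1))
    tibble::tibble(batch = batch, donor = donor, age = age, grade = grade,
                   subtype = subtype, compartment = comp, cell_type = type)
  }) %>% bind_rows()
  n_cell <- nrow(cell_rows)
  cell_rows$cell_id <- sprintf("cell%05d", seq_len(n_cell))
  cell_rows$malignant <- cell_rows$cell_type %in% types$cell_type[types$malignant]
  cell_rows$doublet <- FALSE

  # expected counts: depth-scaled softmax of log-mean + shifts, CNV applied after
  # depth scaling so a 2x gain doubles segment counts
  depth <- rlnorm(n_cell, meanlog = log(4000), sdlog = 0.25)
  comp_idx <- match(cell_rows$compartment, colnames(comp_shift))
  type_idx <- match(cell_rows$cell_type, colnames(type_shift))
  batch_idx <- match(cell_rows$batch, batches)

  lambda_for <- function(ci, ti, bi, mal, dep) {
    lm <- log_mu + comp_shift[, ci] + type_shift[, ti] + batch_shift[bi, ]
    lam <- exp(lm)
    lam <- lam / sum(lam) * dep
    if (mal) lam <- lam * exp(cnv_lfc)
    lam
  }
  lambda <- matrix(0, n_cell, n_gene)
  for (i in seq_len(n_cell)) {
    lambda[i, ] <- lambda_for(comp_idx[i], type_idx[i], batch_idx[i],
                              cell_rows$malignant[i], depth[i])
  }
  counts <- matrix(rnbinom(n_cell * n_gene, mu = as.vector(lambda),
                           size = rep(size_g, each = n_cell)),
                   n_cell, n_gene)

  # synthetic doublets: average two random singlet expected profiles, resample
  n_dbl <- round(config$doublet_fraction * n_cell)
  if (n_dbl > 0) {
    p1 <- sample.int(n_cell, n_dbl, replace = TRUE)
    p2 <- sample.int(n_cell, n_dbl, replace = TRUE)
    lam_d <- (lambda[p1, , drop = FALSE] + lambda[p2, , drop = FALSE]) / 2
    cnt_d <- matrix(rnbinom(n_dbl * n_gene, mu = as.vector(lam_d),
                            size = rep(size_g, each = n_dbl)), n_dbl, n_gene)
    dbl_rows <- cell_rows[p1, ]
    dbl_rows$cell_id <- sprintf("doublet%04d", seq_len(n_dbl))
    dbl_rows$doublet <- TRUE
    dbl_rows$doublet_parents <- paste(cell_rows$cell_id[p1], cell_rows$cell_id[p2], sep = "+")
    cell_rows$doublet_parents <- NA_character_
    cell_rows <- bind_rows(cell_rows, dbl_rows)
    counts <- rbind(counts, cnt_d)
  }

  bundle <- cell_bundle(counts,
                        cell_rows %>% select("cell_id", "batch", "donor", "age",
                                             "grade", "subtype"),
                        genes)
  truth <- list(
    cells = cell_rows %>% select("cell_id", "batch", "donor", "compartment",
                                 "cell_type", "malignant", "doublet",
                                 dplyr::any_of("doublet_parents")),
    cnv_genes = tibble::tibble(symbol = genes$symbol, log_fold_change = cnv_lfc),
    type_signatures = type_signatures,
    composition_effects = config$composition_effects,
    config = config
  )
  list(bundle = bundle, truth = truth)
}

#' Simulate a bulk expression cohort with survival outcomes
#'
#' Per-sample signature activity is standard normal; survival times are
#' exponential with hazard `baseline_hazard * exp(beta * activity)` and an
#' independent exponential censoring process; signature-gene expression is the
#' standard-normal background shifted by the sample's activity; age is
#' simulated independently of outcome.
#'
#' @param n_samples number of samples (>= 20).
#' @param signature character vector of signature gene symbols.
#' @param beta log-hazard per unit of signature activity.
#' @param seed RNG seed.
#' @param n_genes total genes in the expression matrix (signature included).
#' @param baseline_hazard events per month at activity 0; must be positive.
#' @param censor_fraction target fraction of censored samples; 0 means all
#'   events observed.
#' @param activity_gain expression shift per unit activity on signature genes.
#' @return a `survival_cohort`: list with `expression` (samples x genes) and
#'   `samples` tibble (`sample_id`, `time` in months, `event` 0/1, `age`,
#'   `activity` — the latent truth).
#' @export
simulate_bulk_cohort <- function(n_samples, signature, beta, seed = 1L,
                                 n_genes = 500, baseline_hazard = 0.02,
                                 censor_fraction = 0.3, activity_gain = 1) {
  stopifnot(n_samples >= 20)
  if (baseline_hazard <= 0) abort("baseline_hazard must be positive")
  set.seed(as.integer(seed))
  a <- rnorm(n_samples)
  t_event <- rexp(n_samples, rate = baseline_hazard * exp(beta * a))
  if (censor_fraction > 0) {
    c_rate <- baseline_hazard * censor_fraction / (1 - censor_fraction)
    t_cens <- rexp(n_samples, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n_samples)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  extra <- max(0, n_genes - length(signature))
  gene_names <- c(signature, sprintf("BGENE%04d", seq_len(extra)))
  expr <- matrix(rnorm(n_samples * length(gene_names)), n_samples,
                 dimnames = list(sprintf("sample%04d", seq_len(n_samples)), gene_names))
  expr[, signature] <- expr[, signature] + a * activity_gain
  structure(list(
    expression = expr,
    samples = tibble::tibble(sample_id = rownames(expr), time = time,
                             event = event, age = round(rnorm(n_samples, 60, 10)),
                             activity = a)
  ), class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort> %d samples x %d genes, %d events\n",
              nrow(x$expression), ncol(x$expression), sum(x$samples$event)))
  invisible(x)
}

#' Append a totals row to a per-dataset manifest
#'
#' @param manifest tibble with columns `dataset`, `n_patients`, `n_cells`.
#' @return the manifest with a final `Total` row summing both count columns.
#' @export
manifest_totals <- function(manifest) {
  stopifnot(all(c("dataset", "n_patients", "n_cells") %in% names(manifest)))
  bind_rows(manifest,
            tibble::tibble(dataset = "Total",
                           n_patients = sum(manifest$n_patients),
                           n_cells = sum(manifest$n_cells)))
}

#' Write a synthetic atlas fixture to disk
#'
#' Writes the bundle as Matrix Market counts plus TSV metadata
#' (`matrix.mtx`, `barcodes.tsv`, `features.tsv`, `cell_metadata.tsv`), the
#' planted type signatures as `gene_sets.gmt`, the ground truth as
#' `truth_cells.tsv`, and a `manifest.tsv` listing per-dataset patient and
#' cell counts with a totals row. Round-trips losslessly through
#' [read_bundle()].
#'
#' @param bundle a [cell_bundle()]; must be non-empty.
#' @param truth the truth list from [simulate_atlas()] (optional).
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest tibble, invisibly.
#' @export
write_fixture_bundle <- function(bundle, truth = NULL, dir, overwrite = FALSE) {
  if (n_cells(bundle) == 0 || n_genes(bundle) == 0) {
    abort("refusing to write an empty bundle")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(sprintf("directory %s exists and is non-empty; set overwrite = TRUE", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bundle(bundle, dir)
  if (!is.null(truth)) {
    readr::write_tsv(truth$cells, file.path(dir, "truth_cells.tsv"))
    write_gmt(truth$type_signatures, file.path(dir, "gene_sets.gmt"))
  } else {
    write_gmt(compartment_markers(), file.path(dir, "gene_sets.gmt"))
  }
  per_ds <- bundle$cells %>%
    group_by(dataset = .data$batch) %>%
    summarise(n_patients = dplyr::n_distinct(.data$donor), n_cells = dplyr::n(),
              .groups = "drop")
  manifest <- manifest_totals(per_ds)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Simulate a per-sample cell-type composition table
#'
#' A lightweight generator for differential-abundance calibration: per-sample
#' type weights start from a shared Dirichlet-like baseline, get a per-batch
#' and per-sample log-normal wobble, and the designated type's weight is
#' multiplied by `exp(lfc)` in high-grade (grade 3) samples; counts are
#' multinomial at the stated sequencing depth. Covariates grade, subtype and
#' age are drawn independently apart from the planted effect.
#'
#' @param n_samples number of samples.
#' @param n_types number of cell types.
#' @param affected_type index of the type carrying the planted effect.
#' @param lfc log fold-change of that type's weight in grade-3 samples
#'   (0 = null).
#' @param cells_per_sample multinomial depth per sample.
#' @param n_batches batches samples are split across.
#' @param noise_sd SD of the per-sample log-normal weight wobble.
#' @param seed RNG seed.
#' @return a `composition_table` (see [composition_table()]).
#' @export
simulate_composition <- function(n_samples = 40, n_types = 10,
                                 affected_type = 1, lfc = log(2),
                                 cells_per_sample = 1000, n_batches = 2,
                                 noise_sd = 0.25, seed = 1L) {
  set.seed(as.integer(seed))
  types <- sprintf("type%02d", seq_len(n_types))
  base_w <- rlnorm(n_types, 0, 0.3)
  samples <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_samples)),
    batch = sample(sprintf("batch%d", seq_len(n_batches)), n_samples, replace = TRUE),
    grade = sample(1:3, n_samples, replace = TRUE),
    subtype = sample(c("LumA", "LumB", "Her2", "Normal_like", "Basal"),
                     n_samples, replace = TRUE),
    age = round(rnorm(n_samples, 58, 12)))
  batch_tilt <- matrix(rnorm(n_batches * n_types, 0, noise_sd), n_batches)
  counts <- t(vapply(seq_len(n_samples), function(i) {
    w <- base_w * exp(batch_tilt[match(samples$batch[i],
                                       sprintf("batch%d", seq_len(n_batches))), ] +
                        rnorm(n_types, 0, noise_sd))
    if (samples$grade[i] == 3) w[affected_type] <- w[affected_type] * exp(lfc)
    as.integer(rmultinom(1, cells_per_sample, w / sum(w)))
  }, integer(n_types)))
  colnames(counts) <- types
  rownames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples), class = "composition_table")
}
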