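test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(compartment_fractions = c(epithelial = 0.5,
                                                    immune = 0.3,
                                                    stromal = 0.3)),
               "sum to 1")
  expect_error(sim_config(n_genes = 100), "at least 160")
  expect_error(sim_config(cnv_segments = list(list(chromosome = "chr3",
                                                   start = 1, length = 10,
                                                   fold_change = 0))),
               "> 0")
  expect_error(sim_config(doublet_fraction = 1), "doublet_fraction")
})

test_that("simulate_atlas is deterministic and has the stated shape", {
  cfg <- small_config(seed = 7)
  a <- simulate_atlas(cfg)
  b <- simulate_atlas(cfg)
  expect_identical(as.matrix(a$bundle$counts), as.matrix(b$bundle$counts))
  expect_identical(a$truth$cells, b$truth$cells)

  n_singlet <- cfg$n_batches * cfg$donors_per_batch * cfg$cells_per_donor
  n_dbl <- round(cfg$doublet_fraction * n_singlet)
  expect_equal(n_cells(a$bundle), n_singlet + n_dbl)
  expect_equal(sum(a$truth$cells$doublet), n_dbl)
  expect_equal(n_genes(a$bundle), cfg$n_genes)
  expect_equal(dplyr::n_distinct(a$bundle$cells$batch), cfg$n_batches)
  expect_equal(dplyr::n_distinct(a$bundle$cells$donor),
               cfg$n_batches * cfg$donors_per_batch)

  # different seed changes the draw
  c2 <- simulate_atlas(small_config(seed = 8))
  expect_false(identical(as.matrix(a$bundle$counts), as.matrix(c2$bundle$counts)))
})

test_that("planted structure is where the truth says it is", {
  sim <- default_sim()
  truth <- sim$truth

  # CNV genes sit on chr3 positions 11..60 and nowhere else
  gt <- sim$bundle$genes
  on <- truth$cnv_genes$log_fold_change != 0
  expect_equal(sum(on), 50)
  expect_true(all(gt$chromosome[on] == "chr3"))
  idx_on_chr <- which(gt$chromosome == "chr3")
  expect_identical(which(on), idx_on_chr[11:60])
  expect_equal(unique(truth$cnv_genes$log_fold_change[on]), log(2))

  # compartment markers are enriched in their own compartment
  singlet <- !truth$cells$doublet
  comp <- truth$cells$compartment[singlet]
  cnt <- sim$bundle$counts[singlet, , drop = FALSE]
  for (cp in names(compartment_markers())) {
    for (g in compartment_markers()[[cp]]) {
      mu_in <- mean(cnt[comp == cp, g])
      mu_out <- mean(cnt[comp != cp, g])
      expect_gt(mu_in, mu_out)
    }
  }

  # type signatures live on chr1/chr2 and never overlap markers or the CNV block
  sig_genes <- unique(unlist(truth$type_signatures))
  sig_chr <- gt$chromosome[match(sig_genes, gt$symbol)]
  expect_true(all(sig_chr %in% c("chr1", "chr2")))
  expect_length(intersect(sig_genes, unlist(compartment_markers())), 0)
  expect_length(intersect(sig_genes, truth$cnv_genes$symbol[on]), 0)

  # malignant flag matches the malignant type list
  expect_identical(truth$cells$malignant,
                   truth$cells$cell_type %in% sim$truth$config$malignant_types)
})

test_that("grade-3 donors are enriched for the planted type", {
  # pool several seeds so the check reflects the generative effect, not noise
  frac <- purrr::map_dfr(1:5, function(s) {
    sim <- simulate_atlas(small_config(seed = s, doublet_fraction = 0))
    cells <- sim$truth$cells %>%
      dplyr::left_join(sim$bundle$cells %>% dplyr::select("cell_id", "grade"),
                       by = "cell_id") %>%
      dplyr::filter(.data$compartment == "immune")
    cells %>%
      dplyr::group_by(high = .data$grade == 3) %>%
      dplyr::summarise(f = mean(.data$cell_type == "Imm.T"), .groups = "drop")
  })
  agg <- frac %>% dplyr::group_by(.data$high) %>%
    dplyr::summarise(f = mean(.data$f), .groups = "drop")
  if (nrow(agg) == 2) {
    expect_gt(agg$f[agg$high], agg$f[!agg$high])
  } else {
    succeed("no grade contrast drawn in these seeds")
  }
})

test_that("simulate_bulk_cohort has the stated survival structure", {
  co <- simulate_bulk_cohort(200, sprintf("SIG%02d", 1:10), beta = 0.7, seed = 3)
  expect_s3_class(co, "survival_cohort")
  expect_equal(nrow(co$expression), 200)
  expect_true(all(co$samples$time > 0))
  expect_true(all(co$samples$event %in% 0:1))
  # censoring fraction near the 30% target
  expect_lt(abs(mean(co$samples$event == 0) - 0.3), 0.12)
  # signature genes correlate with the latent activity, background does not
  r_sig <- cor(co$expression[, "SIG01"], co$samples$activity)
  r_bg <- cor(co$expression[, "BGENE0001"], co$samples$activity)
  expect_gt(r_sig, 0.5)
  expect_lt(abs(r_bg), 0.3)
  # no censoring when asked
  co0 <- simulate_bulk_cohort(50, "SIG01", beta = 0, censor_fraction = 0)
  expect_true(all(co0$samples$event == 1))
  expect_error(simulate_bulk_cohort(50, "SIG01", beta = 0, baseline_hazard = 0),
               "positive")
  expect_error(simulate_bulk_cohort(5, "SIG01", beta = 0))
})

test_that("manifest_totals appends an exact totals row", {
  m <- tibble::tibble(dataset = c("a", "b"), n_patients = c(3L, 4L),
                      n_cells = c(100L, 250L))
  out <- manifest_totals(m)
  expect_equal(nrow(out), 3)
  expect_equal(out$dataset[3], "Total")
  expect_equal(out$n_patients[3], 7)
  expect_equal(out$n_cells[3], 350)
  expect_error(manifest_totals(tibble::tibble(dataset = "a")))
})

test_that("simulate_composition plants the requested effect", {
  ct <- simulate_composition(n_samples = 30, lfc = log(3), seed = 2)
  expect_s3_class(ct, "composition_table")
  expect_equal(dim(ct$counts), c(30, 10))
  expect_true(all(rowSums(ct$counts) == 1000))
  p1 <- ct$counts[, 1] / rowSums(ct$counts)
  expect_gt(mean(p1[ct$samples$grade == 3]), mean(p1[ct$samples$grade != 3]))
})

test_that("write_fixture_bundle round-trips and refuses unsafe writes", {
  sim <- simulate_atlas(small_config(seed = 11))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "fx")
  manifest <- write_fixture_bundle(sim$bundle, sim$truth, out)
  expect_true(all(c("matrix.mtx", "barcodes.tsv", "features.tsv",
                    "cell_metadata.tsv", "truth_cells.tsv", "gene_sets.gmt",
                    "manifest.tsv") %in% list.files(out)))
  expect_equal(manifest$dataset[nrow(manifest)], "Total")
  expect_equal(manifest$n_cells[nrow(manifest)], n_cells(sim$bundle))

  rt <- read_bundle(out)
  expect_identical(as.matrix(rt$counts), as.matrix(sim$bundle$counts))
  sets <- read_gmt(file.path(out, "gene_sets.gmt"))
  expect_identical(sets, sim$truth$type_signatures)

  expect_error(write_fixture_bundle(sim$bundle, sim$truth, out), "overwrite")
  expect_silent(write_fixture_bundle(sim$bundle, sim$truth, out, overwrite = TRUE))
  empty <- bundle_subset(sim$bundle, cells = integer(0))
  expect_error(write_fixture_bundle(empty, NULL, file.path(dir, "fx2")), "empty")
})
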