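# builds a small two-chromosome bundle where query cells carry an expression
# shift on a contiguous block of chr1
cnv_toy <- function(seed = 1, n_ref = 40, n_query = 20, n_per_chr = 30,
                    shift_cols = 6:15, fold = 3) {
  set.seed(seed)
  n <- n_ref + n_query
  g <- 2 * n_per_chr
  m <- matrix(rpois(n * g, 10), n, g)
  m[(n_ref + 1):n, shift_cols] <- matrix(
    rpois(n_query * length(shift_cols), 10 * fold), n_query)
  colnames(m) <- sprintf("g%03d", seq_len(g))
  rownames(m) <- sprintf("c%03d", seq_len(n))
  cells <- tibble::tibble(cell_id = rownames(m), batch = "b1", donor = "d1")
  genes <- tibble::tibble(symbol = colnames(m),
                          chromosome = rep(c("chr1", "chr2"), each = n_per_chr),
                          start = rep(seq_len(n_per_chr) * 1000L, 2))
  cell_bundle(m, cells, genes)
}

test_that("cnv_smooth matches a direct moving-average oracle", {
  b <- cnv_toy()
  expect_warning(cnv <- cnv_smooth(b, reference_cells = 1:40, window = 5,
                                   cutoff = 0), NA)
  expect_s3_class(cnv, "cnv_matrix")
  expect_equal(cnv$convention, "deviation")

  # oracle: relative log expression vs reference mean, windowed mean within
  # each chromosome with truncation at boundaries, per-cell median centering
  norm <- as.matrix(lognormalize(b))
  rel <- sweep(norm, 2, colMeans(norm[1:40, ]), `-`)
  oracle <- rel
  for (ch in c("chr1", "chr2")) {
    cols <- which(b$genes$chromosome == ch)
    for (j in seq_along(cols)) {
      win <- cols[max(1, j - 2):min(length(cols), j + 2)]
      oracle[, cols[j]] <- rowMeans(rel[, win, drop = FALSE])
    }
  }
  oracle <- oracle - apply(oracle, 1, median)
  expect_equal(cnv$scores, oracle, tolerance = 1e-12)
})

test_that("cnv_smooth validates inputs and reduces oversized windows", {
  b <- cnv_toy()
  expect_error(cnv_smooth(b, 1:40, window = 4), "odd")
  expect_error(cnv_smooth(b, 1:40, window = 1), "odd")
  expect_error(cnv_smooth(b, integer(0)), "empty")
  w <- capture_warnings(cnv_smooth(b, 1:40, window = 51, cutoff = 0))
  expect_length(w, 2)  # both chromosomes are narrower than the window
  expect_match(w, "using", all = TRUE)
  b2 <- toy_bundle(matrix(1:4, 2, 2))
  b2$genes$chromosome <- NULL
  expect_error(cnv_smooth(b2, 1), "chromosome")
})

test_that("the gain is localized: signal in the segment, none across chromosomes", {
  b <- cnv_toy(seed = 2)
  cnv <- cnv_smooth(b, reference_cells = 1:40, window = 5, cutoff = 0.1)
  q <- 41:60
  seg <- b$genes$symbol[8:13]                       # interior of the shifted block
  chr2 <- cnv$genes$symbol[cnv$genes$chromosome == "chr2"]
  seg_mean <- mean(cnv$scores[q, seg])
  chr2_scores <- cnv$scores[q, chr2]
  expect_gt(seg_mean, mean(chr2_scores) + 3 * sd(chr2_scores))
  # chr2 of query cells looks like chr2 of held-in reference cells
  expect_lt(abs(mean(chr2_scores) - mean(cnv$scores[1:40, chr2])), 0.08)
})

test_that("reference-expression cutoff drops silent genes", {
  b <- cnv_toy()
  # silence one gene in the reference
  m <- as.matrix(b$counts)
  m[1:40, "g020"] <- 0
  b2 <- cell_bundle(m, b$cells, b$genes)
  cnv <- cnv_smooth(b2, 1:40, window = 5, cutoff = 0.1)
  expect_false("g020" %in% cnv$genes$symbol)
  expect_equal(ncol(cnv$scores), nrow(cnv$genes))
})

test_that("malignancy_score is the mean absolute deviation", {
  m <- rbind(a = c(0.2, -0.2, 0), b = c(0, 0, 0), d = c(1, 1, -1))
  sc <- malignancy_score(m)
  expect_equal(unname(sc$malignancy_score), c(0.4 / 3, 0, 1))
  expect_identical(sc$cell_id, c("a", "b", "d"))
  # ratio-convention input is converted to deviations first
  rat <- structure(list(scores = m + 1, convention = "ratio"),
                   class = "cnv_matrix")
  expect_equal(unname(malignancy_score(rat)$malignancy_score),
               unname(sc$malignancy_score))
})

test_that("classify_malignant applies per-dataset control intervals", {
  set.seed(7)
  n <- 300
  scores <- runif(n, 0, 1)
  dataset <- rep(c("dsA", "dsB"), each = n / 2)
  epi <- rep(c(FALSE, TRUE), n / 2)
  # two obvious malignant epithelial outliers, one per dataset
  scores[which(epi & dataset == "dsA")[1]] <- 50
  scores[which(epi & dataset == "dsB")[1]] <- 50
  res <- classify_malignant(scores, dataset, epi, n_controls = 50, seed = 1)

  expect_equal(nrow(res$intervals), 2)
  expect_true(all(res$intervals$n_controls == 50))
  for (i in 1:2) {
    ds <- res$intervals$dataset[i]
    ctrl_scores <- scores[match(res$intervals$control_ids[[i]],
                                res$cells$cell_id)]
    expect_equal(c(res$intervals$low[i], res$intervals$high[i]),
                 unname(quantile(ctrl_scores, c(0.05, 0.95))))
  }
  # the planted outliers are flagged; non-epithelial cells stay NA
  expect_true(all(res$cells$malignant[res$cells$score == 50]))
  expect_true(all(is.na(res$cells$malignant[!epi])))

  w1 <- capture_warnings(classify_malignant(scores, dataset, epi,
                                            n_controls = 1000))
  expect_match(w1, "using all", all = TRUE)
  w2 <- capture_warnings(classify_malignant(scores[epi], dataset[epi],
                                            rep(TRUE, sum(epi))))
  expect_match(w2, "no non-epithelial", all = TRUE)
})
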