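#' Build a per-sample cell-type composition table
#'
#' Tallies cells per sample x cell type and carries the per-sample covariates
#' (grade, subtype, age, batch where present) needed by the diversity and
#' differential-abundance stages.
#'
#' @param cells tibble of per-cell metadata with `cell_type` plus the sample
#'   key and any covariates.
#' @param sample_col column identifying the sample/donor (default `donor`).
#' @param type_col column holding the cell-type label.
#' @return a `composition_table`: list with `counts` (samples x types integer
#'   matrix) and `samples` (tibble: `sample_id` + covariates).
#' @export
composition_table <- function(cells, sample_col = "donor", type_col = "cell_type") {
  stopifnot(all(c(sample_col, type_col) %in% names(cells)))
  tab <- table(cells[[sample_col]], cells[[type_col]])
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  covars <- intersect(c("grade", "subtype", "age", "batch"), names(cells))
  samples <- cells %>%
    group_by(sample_id = .data[[sample_col]]) %>%
    summarise(across(dplyr::all_of(covars), ~ .x[1]), .groups = "drop")
  samples <- samples[match(rownames(counts), samples$sample_id), ]
  structure(list(counts = counts, samples = samples), class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d samples x %d cell types\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Cell-type diversity score (CTDS)
#'
#' Per sample (and compartment, when a compartment map is given), the
#' Shannon entropy of cell-type proportions normalized by `ln(K)` over the
#' compartment's type universe: 1 when all K types are equally represented,
#' 0 when a single type dominates. Small-sample bias is reduced with the
#' Miller-Madow correction `(K_observed - 1) / (2 n)` before normalization,
#' and the score is clipped to `[0, 1]`, so samples of different sizes are
#' comparable. Compartments with a single-type universe score 0 by
#' convention and are flagged.
#'
#' @param table a `composition_table`.
#' @param compartment_map optional named character vector mapping cell types
#'   to compartments; when `NULL` all types form one `"all"` compartment.
#' @return tibble: `sample_id`, `compartment`, `n_cells`, `k_universe`,
#'   `ctds`, `degenerate` flag, plus the sample covariates.
#' @export
ctds <- function(table, compartment_map = NULL) {
  stopifnot(inherits(table, "composition_table"))
  types <- colnames(table$counts)
  if (is.null(compartment_map)) {
    compartment_map <- setNames(rep("all", length(types)), types)
  }
  missing_types <- setdiff(types, names(compartment_map))
  if (length(missing_types) > 0) {
    abort(sprintf("compartment_map lacks types: %s",
                  paste(missing_types, collapse = ", ")))
  }
  out <- list()
  for (cp in unique(compartment_map[types])) {
    cp_types <- types[compartment_map[types] == cp]
    k <- length(cp_types)
    sub <- table$counts[, cp_types, drop = FALSE]
    n <- rowSums(sub)
    score <- vapply(seq_len(nrow(sub)), function(i) {
      if (n[i] == 0) return(NA_real_)
      if (k == 1) return(0)
      p <- sub[i, ] / n[i]
      h <- -sum(p[p > 0] * log(p[p > 0]))
      h_mm <- h + (sum(p > 0) - 1) / (2 * n[i])
      min(1, max(0, h_mm / log(k)))
    }, numeric(1))
    out[[length(out) + 1]] <- tibble::tibble(
      sample_id = rownames(sub), compartment = cp, n_cells = as.integer(n),
      k_universe = k, ctds = score, degenerate = k == 1)
  }
  bind_rows(out) %>% left_join(table$samples, by = "sample_id")
}

#' Centered log-ratio transform of composition counts
#'
#' Adds a pseudocount of 0.5 to each count, converts to proportions, and
#' centers the log proportions per sample so each row sums to zero exactly.
#'
#' @param counts samples x types count matrix.
#' @return samples x types CLR matrix.
#' @export
clr_transform <- function(counts) {
  p <- (counts + 0.5) / rowSums(counts + 0.5)
  lp <- log(p)
  sweep(lp, 1, rowMeans(lp), `-`)
}

#' Covariate-adjusted differential abundance
#'
#' Tests each cell type's CLR-transformed proportion against a phenotype
#' contrast with the remaining covariates (and batch, as fixed-effect
#' blocks) adjusted for. The grade contrast is dichotomized high (grade 3)
#' vs low (grades 1-2); a categorical contrast tests the given level against
#' the rest. Per type: coefficient, Wald 95% CI, p, BH-adjusted q, and the
#' direction (enriched/depleted with the contrast).
#'
#' @param table a `composition_table` with >= 10 samples; samples with
#'   missing modeled covariates are dropped.
#' @param contrast covariate to test: `"grade"` (default), `"age"`, or a
#'   categorical column with `contrast_level` set.
#' @param contrast_level for a categorical contrast, the level tested
#'   against the rest.
#' @param covariates additional adjustment covariates; defaults to all of
#'   grade/subtype/age/batch present except the contrast itself.
#' @return a `da_result`: tibble with `cell_type`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `q`, `direction`.
#' @export
differential_abundance <- function(table, contrast = "grade",
                                   contrast_level = NULL, covariates = NULL) {
  stopifnot(inherits(table, "composition_table"))
  samples <- table$samples
  counts <- table$counts
  if (!contrast %in% names(samples)) abort(sprintf("contrast `%s` not in covariates", contrast))

  absent <- colSums(counts) == 0
  if (any(absent)) {
    warn(sprintf("cell type(s) absent from all samples dropped: %s",
                 paste(colnames(counts)[absent], collapse = ", ")))
    counts <- counts[, !absent, drop = FALSE]
  }
  if (is.null(covariates)) {
    covariates <- setdiff(intersect(c("grade", "subtype", "age", "batch"),
                                    names(samples)), contrast)
  }
  df <- samples
  if (contrast == "grade") {
    df$.contrast <- as.integer(df$grade == 3)  # high (3) vs low (1-2)
  } else if (is.numeric(df[[contrast]])) {
    df$.contrast <- df[[contrast]]
  } else {
    if (is.null(contrast_level)) {
      abort(sprintf("categorical contrast `%s` needs contrast_level", contrast))
    }
    df$.contrast <- as.integer(df[[contrast]] == contrast_level)
  }
  used <- c(".contrast", covariates)
  ok <- complete.cases(df[, used, drop = FALSE])
  df <- df[ok, , drop = FALSE]
  counts <- counts[ok, , drop = FALSE]
  if (nrow(df) < 10) abort("need >= 10 samples with complete covariates")
  if (length(unique(df$.contrast)) < 2) abort("contrast has < 2 observed levels")

  for (cv in covariates) if (!is.numeric(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  fml <- stats::as.formula(paste("y ~ .contrast",
                                 paste(c("", covariates), collapse = " + ")))
  y_mat <- clr_transform(counts)

  # fail loudly on aliased designs rather than returning a silent estimate
  X <- model.matrix(stats::as.formula(paste("~ .contrast",
                                            paste(c("", covariates), collapse = " + "))), df)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- lm(y_mat[, 1] ~ X - 1)
    aliased <- colnames(X)[is.na(coef(fit0))]
    abort(sprintf("rank-deficient design; aliased terms: %s",
                  paste(aliased, collapse = ", ")))
  }

  res <- purrr::map(colnames(counts), function(ct) {
    d <- df; d$y <- y_mat[, ct]
    fit <- lm(fml, data = d)
    sm <- summary(fit)$coefficients
    est <- sm[".contrast", "Estimate"]
    se <- sm[".contrast", "Std. Error"]
    tibble::tibble(cell_type = ct, estimate = est, se = se,
                   ci_low = est - qnorm(0.975) * se,
                   ci_high = est + qnorm(0.975) * se,
                   p = sm[".contrast", "Pr(>|t|)"])
  }) %>% bind_rows() %>%
    mutate(q = p.adjust(.data$p, "BH"),
           direction = ifelse(.data$estimate > 0, "enriched", "depleted"))
  class(res) <- c("da_result", class(res))
  res
}
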