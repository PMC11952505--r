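#' Cox proportional-hazards fit (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with
#' step-halving; Wald tests per coefficient. Convergence is declared when
#' the gradient norm falls below `tol` (default 1e-8), within `max_iter`
#' iterations. Monotone likelihood (perfect separation, drifting
#' coefficients) is flagged and the coefficient still reported with a
#' warning.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @param x covariate matrix or data.frame (samples x p), full rank.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton-Raphson iteration cap.
#' @return a `cox_fit`: list with `coefficients` tibble (`term`, `estimate`,
#'   `hr`, `se`, `z`, `p`), `loglik` (c(null, final)), `iterations`,
#'   `converged`, `monotone` flag, `n`, `n_events`.
#' @export
fit_cox <- function(time, event, x, tol = 1e-8, max_iter = 50) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  n <- length(time)
  stopifnot(nrow(x) == n, length(event) == n, all(time > 0))
  if (sum(event) == 0) abort("no events; cannot fit")
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) {
    bad <- colnames(x)[qx$pivot[seq(qx$rank + 1, ncol(x) + 1)] - 1]
    abort(sprintf("covariate matrix not full rank; aliased: %s",
                  paste(bad, collapse = ", ")))
  }
  p <- ncol(x)
  terms <- colnames(x) %||% paste0("x", seq_len(p))

  ord <- order(time)
  tt <- time[ord]; ee <- event[ord]; xx <- x[ord, , drop = FALSE]
  utimes <- unique(tt[ee == 1])

  loglik_grad_hess <- function(beta) {
    eta <- drop(xx %*% beta)
    w <- exp(eta)
    # cumulative risk-set sums from the largest time backwards
    rev_cs <- function(v) rev(cumsum(rev(v)))
    s0_at <- rev_cs(w)
    s1_at <- apply(xx * w, 2, function(col) rev_cs(col))
    ll <- 0; g <- numeric(p); h <- matrix(0, p, p)
    for (t in utimes) {
      at_risk_start <- match(TRUE, tt >= t)
      d_idx <- which(tt == t & ee == 1)
      d <- length(d_idx)
      s0 <- s0_at[at_risk_start]
      s1 <- s1_at[at_risk_start, ]
      risk <- at_risk_start:n
      s2 <- crossprod(xx[risk, , drop = FALSE] * w[risk], xx[risk, , drop = FALSE])
      ll <- ll + sum(eta[d_idx]) - d * log(s0)
      g <- g + colSums(xx[d_idx, , drop = FALSE]) - d * s1 / s0
      h <- h - d * (s2 / s0 - tcrossprod(s1 / s0))
    }
    list(ll = ll, g = g, h = h)
  }

  beta <- numeric(p)
  null_ll <- loglik_grad_hess(beta)$ll
  cur <- loglik_grad_hess(beta)
  converged <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- solve(cur$h, -cur$g)
    new_beta <- beta + step
    new <- loglik_grad_hess(new_beta)
    halvings <- 0
    while (new$ll < cur$ll && halvings < 10) {
      step <- step / 2
      new_beta <- beta + step
      new <- loglik_grad_hess(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta; cur <- new
    if (sqrt(sum(cur$g^2)) < tol) { converged <- TRUE; break }
  }
  monotone <- any(abs(beta) > 15)
  if (monotone) {
    warn("possible monotone likelihood (perfect separation); coefficients unreliable")
  }
  se <- sqrt(diag(solve(-cur$h)))
  z <- beta / se
  structure(list(
    coefficients = tibble::tibble(term = terms, estimate = unname(beta),
                                  hr = exp(unname(beta)), se = unname(se),
                                  z = unname(z),
                                  p = unname(2 * pnorm(-abs(z)))),
    loglik = c(null = null_ll, final = cur$ll),
    iterations = iter, converged = converged, monotone = monotone,
    n = n, n_events = sum(event)), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, loglik = %.3f (%s)\n",
              x$n, x$n_events, x$loglik["final"],
              if (x$converged) sprintf("converged in %d iter", x$iterations)
              else "NOT converged"))
  print(x$coefficients)
  invisible(x)
}

#' Fisher's method for combining independent p-values
#'
#' `X = -2 sum(log p)` referred to a chi-square with `2m` degrees of
#' freedom. Zero p-values are clipped to the smallest positive double with
#' a warning.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return tibble: `statistic`, `df`, `p_combined`.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warn("p-value of 0 clipped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  tibble::tibble(statistic = x, df = 2 * length(p),
                 p_combined = pchisq(x, df = 2 * length(p), lower.tail = FALSE))
}

#' Clade-level survival scan across bulk cohorts
#'
#' For every clade of the taxonomy (each child side of every internal node),
#' the clade's up-signature genes, an inflammation set and a proliferation
#' set are projected onto each cohort with [ssgsea_project()]; a Cox model
#' `time ~ clade score + age + inflammation + proliferation` is fitted with
#' z-standardized scores (hazard ratios are per SD), the clade-score
#' p-values are BH-adjusted within each cohort, and cohorts are combined
#' per clade by Fisher's method. Clades whose signature has no cohort genes
#' are skipped and recorded.
#'
#' @param taxonomy a `cluster_taxonomy`.
#' @param signatures the tibble from [node_signatures()].
#' @param cohorts named list of `survival_cohort`s.
#' @param inflammation,proliferation gene-symbol vectors for the confounder
#'   scores.
#' @param q_cutoff significance cutoff used for the `call` column
#'   (advantage = HR < 1 at q < cutoff, disadvantage = HR > 1).
#' @return list: `results` (tibble per clade x cohort: `node_id`, `clade`,
#'   `cohort`, `n_genes`, `coef`, `hr`, `se`, `p`, `q`, `call`), `combined`
#'   (per clade: Fisher `statistic`, `df`, `p_combined`, `concordant_hr`),
#'   and `skipped` (clades without cohort genes).
#' @export
node_survival_scan <- function(taxonomy, signatures, cohorts,
                               inflammation, proliferation, q_cutoff = 0.05) {
  stopifnot(length(names(cohorts)) == length(cohorts))
  clades <- signatures %>%
    group_by(.data$node_id, clade = .data$direction) %>%
    summarise(genes = list(.data$gene), .groups = "drop")
  if (nrow(clades) == 0) abort("no clade signatures supplied")
  res <- list(); skipped <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    for (i in seq_len(nrow(clades))) {
      sig <- intersect(clades$genes[[i]], colnames(co$expression))
      if (length(sig) == 0) {
        skipped[[length(skipped) + 1]] <- tibble::tibble(
          node_id = clades$node_id[i], clade = clades$clade[i], cohort = cn)
        next
      }
      sets <- list(clade = sig, inflam = inflammation, prolif = proliferation)
      sc <- ssgsea_project(co$expression, sets)
      z <- scale(as.matrix(sc[, c("clade", "inflam", "prolif")]))
      xm <- cbind(clade = z[, "clade"], age = co$samples$age,
                  inflam = z[, "inflam"], prolif = z[, "prolif"])
      fit <- fit_cox(co$samples$time, co$samples$event, xm)
      cf <- fit$coefficients[fit$coefficients$term == "clade", ]
      res[[length(res) + 1]] <- tibble::tibble(
        node_id = clades$node_id[i], clade = clades$clade[i], cohort = cn,
        n_genes = length(sig), coef = cf$estimate, hr = cf$hr, se = cf$se,
        p = cf$p)
    }
  }
  results <- bind_rows(res) %>%
    group_by(.data$cohort) %>%
    mutate(q = p.adjust(.data$p, "BH")) %>%
    ungroup() %>%
    mutate(call = dplyr::case_when(
      .data$q < q_cutoff & .data$hr < 1 ~ "advantage",
      .data$q < q_cutoff & .data$hr > 1 ~ "disadvantage",
      TRUE ~ "ns"))
  combined <- results %>%
    group_by(.data$node_id, .data$clade) %>%
    summarise(fisher_combine(.data$p),
              concordant_hr = length(unique(sign(log(.data$hr)))) == 1,
              .groups = "drop")
  list(results = results, combined = combined, skipped = bind_rows(skipped))
}
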