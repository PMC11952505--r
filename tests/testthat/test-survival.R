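test_that("fit_cox matches a grid-search Breslow partial-likelihood oracle", {
  time <- c(2, 5, 5, 7, 9, 12, 14, 20)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- matrix(c(0.5, -1.2, 0.3, 1.8, -0.7, 0.2, 1.1, -0.4), ncol = 1,
              dimnames = list(NULL, "z"))

  breslow_ll <- function(beta) {
    eta <- x[, 1] * beta
    ll <- 0
    for (t in unique(time[event == 1])) {
      d <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_oracle <- grid[which.max(vapply(grid, breslow_ll, numeric(1)))]

  fit <- fit_cox(time, event, x)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate, beta_oracle, tolerance = 1e-3)
  expect_equal(unname(fit$loglik["final"]),
               breslow_ll(fit$coefficients$estimate), tolerance = 1e-10)
  expect_equal(unname(fit$loglik["null"]), breslow_ll(0), tolerance = 1e-10)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$estimate))
})

test_that("fit_cox matches survival::coxph with Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(1)
  n <- 150
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  time <- round(rexp(n, 0.05 * exp(0.6 * x[, "a"] - 0.4 * x[, "b"])), 0) + 1
  event <- rbinom(n, 1, 0.8)
  fit <- fit_cox(time, event, x)
  ref <- survival::coxph(survival::Surv(time, event) ~ a + b,
                         data = data.frame(time, event, x),
                         ties = "breslow")
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  expect_equal(unname(fit$loglik["final"]), ref$loglik[2], tolerance = 1e-7)
})

test_that("fit_cox recovers a planted beta = 0.7", {
  est <- vapply(1:20, function(s) {
    co <- simulate_bulk_cohort(500, "SIG", beta = 0.7, seed = s, n_genes = 1)
    fit <- fit_cox(co$samples$time, co$samples$event,
                   cbind(activity = co$samples$activity))
    fit$coefficients$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.05)
})

test_that("fit_cox flags degeneracies", {
  time <- c(1, 2, 3, 4, 5, 6)
  expect_error(fit_cox(time, rep(0, 6), matrix(rnorm(6))), "no events")
  x2 <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(fit_cox(time, rep(1, 6), x2), "aliased.*b")
  # perfectly separated covariate drifts: monotone-likelihood warning
  xs <- matrix(c(5, 4, 3, 2, 1, 0), dimnames = list(NULL, "sep"))
  expect_warning(fit <- fit_cox(time, rep(1, 6), xs), "monotone")
  expect_true(fit$monotone)
})

test_that("tidy and glance expose broom-style Cox output", {
  co <- simulate_bulk_cohort(100, "SIG", beta = 0.5, seed = 2, n_genes = 1)
  fit <- fit_cox(co$samples$time, co$samples$event,
                 cbind(activity = co$samples$activity, age = co$samples$age))
  td <- tidy(fit, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "hr", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(td$conf.high - td$estimate, qnorm(0.975) * td$std.error)
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_true(gl$converged)
})

test_that("fisher_combine matches its closed forms", {
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$statistic, -2 * (log(0.05) + log(0.05)))
  expect_equal(res$statistic, 11.98293, tolerance = 1e-5)
  expect_equal(res$df, 4)
  expect_equal(res$p_combined, pchisq(11.98293, 4, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res$p_combined, 0.01747, tolerance = 1e-3)

  # single p is returned (almost) unchanged: -2 log p ~ chisq_2
  expect_equal(fisher_combine(0.2)$p_combined, 0.2, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1))$statistic, 0)
  expect_warning(res0 <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(res0$p_combined > 0)
  expect_error(fisher_combine(c(0.5, 1.2)))
})

test_that("node_survival_scan finds a planted hazardous clade", {
  sig_genes <- sprintf("HAZ%02d", 1:15)
  cohorts <- list(
    cohortA = simulate_bulk_cohort(250, sig_genes, beta = 0.8, seed = 3,
                                   n_genes = 120),
    cohortB = simulate_bulk_cohort(250, sig_genes, beta = 0.8, seed = 4,
                                   n_genes = 120))
  signatures <- dplyr::bind_rows(
    tibble::tibble(node_id = 1L, gene = sig_genes, z = 5, q = 1e-4,
                   direction = "left"),
    tibble::tibble(node_id = 1L, gene = sprintf("BGENE%04d", 1:15), z = 5,
                   q = 1e-4, direction = "right"))
  inflam <- sprintf("BGENE%04d", 20:29)
  prolif <- sprintf("BGENE%04d", 30:39)
  scan <- node_survival_scan(taxonomy = NULL, signatures, cohorts,
                             inflam, prolif)

  left <- scan$results[scan$results$clade == "left", ]
  expect_equal(nrow(left), 2)
  expect_true(all(left$hr > 1))
  expect_true(all(left$call == "disadvantage"))
  comb <- scan$combined[scan$combined$clade == "left", ]
  expect_lt(comb$p_combined, 1e-6)
  expect_true(comb$concordant_hr)
  # q values are BH within cohort
  for (cn in names(cohorts)) {
    sub <- scan$results[scan$results$cohort == cn, ]
    expect_equal(sub$q, p.adjust(sub$p, "BH"))
  }
  expect_equal(nrow(scan$skipped), 0)
})

test_that("node_survival_scan records clades without measurable genes", {
  co <- list(c1 = simulate_bulk_cohort(60, "SIG", beta = 0, seed = 5,
                                       n_genes = 50))
  signatures <- dplyr::bind_rows(
    tibble::tibble(node_id = 1L, gene = "SIG", z = 3, q = 0.01,
                   direction = "left"),
    tibble::tibble(node_id = 1L, gene = "ABSENT", z = 3, q = 0.01,
                   direction = "right"))
  scan <- node_survival_scan(NULL, signatures, co, "BGENE0001", "BGENE0002")
  expect_equal(nrow(scan$skipped), 1)
  expect_equal(scan$skipped$clade, "right")
  expect_equal(nrow(scan$results), 1)
})

test_that("Benjamini-Hochberg worked vector behaves as stated", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})
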