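#' Tidy a Cox fit
#'
#' @param x a `cox_fit` from [fit_cox()].
#' @param conf.int add Wald confidence bounds.
#' @param conf.level confidence level.
#' @param ... unused.
#' @return tibble with one row per term: `term`, `estimate` (log hazard),
#'   `hr`, `std.error`, `statistic`, `p.value` (+ `conf.low`/`conf.high`).
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$coefficients %>%
    rename(std.error = "se", statistic = "z", p.value = "p")
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out <- out %>% mutate(conf.low = .data$estimate - zq * .data$std.error,
                          conf.high = .data$estimate + zq * .data$std.error)
  }
  out
}

#' @rdname tidy.cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 logLik_null = unname(x$loglik["null"]),
                 logLik = unname(x$loglik["final"]),
                 iterations = x$iterations, converged = x$converged,
                 monotone = x$monotone)
}

#' Tidy a differential-abundance result
#'
#' @param x a `da_result` from [differential_abundance()].
#' @param ... unused.
#' @return tibble with broom-style column names.
#' @method tidy da_result
#' @export
tidy.da_result <- function(x, ...) {
  tibble::as_tibble(x) %>%
    rename(term = "cell_type", std.error = "se", p.value = "p",
           conf.low = "ci_low", conf.high = "ci_high")
}

#' Tidy a cluster taxonomy
#'
#' @param x a `cluster_taxonomy`.
#' @param ... unused.
#' @return the node table with member clusters collapsed to a string.
#' @method tidy cluster_taxonomy
#' @export
tidy.cluster_taxonomy <- function(x, ...) {
  x$nodes %>%
    mutate(clusters = purrr::map_chr(.data$clusters,
                                     ~ paste(.x, collapse = ",")))
}
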