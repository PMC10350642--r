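# broom-style tidiers for the package's fitted/summary objects.

#' @rdname paired_t_test
#' @param x A `paired_t` object.
#' @param ... Unused.
#' @export
tidy.paired_t <- function(x, ...) {
  tibble(estimate = x$mean_diff, statistic = x$t, df = x$df,
         p.value = x$p, method = x$method)
}

#' @rdname paired_t_test
#' @export
glance.paired_t <- function(x, ...) {
  tibble(statistic = x$t, df = x$df, p.value = x$p, n = x$n)
}

#' @rdname cohen_kappa
#' @param x A `kappa_result` object.
#' @param ... Unused.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, p_o = x$p_o, p_e = x$p_e, band = x$band)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary` object.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$table
}

#' @rdname summarize_cohort
#' @export
glance.cohort_summary <- function(x, ...) {
  x$table[x$table$stratum == "all", ]
}
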