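RATING_LEVELS <- c("early_better", "same", "delayed_better")

#' Contingency table from two observers' ratings
#'
#' @param ratings Tibble/data frame with columns `obs1`, `obs2`, each drawn
#'   from `early_better` / `same` / `delayed_better`.
#' @return A 3x3 integer matrix (rows = observer 1, columns = observer 2).
#' @export
ratings_table <- function(ratings) {
  stopifnot(all(c("obs1", "obs2") %in% names(ratings)))
  bad <- setdiff(unique(c(as.character(ratings$obs1), as.character(ratings$obs2))),
                 RATING_LEVELS)
  if (length(bad)) {
    stop_dtpet(paste0("Unknown rating categories: ", paste(bad, collapse = ", ")),
               "dtpet_domain_error")
  }
  table(factor(ratings$obs1, RATING_LEVELS), factor(ratings$obs2, RATING_LEVELS))
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement on a square contingency table:
#' `p_o = trace/total`, `p_e = sum(row_i * col_i)/total^2`,
#' `kappa = (p_o - p_e)/(1 - p_e)`. The qualitative agreement band follows
#' the conventional scale (see [kappa_band()]).
#'
#' @param x A square matrix/table of counts, or a data frame of two rating
#'   columns `obs1`, `obs2` (converted via [ratings_table()]).
#' @return A `kappa_result` object (`kappa`, `p_o`, `p_e`, `band`, `table`).
#' @examples
#' cohen_kappa(matrix(c(20, 10, 0, 5, 15, 0, 0, 0, 0), 3, 3))
#' @export
cohen_kappa <- function(x) {
  if (is.data.frame(x)) x <- ratings_table(x)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop_dtpet("Contingency table must be square.", "dtpet_domain_error")
  }
  if (any(x < 0)) stop_dtpet("Counts must be non-negative.", "dtpet_domain_error")
  total <- sum(x)
  if (total <= 0) stop_dtpet("Contingency table must have a positive total.",
                             "dtpet_domain_error")
  p_o <- sum(diag(x)) / total
  p_e <- sum(rowSums(x) * colSums(x)) / total^2
  if (p_e >= 1) {
    stop_dtpet("Kappa undefined: expected agreement p_e = 1 (all mass in one category).",
               "dtpet_degenerate_error")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e,
                 band = kappa_band(kappa), table = x),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4g (%s); p_o = %.4g, p_e = %.4g\n",
              x$kappa, x$band, x$p_o, x$p_e))
  invisible(x)
}

#' Qualitative agreement band for a kappa value
#'
#' Conventional scale: poor < 0.20, fair 0.20-0.40, moderate 0.40-0.60,
#' good 0.60-0.80, very good 0.80-1.00. The published band endpoints overlap,
#' so this package fixes the convention as half-open intervals `[lo, hi)` with
#' very good closed at 1.00; negative kappa is poor.
#'
#' @param kappa Kappa value(s), each `<= 1`.
#' @return Character band label(s).
#' @examples
#' kappa_band(c(0.71, 0.40, 1))
#' @export
kappa_band <- function(kappa) {
  if (any(kappa > 1)) stop_dtpet("kappa cannot exceed 1.", "dtpet_domain_error")
  cut(kappa,
      breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, 1.00),
      labels = c("poor consistency", "fair agreement", "moderate agreement",
                 "good agreement", "very good agreement"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

#' Simulate two blinded observers rating dual-time-point image pairs
#'
#' A synthetic stand-in for visual comparison by two independent readers:
#' each observer perceives the patient's delta-AI with additive Gaussian
#' perception noise and rates the delayed image better when the perceived
#' change exceeds `threshold`, the early image better below `-threshold`, and
#' the two the same in between.
#'
#' @param records AI record tibble (needs `patient_id`, `dai`).
#' @param noise_sd Perception noise standard deviation (AI units, `>= 0`).
#' @param threshold Same-band half-width (AI units, `> 0`).
#' @param seed Optional seed (caller's RNG state restored).
#' @return A tibble `patient_id`, `obs1`, `obs2` with ratings from
#'   `early_better` / `same` / `delayed_better`.
#' @export
simulate_observers <- function(records, noise_sd = 1.5, threshold = 1, seed = NULL) {
  stopifnot(all(c("patient_id", "dai") %in% names(records)))
  if (noise_sd < 0) stop_dtpet("noise_sd must be >= 0.", "dtpet_domain_error")
  if (threshold <= 0) stop_dtpet("threshold must be > 0.", "dtpet_domain_error")
  rate <- function(perceived) {
    ifelse(perceived > threshold, "delayed_better",
           ifelse(perceived < -threshold, "early_better", "same"))
  }
  n <- nrow(records)
  draws <- with_seed_(seed, matrix(rnorm(2 * n, 0, max(noise_sd, 0)), ncol = 2))
  tibble(
    patient_id = records$patient_id,
    obs1 = factor(rate(records$dai + draws[, 1]), RATING_LEVELS),
    obs2 = factor(rate(records$dai + draws[, 2]), RATING_LEVELS)
  )
}
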