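#' Asymmetry index between the EZ and its contralateral mirror region
#'
#' \deqn{AI = 100 \times 2 \times
#'   \frac{SUV_{contra} - SUV_{EZ}}{SUV_{contra} + SUV_{EZ}}}
#' Positive AI means the epileptogenic-zone side is hypometabolic relative to
#' its mirror. AI is scale-invariant (normalization constants cancel) and
#' antisymmetric in its arguments; values lie in (-200, 200).
#'
#' @param suv_ez SUVmean of the epileptogenic-zone region (`>= 0`).
#' @param suv_contra SUVmean of the contralateral mirror region (`>= 0`).
#' @return The asymmetry index (vectorized).
#' @examples
#' asymmetry_index(5.21, 5.94)
#' @export
asymmetry_index <- function(suv_ez, suv_contra) {
  if (any(suv_ez < 0) || any(suv_contra < 0)) {
    stop_dtpet("SUVmeans must be non-negative.", "dtpet_domain_error")
  }
  if (any(suv_ez + suv_contra <= 0)) {
    stop_dtpet("suv_ez + suv_contra must be positive.", "dtpet_domain_error")
  }
  100 * 2 * (suv_contra - suv_ez) / (suv_contra + suv_ez)
}

#' Change in asymmetry between the delayed and early scans
#'
#' `delta_ai = AI2 - AI1`; positive when the asymmetry grows with time.
#'
#' @param ai1 Early-scan asymmetry index.
#' @param ai2 Delayed-scan asymmetry index.
#' @return `ai2 - ai1` (vectorized).
#' @export
delta_ai <- function(ai1, ai2) {
  if (!all(is.finite(ai1)) || !all(is.finite(ai2))) {
    stop_dtpet("AI values must be finite.", "dtpet_domain_error")
  }
  ai2 - ai1
}

#' Diagnostic banding of an asymmetry index
#'
#' AI below 10 is sub-threshold, 10-15 (closed interval) is suggestive of an
#' epileptogenic zone, and strictly above 15 is diagnostic. The interval
#' endpoints follow the conventional reading bands; boundary membership
#' (closed at both 10 and 15) is this package's documented convention.
#'
#' @param ai Asymmetry index value(s).
#' @return A factor with levels `sub_threshold`, `suggestive`, `diagnostic`.
#' @examples
#' classify_ai(c(0, 14.92, 23.64))
#' @export
classify_ai <- function(ai) {
  if (!all(is.finite(ai))) stop_dtpet("AI values must be finite.", "dtpet_domain_error")
  out <- ifelse(ai > 15, "diagnostic", ifelse(ai >= 10, "suggestive", "sub_threshold"))
  factor(out, levels = c("sub_threshold", "suggestive", "diagnostic"))
}

#' Paired t-test for dual-time-point comparisons
#'
#' Classical paired t on the differences `x_delayed - x_early`:
#' `t = mean(d) / (sd(d)/sqrt(n))` with sample (n-1) standard deviation,
#' `df = n - 1`, and the two-sided p-value obtained from the t distribution
#' through the regularized incomplete beta function
#' `p = I_{df/(df+t^2)}(df/2, 1/2)`.
#'
#' @param x_early,x_delayed Equal-length numeric vectors, `n >= 2`.
#' @return A `paired_t` object (fields `t`, `df`, `p`, `mean_diff`, `sd_diff`,
#'   `n`); see [tidy()] / [glance()].
#' @examples
#' paired_t_test(c(1, 2, 3, 4), c(2, 3, 5, 5))
#' @export
paired_t_test <- function(x_early, x_delayed) {
  if (length(x_early) != length(x_delayed)) {
    stop_dtpet("x_early and x_delayed must have equal length.", "dtpet_domain_error")
  }
  n <- length(x_early)
  if (n < 2) stop_dtpet("Paired t-test needs n >= 2 pairs.", "dtpet_domain_error")
  d <- x_delayed - x_early
  m <- mean(d)
  s <- sd(d)
  df <- n - 1
  if (s == 0) {
    if (m != 0) {
      stop_dtpet(paste0(
        "Degenerate paired t-test: all differences identical (", format(m),
        ") with zero variance."), "dtpet_degenerate_error")
    }
    tstat <- 0; p <- 1
  } else {
    tstat <- m / (s / sqrt(n))
    p <- pbeta(df / (df + tstat^2), df / 2, 0.5)
  }
  structure(list(t = tstat, df = df, p = p, mean_diff = m, sd_diff = s, n = n,
                 method = "paired t-test (two-sided)"),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4g, df = %d, p = %.4g (n = %d, mean diff = %.4g)\n",
              x$t, as.integer(x$df), format_p_(x$p), as.integer(x$n), x$mean_diff))
  invisible(x)
}

# p-values are reported to 4 significant figures; values below 1e-3 are
# floored for display only (never stored as literal zero).
format_p_ <- function(p) signif(p, 4)

#' Assemble per-patient AI records from a quantified cohort
#'
#' Joins the early/delayed EZ and contralateral SUVmeans patient by patient,
#' computes AI1, AI2, delta-AI and the diagnostic band at each time point, and
#' attaches MRI status and EZ side. Patients whose PET lateralization opposes
#' the designated EZ side simply produce negative AI and are retained.
#'
#' @param cohort A `pet_cohort`, or a long SUVmean table as returned by
#'   [quantify_cohort()] (in which case `scans` must be supplied).
#' @param scans Per-patient metadata tibble (`patient_id`, `ez_label`,
#'   `mri_status`, `ez_side`, ...); taken from the cohort when omitted.
#' @return A tibble with one row per patient: SUVmean pairs at both time
#'   points, `ai1`, `ai2`, `dai`, `band1`, `band2`, `mri_status`, `ez_side`.
#' @export
ai_records <- function(cohort, scans = NULL) {
  if (inherits(cohort, "pet_cohort")) {
    regional <- cohort$regional
    scans <- cohort$scans
    pairs <- cohort$labels$pairs
  } else {
    regional <- cohort
    if (is.null(scans)) {
      stop_dtpet("scans metadata must be supplied with a bare SUVmean table.",
                 "dtpet_config_error")
    }
    pairs <- NULL
  }
  meta <- scans[, intersect(c("patient_id", "ez_label", "mri_status", "ez_side"),
                            names(scans))]
  long <- dplyr::left_join(regional, meta, by = "patient_id")
  contra_of <- function(lab) {
    if (!is.null(pairs)) {
      ifelse(lab %in% pairs$lh_label,
             pairs$rh_label[match(lab, pairs$lh_label)],
             pairs$lh_label[match(lab, pairs$rh_label)])
    } else {
      # fall back on the lh/rh label offset convention
      ifelse(lab > RH_OFFSET, lab - RH_OFFSET, lab + RH_OFFSET)
    }
  }
  ez_rows <- dplyr::filter(long, .data$label == .data$ez_label)
  co_rows <- dplyr::filter(long, .data$label == contra_of(.data$ez_label))
  ez <- dplyr::select(ez_rows, "patient_id", "timepoint", "mri_status",
                      "ez_side", suv_ez = "suvmean")
  co <- dplyr::select(co_rows, "patient_id", "timepoint", suv_contra = "suvmean")
  wide <- dplyr::inner_join(ez, co, by = c("patient_id", "timepoint")) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("suv_ez", "suv_contra"))
  out <- dplyr::mutate(
    wide,
    ai1 = asymmetry_index(.data$suv_ez_early, .data$suv_contra_early),
    ai2 = asymmetry_index(.data$suv_ez_delayed, .data$suv_contra_delayed),
    dai = delta_ai(.data$ai1, .data$ai2),
    band1 = classify_ai(.data$ai1),
    band2 = classify_ai(.data$ai2)
  )
  dplyr::relocate(out, "patient_id", "suv_ez_early", "suv_contra_early",
                  "suv_ez_delayed", "suv_contra_delayed", "ai1", "ai2", "dai",
                  "band1", "band2", "mri_status", "ez_side")
}

#' Cohort-level summary of AI1, AI2 and delta-AI
#'
#' Reproduces the standard dual-time-point summary table: mean and sample SD
#' of AI1, AI2 and delta-AI overall and stratified by MRI status, counts and
#' percentages of patients with increased / decreased / unchanged AI at the
#' delayed time point (ties are their own category, never folded in), and the
#' paired t-test of AI2 against AI1 per stratum. Strata with fewer than two
#' patients get `NA` statistics flagged in `note`, never fabricated values; a
#' degenerate zero-variance paired test is surfaced as a warning with `NA`
#' t and p.
#'
#' @param records AI record tibble from [ai_records()] (needs columns `ai1`,
#'   `ai2`, `dai`, `mri_status`).
#' @return A `cohort_summary` object; `tidy()` returns the per-stratum table
#'   (rows `all`, `mri_positive`, `mri_negative`), `glance()` the overall row.
#' @export
summarize_cohort <- function(records) {
  req <- c("ai1", "ai2", "dai", "mri_status")
  if (!all(req %in% names(records))) {
    stop_dtpet(paste0("records must contain columns: ", paste(req, collapse = ", ")),
               "dtpet_config_error")
  }
  if (nrow(records) < 2) stop_dtpet("Need at least 2 records.", "dtpet_config_error")
  if (anyNA(records$mri_status)) {
    stop_dtpet("Every record needs an MRI status.", "dtpet_config_error")
  }
  strata <- list(
    all = records,
    mri_positive = records[records$mri_status == "positive", ],
    mri_negative = records[records$mri_status == "negative", ]
  )
  rows <- purrr::imap(strata, function(df, nm) {
    n <- nrow(df)
    if (n < 2) {
      return(tibble(
        stratum = nm, n = n,
        ai1_mean = if (n) mean(df$ai1) else NA_real_, ai1_sd = NA_real_,
        ai2_mean = if (n) mean(df$ai2) else NA_real_, ai2_sd = NA_real_,
        dai_mean = if (n) mean(df$dai) else NA_real_, dai_sd = NA_real_,
        n_increased = sum(df$dai > 0), n_decreased = sum(df$dai < 0),
        n_unchanged = sum(df$dai == 0),
        pct_increased = if (n) round(100 * sum(df$dai > 0) / n, 2) else NA_real_,
        pct_decreased = if (n) round(100 * sum(df$dai < 0) / n, 2) else NA_real_,
        t = NA_real_, df = NA_integer_, p = NA_real_,
        note = "fewer than 2 patients; test statistics unavailable"
      ))
    }
    tt <- tryCatch(paired_t_test(df$ai1, df$ai2), dtpet_degenerate_error = function(e) e)
    degen <- inherits(tt, "error")
    if (degen) {
      warn(sprintf("Stratum '%s': %s", nm, conditionMessage(tt)))
    }
    tibble(
      stratum = nm, n = n,
      ai1_mean = mean(df$ai1), ai1_sd = sd(df$ai1),
      ai2_mean = mean(df$ai2), ai2_sd = sd(df$ai2),
      dai_mean = mean(df$dai), dai_sd = sd(df$dai),
      n_increased = sum(df$dai > 0), n_decreased = sum(df$dai < 0),
      n_unchanged = sum(df$dai == 0),
      pct_increased = round(100 * sum(df$dai > 0) / n, 2),
      pct_decreased = round(100 * sum(df$dai < 0) / n, 2),
      t = if (degen) NA_real_ else tt$t,
      df = if (degen) NA_integer_ else as.integer(tt$df),
      p = if (degen) NA_real_ else tt$p,
      note = if (degen) "degenerate paired t (zero-variance differences)" else NA_character_
    )
  })
  structure(list(table = dplyr::bind_rows(rows), n = nrow(records)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Dual-time-point AI summary (n = %d)\n", x$n))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}
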