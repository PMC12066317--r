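#' Percent improvement rate
#'
#' `((pre - post) / pre) * 100`. Undefined (NA) when `pre == 0`; a
#' warning flags such entries. Values are returned at full precision;
#' round for display only.
#'
#' @param pre,post Numeric vectors of pre- and post-treatment scores.
#' @return Numeric vector of improvement rates in percent.
#' @export
improvement_rate <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  out <- (pre - post) / pre * 100
  zero <- !is.na(pre) & pre == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    warning("improvement rate undefined for ", sum(zero),
            " entr", if (sum(zero) == 1) "y" else "ies", " with pre == 0")
  }
  out
}

#' Normality gate for paired differences
#'
#' Shapiro-Wilk on the differences decides the paired test: p > alpha
#' selects the paired t-test, otherwise the Wilcoxon signed-rank test.
#' Constant differences (Shapiro-Wilk undefined) fall to the Wilcoxon
#' branch with a flag.
#'
#' @param differences Numeric vector (n >= 3).
#' @param alpha Gate level; default 0.05.
#' @return List with `test_used` (`"paired_t"` or
#'   `"wilcoxon_signed_rank"`), `shapiro_p` and `flag`.
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 3)
    stop("normality gate needs at least 3 differences")
  if (stats::sd(differences) == 0)
    return(list(test_used = "wilcoxon_signed_rank", shapiro_p = NA_real_,
                flag = "constant_differences"))
  sw <- stats::shapiro.test(differences)
  list(test_used = if (sw$p.value > alpha) "paired_t" else "wilcoxon_signed_rank",
       shapiro_p = sw$p.value, flag = "ok")
}

#' Paired pre/post test with normality gating
#'
#' Runs the test chosen by [normality_gate()]: a paired t-test, or the
#' Wilcoxon signed-rank test of [signed_rank_test()] (exact for small n,
#' tie-corrected normal approximation otherwise; the reported statistic
#' on that branch is the continuity/tie-corrected Z, signed like
#' pre - post). Summaries are mean (SD) on the t branch and
#' median (Q1, Q3) on the Wilcoxon branch, matching the usual
#' normality-dependent reporting convention.
#'
#' @param pre,post Aligned numeric vectors (n >= 3).
#' @param scale Scale name carried into the result.
#' @param alpha Normality-gate level.
#' @return List with `scale`, `n`, `statistic`, `p_value`, `test_used`,
#'   `summary_pre`, `summary_post`, `flag`.
#' @export
paired_change_test <- function(pre, post, scale = "", alpha = 0.05) {
  if (length(pre) != length(post)) stop("pre/post length mismatch")
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  d <- pre - post
  gate <- normality_gate(d, alpha)
  if (gate$test_used == "paired_t") {
    tt <- stats::t.test(pre, post, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
    fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  } else {
    sr <- signed_rank_test(d)
    stat <- sr$z; p <- sr$p_value
    fmt <- function(x) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
    }
  }
  list(scale = scale, n = length(d), statistic = stat, p_value = p,
       test_used = gate$test_used, summary_pre = fmt(pre),
       summary_post = fmt(post), flag = gate$flag)
}

#' Spearman correlations of active-contact coordinates with improvement
#'
#' Per-hemisphere join of contact coordinates to per-patient improvement
#' rates; Spearman rho and p for each axis x hemisphere x scale.
#'
#' @param coords Data frame from [active_contact_coordinates()].
#' @param clinical Clinical data frame.
#' @param scales Scales to correlate; default HAMA and HAMD.
#' @param measure `"improvement"` (default) or `"change"`.
#' @return Data frame with `scale`, `hemisphere`, `axis`, `n`, `rho`,
#'   `p_value`, `flag`.
#' @export
coordinate_outcome_correlations <- function(coords, clinical,
                                            scales = c("HAMA", "HAMD"),
                                            measure = "improvement") {
  rows <- list()
  for (sc in scales) {
    y_all <- clinical_outcome(clinical, sc, measure)
    for (h in unique(coords$hemisphere)) {
      cs <- coords[coords$hemisphere == h, ]
      y <- y_all[cs$patient_id]
      for (ax in c("x", "y", "z")) {
        r <- spearman_cor(cs[[ax]], y)
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, hemisphere = h, axis = ax, n = r$n, rho = r$rho,
          p_value = r$p_value, flag = r$flag, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlations of VTA-region overlaps with improvement
#'
#' @param overlap_table Data frame from [cohort_overlap_table()].
#' @param clinical Clinical data frame.
#' @param scales Scales to correlate.
#' @param measure `"improvement"` (default) or `"change"`.
#' @return Data frame with `scale`, `hemisphere`, `region_label`, `n`,
#'   `rho`, `p_value`, `flag`.
#' @export
overlap_outcome_correlations <- function(overlap_table, clinical,
                                         scales = c("HAMA", "HAMD"),
                                         measure = "improvement") {
  rows <- list()
  for (sc in scales) {
    y_all <- clinical_outcome(clinical, sc, measure)
    for (h in unique(overlap_table$hemisphere)) {
      for (reg in unique(overlap_table$region_label)) {
        ot <- overlap_table[overlap_table$hemisphere == h &
                              overlap_table$region_label == reg, ]
        r <- spearman_cor(ot$overlap_mm3, y_all[ot$patient_id])
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, hemisphere = h, region_label = reg, n = r$n,
          rho = r$rho, p_value = r$p_value, flag = r$flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Baseline/follow-up cohort summary table
#'
#' One row per clinical scale (normality-gated paired test, formatted
#' pre/post summaries, improvement rate of the medians) plus one row per
#' stimulation parameter (mean and SD across electrodes).
#'
#' @param cohort A `dbs_cohort`.
#' @return Data frame summarising the cohort.
#' @export
summarize_cohort <- function(cohort) {
  cl <- cohort$clinical
  scales <- c(updrs3 = "UPDRS-III", pdq39 = "PDQ-39", hama = "HAMA",
              hamd = "HAMD", ledd = "LEDD")
  rows <- lapply(names(scales), function(s) {
    pre <- cl[[paste0(s, "_pre")]]; post <- cl[[paste0(s, "_post")]]
    r <- paired_change_test(pre, post, scale = scales[[s]])
    data.frame(item = scales[[s]], type = "scale", n = r$n,
               pre = r$summary_pre, post = r$summary_post,
               statistic = round(r$statistic, 3),
               p_value = signif(r$p_value, 3), test_used = r$test_used,
               improvement_rate_of_medians =
                 round(improvement_rate(stats::median(pre), stats::median(post)), 2),
               stringsAsFactors = FALSE)
  })
  el <- cohort$electrodes
  pars <- c(amplitude_v = "Voltage (V)", frequency_hz = "Frequency (Hz)",
            pulse_width_us = "Pulse width (µs)")
  prow <- lapply(names(pars), function(p)
    data.frame(item = pars[[p]], type = "parameter", n = nrow(el),
               pre = NA_character_,
               post = sprintf("%.2f ± %.2f", mean(el[[p]]), stats::sd(el[[p]])),
               statistic = NA_real_, p_value = NA_real_,
               test_used = NA_character_,
               improvement_rate_of_medians = NA_real_,
               stringsAsFactors = FALSE))
  do.call(rbind, c(rows, prow))
}
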