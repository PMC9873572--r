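# Pre-specified predictor analyses: Oldham-corrected blood-pressure
# change and its correlation, the spironolactone binary predictor, and
# immunohistochemistry H-scores.

#' Oldham-corrected blood-pressure change
#'
#' Expresses a change as a percentage of the mean of the baseline and
#' post-treatment values: `100 * (post - baseline) / ((baseline + post)/2)`.
#' This removes the artifactual correlation between a change and its
#' common starting value (regression to the mean). Falls are negative.
#'
#' @param baseline,post Blood pressures (mmHg), positive.
#' @return Corrected change in percent, bounded in (-200, 200).
#' @export
oldham_corrected_change <- function(baseline, post) {
  if (any(is.na(baseline)) || any(is.na(post)) ||
      any(baseline <= 0) || any(post <= 0))
    stop("pressures must be positive")
  100 * (post - baseline) / ((baseline + post) / 2)
}

#' Correlation between spironolactone and post-surgical BP responses
#'
#' Pearson correlation between two vectors of Oldham-corrected changes
#' for the same patients (typically: systolic change after 4 weeks of
#' spironolactone vs change at 6 months post-adrenalectomy), with a
#' Fisher-z confidence interval and a p-value from the t-distributed
#' correlation test.
#'
#' @param spiro_change,surgery_change Paired corrected changes (%).
#' @param level Confidence coefficient.
#' @return List with `r`, `interval`, `p_value` and `n`.
#' @export
oldham_correlation <- function(spiro_change, surgery_change, level = 0.95) {
  ok <- !is.na(spiro_change) & !is.na(surgery_change)
  x <- spiro_change[ok]
  y <- surgery_change[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a corrected-change vector")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  list(r = unname(ct$estimate),
       interval = new_interval(ct$conf.int[1], ct$conf.int[2], level, "fisher-z"),
       p_value = ct$p.value, n = length(x))
}

#' Spironolactone response as a binary predictor of clinical success
#'
#' Cross-tabulates, among operated patients, systolic BP at or below the
#' cutoff after 4 weeks of spironolactone against complete clinical
#' success, returning the odds ratio with its Woolf interval and the
#' fraction of at-or-below-cutoff patients achieving at least partial
#' clinical success.
#'
#' @param cohort Graded and classified cohort data frame with a
#'   `spiro_sbp_4wk` column.
#' @param sbp_cutoff Cutoff in mmHg, default 135.
#' @param level Confidence coefficient.
#' @return List with the 2x2 `counts`, `odds_ratio` (see
#'   [odds_ratio_ci()]), `fraction_partial_or_complete_below_cutoff` and
#'   `n`.
#' @export
spiro_binary_predictor <- function(cohort, sbp_cutoff = 135, level = 0.95) {
  use <- cohort$management == "surgery" & !is.na(cohort$spiro_sbp_4wk) &
    !is.na(cohort$clinical_level)
  sub <- cohort[use, , drop = FALSE]
  if (!nrow(sub)) stop("no operated patients with spironolactone response data")
  low <- sub$spiro_sbp_4wk <= sbp_cutoff
  if (all(low) || !any(low))
    stop("degenerate margin: all patients fall on one side of the cutoff")
  complete <- sub$clinical_level == "complete"
  partial_plus <- sub$clinical_level %in% c("complete", "partial")
  counts <- c(a = sum(low & complete), b = sum(low & !complete),
              c = sum(!low & complete), d = sum(!low & !complete))
  list(counts = counts,
       odds_ratio = odds_ratio_ci(counts[["a"]], counts[["b"]],
                                  counts[["c"]], counts[["d"]], level),
       fraction_partial_or_complete_below_cutoff =
         sum(low & partial_plus) / sum(low),
       n = nrow(sub))
}

#' Immunohistochemistry H-score
#'
#' Semi-quantitative staining score
#' `1 x (% weak) + 2 x (% intermediate) + 3 x (% strong)`, ranging 0-300.
#'
#' @param pct_weak,pct_intermediate,pct_strong Percentages of cells
#'   staining at intensity 1+, 2+ and 3+ (each in \[0, 100\], summing to
#'   at most 100).
#' @return The H-score.
#' @examples
#' h_score(20, 30, 50)  # 230
#' @export
h_score <- function(pct_weak, pct_intermediate, pct_strong) {
  p <- c(pct_weak, pct_intermediate, pct_strong)
  if (any(is.na(p)) || any(p < 0) || any(p > 100))
    stop("percentages must lie in [0, 100]")
  if (any(pct_weak + pct_intermediate + pct_strong > 100 + 1e-9))
    stop("staining percentages sum to more than 100")
  1 * pct_weak + 2 * pct_intermediate + 3 * pct_strong
}
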