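# The primary analysis: per-patient accuracy scoring of the two tests,
# the paired 2x2 accuracy table per hierarchical endpoint, the
# Newcombe-Wilson score interval for the difference of paired proportions,
# exact McNemar superiority and margin-based non-inferiority tests, and
# sensitivity / false-positive-rate estimation.

#' Score one patient's accuracy point for each test
#'
#' A test is accurate (scores 1) if it recommended surgery (graded high)
#' and surgery achieved the endpoint, or if it did not indicate surgery
#' and surgery did not achieve the endpoint. Medically managed patients
#' are treated as true negatives: each test scores 1 unless it graded
#' high. Patients operated on clinical grounds with two intermediate
#' grades carry non-high grades for both tests and are scored by the same
#' rule (accurate only if surgery failed). Deferred patients are unscored.
#'
#' @param management "surgery", "medical" or "deferred".
#' @param mto_level,avs_level Grade levels ("high", "intermediate", "low",
#'   "failed").
#' @param endpoint_success Logical: did the patient achieve the endpoint
#'   limb (required for surgery patients, ignored otherwise).
#' @return Named integer vector `c(mto = 0/1, avs = 0/1)`; both `NA` for
#'   deferred (unscored) patients.
#' @export
score_patient <- function(management, mto_level, avs_level,
                          endpoint_success = NA) {
  if (management == "deferred")
    return(c(mto = NA_integer_, avs = NA_integer_))
  if (management == "medical")
    return(c(mto = as.integer(mto_level != "high"),
             avs = as.integer(avs_level != "high")))
  if (is.na(endpoint_success))
    stop("endpoint_success required for surgery patients")
  point <- function(level) {
    if (level == "high") as.integer(endpoint_success)
    else as.integer(!endpoint_success)
  }
  c(mto = point(mto_level), avs = point(avs_level))
}

#' Paired 2x2 accuracy table for one hierarchical endpoint
#'
#' Cross-classifies the per-patient accuracy points of the two tests among
#' operated patients with an evaluable endpoint. With
#' `exclude_clinical_indication = TRUE` the patients operated on clinical
#' grounds with two intermediate grades are dropped from the denominator
#' instead of being scored with two negative recommendations.
#'
#' @param cohort Graded and classified cohort data frame (see
#'   [grade_cohort()], [classify_cohort()]).
#' @param endpoint_limb One of "h1", "h2", "h3", "h4".
#' @param exclude_clinical_indication Denominator convention flag
#'   (default `FALSE`: keep those patients, scored negative by both tests).
#' @return A list of class `paired_accuracy_table` with counts `n_both`,
#'   `n_mto_only`, `n_avs_only`, `n_neither`, total `n` and the limb.
#' @export
build_table <- function(cohort, endpoint_limb = "h1",
                        exclude_clinical_indication = FALSE) {
  endpoint_limb <- match.arg(endpoint_limb, c("h1", "h2", "h3", "h4"))
  op <- cohort$management == "surgery" & !is.na(cohort[[endpoint_limb]])
  if (exclude_clinical_indication)
    op <- op & !(cohort$mto_level != "high" & cohort$avs_level != "high")
  if (!any(op)) stop("no operated patients with an evaluable endpoint")
  sub <- cohort[op, , drop = FALSE]
  pts <- vapply(seq_len(nrow(sub)), function(i)
    score_patient("surgery", sub$mto_level[i], sub$avs_level[i],
                  sub[[endpoint_limb]][i]),
    integer(2))
  m <- pts[1, ]; a <- pts[2, ]
  structure(list(n_both = sum(m == 1 & a == 1),
                 n_mto_only = sum(m == 1 & a == 0),
                 n_avs_only = sum(m == 0 & a == 1),
                 n_neither = sum(m == 0 & a == 0),
                 n = length(m), endpoint = endpoint_limb),
            class = "paired_accuracy_table")
}

#' Construct a paired accuracy table from counts
#'
#' @param n_both,n_mto_only,n_avs_only,n_neither Cell counts.
#' @param endpoint Optional endpoint label.
#' @return A `paired_accuracy_table`.
#' @export
paired_accuracy_table <- function(n_both, n_mto_only, n_avs_only, n_neither,
                                  endpoint = NA_character_) {
  counts <- c(n_both, n_mto_only, n_avs_only, n_neither)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(list(n_both = n_both, n_mto_only = n_mto_only,
                 n_avs_only = n_avs_only, n_neither = n_neither,
                 n = sum(counts), endpoint = endpoint),
            class = "paired_accuracy_table")
}

#' @export
print.paired_accuracy_table <- function(x, ...) {
  cat(sprintf("paired accuracy table%s (n = %d)\n",
              if (!is.na(x$endpoint)) paste0(" [", x$endpoint, "]") else "", x$n))
  m <- matrix(c(x$n_both, x$n_mto_only, x$n_avs_only, x$n_neither), 2, 2,
              byrow = TRUE,
              dimnames = list(c("MTO accurate", "MTO inaccurate"),
                              c("AVS accurate", "AVS inaccurate")))
  print(m)
  invisible(x)
}

wilson_limits <- function(x, n, z) {
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

newcombe_phi <- function(e, f, g, h) {
  A <- (e + f) * (g + h) * (e + g) * (f + h)
  if (A == 0) 0 else (e * h - f * g) / sqrt(A)
}

newcombe_paired_limits <- function(e, f, g, h, z) {
  n <- e + f + g + h
  p1 <- (e + f) / n
  p2 <- (e + g) / n
  d <- p1 - p2
  phi <- newcombe_phi(e, f, g, h)
  w1 <- wilson_limits(e + f, n, z)
  w2 <- wilson_limits(e + g, n, z)
  dl <- sqrt(max(0, (p1 - w1[["lower"]])^2 -
                    2 * phi * (p1 - w1[["lower"]]) * (w2[["upper"]] - p2) +
                    (w2[["upper"]] - p2)^2))
  du <- sqrt(max(0, (w1[["upper"]] - p1)^2 -
                    2 * phi * (w1[["upper"]] - p1) * (p2 - w2[["lower"]]) +
                    (p2 - w2[["lower"]])^2))
  c(lower = max(-1, d - dl), upper = min(1, d + du))
}

#' Difference in paired accuracy with Newcombe-Wilson score interval
#'
#' Point estimate `(n_mto_only - n_avs_only) / n` of the difference in
#' accuracy (MTO minus AVS) with the Newcombe score interval for a
#' difference of paired proportions: Wilson limits for the two marginal
#' accuracies are combined by the square-and-add rule with a
#' phi-coefficient correction for the pairing (phi is set to 0 when any
#' marginal of the 2x2 table is 0). Superiority is tested by the exact
#' McNemar test on the discordant counts; the non-inferiority p-value for
#' the null `difference = margin` is obtained by interval inversion - the
#' smallest two-sided level at which the interval's lower bound reaches
#' the margin.
#'
#' @param table A [paired_accuracy_table()].
#' @param level Confidence coefficient, default 0.95.
#' @param margin Non-inferiority margin on the difference scale,
#'   default -0.17.
#' @return A list of class `diff_ci`: `estimate`, `interval`, `margin`,
#'   `p_superiority`, `p_noninferiority`, the marginal accuracies and the
#'   table.
#' @export
accuracy_difference <- function(table, level = 0.95, margin = -0.17) {
  stopifnot(inherits(table, "paired_accuracy_table"))
  if (table$n == 0) stop("empty accuracy table")
  e <- table$n_both; f <- table$n_mto_only
  g <- table$n_avs_only; h <- table$n_neither
  n <- table$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  lim <- newcombe_paired_limits(e, f, g, h, z)
  est <- (f - g) / n
  p_sup <- exact_mcnemar_p(f, g)
  p_ni <- if (est <= margin) 1 else {
    lower_at <- function(zz) newcombe_paired_limits(e, f, g, h, zz)[["lower"]]
    if (lower_at(40) > margin) 0 else {
      zz <- stats::uniroot(function(zz) lower_at(zz) - margin,
                           c(1e-9, 40), tol = 1e-10)$root
      2 * (1 - stats::pnorm(zz))
    }
  }
  int <- new_interval(lim[["lower"]], lim[["upper"]], level, "newcombe-paired")
  structure(list(estimate = est, interval = int, margin = margin,
                 p_superiority = p_sup, p_noninferiority = p_ni,
                 accuracy_mto = (e + f) / n, accuracy_avs = (e + g) / n,
                 table = table),
            class = "diff_ci")
}

#' @export
print.diff_ci <- function(x, ...) {
  cat(sprintf(paste0("accuracy MTO %.1f%%, AVS %.1f%% (n = %d%s)\n",
                     "difference %.1f%% (%.0f%% CI %.1f to %.1f%%)\n",
                     "P superiority = %.2g; P non-inferiority (margin %.0f%%) = %.2g\n"),
              100 * x$accuracy_mto, 100 * x$accuracy_avs, x$table$n,
              if (!is.na(x$table$endpoint)) paste0(", ", x$table$endpoint) else "",
              100 * x$estimate, 100 * x$interval$level, 100 * x$interval$lower,
              100 * x$interval$upper, x$p_superiority, 100 * x$margin,
              x$p_noninferiority))
  invisible(x)
}

#' Sensitivity and false-positive rate of each test
#'
#' Sensitivity: among operated patients achieving the endpoint limb, the
#' proportion graded high by the test. False-positive rate: patients
#' managed medically are assumed true negatives (their adrenals were not
#' removed, so negative grades cannot be verified); among them, the
#' proportion graded high by the test. Both rates carry exact
#' Clopper-Pearson intervals.
#'
#' @param cohort Graded and classified cohort data frame.
#' @param endpoint_limb One of "h1".."h4" (default "h1").
#' @param level Confidence coefficient.
#' @return A list of class `diagnostic_rates` with per-test `sensitivity`
#'   and `false_positive_rate` entries (`x`, `n`, `estimate`, `interval`).
#' @export
diagnostic_rates <- function(cohort, endpoint_limb = "h1", level = 0.95) {
  endpoint_limb <- match.arg(endpoint_limb, c("h1", "h2", "h3", "h4"))
  cured <- cohort$management == "surgery" & !is.na(cohort[[endpoint_limb]]) &
    cohort[[endpoint_limb]]
  negatives <- cohort$management == "medical"
  if (!any(cured)) stop("no operated patients achieved the endpoint")
  if (!any(negatives)) stop("no assumed true negatives (medical group empty)")
  rate <- function(x, n) {
    ci <- clopper_pearson_ci(x, n, level)
    list(x = x, n = n, estimate = x / n, interval = ci)
  }
  out <- list(endpoint = endpoint_limb)
  for (test in c("mto", "avs")) {
    high <- cohort[[paste0(test, "_level")]] == "high"
    out[[test]] <- list(
      sensitivity = rate(sum(high & cured), sum(cured)),
      false_positive_rate = rate(sum(high & negatives), sum(negatives)))
  }
  structure(out, class = "diagnostic_rates")
}

#' @export
print.diagnostic_rates <- function(x, ...) {
  cat(sprintf("diagnostic rates (%s)\n", x$endpoint))
  for (test in c("mto", "avs")) {
    s <- x[[test]]$sensitivity; f <- x[[test]]$false_positive_rate
    cat(sprintf("  %s: sensitivity %d/%d = %.1f%% (%.1f to %.1f), FPR %d/%d = %.1f%% (%.1f to %.1f)\n",
                toupper(test), s$x, s$n, 100 * s$estimate,
                100 * s$interval$lower, 100 * s$interval$upper,
                f$x, f$n, 100 * f$estimate,
                100 * f$interval$lower, 100 * f$interval$upper))
  }
  invisible(x)
}

#' Accuracy comparison across all four hierarchical endpoints
#'
#' Builds the paired accuracy table and [accuracy_difference()] for each
#' hierarchical limb in order, each with its own denominator (data
#' availability differs per endpoint). No multiplicity adjustment is
#' applied: the fixed hierarchy substitutes for adjustment.
#'
#' @param cohort Graded and classified cohort data frame.
#' @param level Confidence coefficient.
#' @param margin Non-inferiority margin.
#' @param exclude_clinical_indication Denominator convention, see
#'   [build_table()].
#' @return Named list of `diff_ci` objects for `h1`..`h4`.
#' @export
hierarchical_report <- function(cohort, level = 0.95, margin = -0.17,
                                exclude_clinical_indication = FALSE) {
  limbs <- c("h1", "h2", "h3", "h4")
  out <- lapply(limbs, function(l)
    accuracy_difference(build_table(cohort, l, exclude_clinical_indication),
                        level = level, margin = margin))
  names(out) <- limbs
  out
}
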