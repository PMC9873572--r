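# Stratified bootstrap assessing the impact of failed AVS runs on the
# paired accuracy difference.

# per-patient accuracy category (1 both, 2 mto-only, 3 avs-only,
# 4 neither) among operated patients with an evaluable endpoint
accuracy_categories <- function(cohort, endpoint_limb) {
  op <- cohort$management == "surgery" & !is.na(cohort[[endpoint_limb]])
  sub <- cohort[op, , drop = FALSE]
  if (!nrow(sub)) stop("no operated patients with an evaluable endpoint")
  pts <- vapply(seq_len(nrow(sub)), function(i)
    score_patient("surgery", sub$mto_level[i], sub$avs_level[i],
                  sub[[endpoint_limb]][i]),
    integer(2))
  data.frame(category = 1L + (pts[1, ] == 0) * 2L + (pts[2, ] == 0) * 1L,
             avs_failed = sub$avs_level == "failed")
  # category: mto=1,avs=1 -> 1; mto=1,avs=0 -> 2; mto=0,avs=1 -> 3; 0,0 -> 4
}

diff_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  (counts[2] - counts[3]) / n
}

#' Bootstrap sensitivity of the accuracy difference to AVS failures
#'
#' Resamples the operated cohort with replacement, stratified by whether
#' AVS failed, preserving the stratum sizes. Each replicate computes the
#' MTO-minus-AVS accuracy difference for the full replicate and for its
#' AVS-successful subset; the difference between these two differences is
#' the replicate statistic. A percentile confidence interval summarizes
#' its distribution; the result is flagged `sensitive` when the interval
#' excludes zero. With no AVS failures the statistic is identically zero.
#'
#' @param cohort Graded and classified cohort data frame.
#' @param endpoint_limb One of "h1".."h4".
#' @param n_reps Number of bootstrap replicates (default one million; use
#'   fewer for exploratory runs).
#' @param seed Optional seed for the resampling draw.
#' @param level Confidence coefficient of the percentile interval.
#' @return A list of class `bootstrap_result`: `delta_deltas` (replicate
#'   statistics), `interval`, `n_reps`, `seed`, `sensitive`,
#'   `n_avs_failed`, `n_avs_success` and `degenerate` (no failed stratum).
#' @export
bootstrap_avs_failure_sensitivity <- function(cohort, endpoint_limb = "h1",
                                              n_reps = 1e6, seed = NULL,
                                              level = 0.95) {
  endpoint_limb <- match.arg(endpoint_limb, c("h1", "h2", "h3", "h4"))
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  cats <- accuracy_categories(cohort, endpoint_limb)
  fail <- cats$category[cats$avs_failed]
  succ <- cats$category[!cats$avs_failed]
  n_f <- length(fail)
  n_s <- length(succ)
  tab <- function(x) tabulate(x, nbins = 4L)
  if (n_f == 0L || n_s == 0L) {
    # a single stratum: full replicate equals its AVS-successful (or
    # failed) subset complement, so the statistic is identically 0
    dd <- rep(0, n_reps)
  } else {
    p_f <- tab(fail) / n_f
    p_s <- tab(succ) / n_s
    cf <- stats::rmultinom(n_reps, n_f, p_f)
    cs <- stats::rmultinom(n_reps, n_s, p_s)
    d_all <- (cf[2, ] + cs[2, ] - cf[3, ] - cs[3, ]) / (n_f + n_s)
    d_succ <- (cs[2, ] - cs[3, ]) / n_s
    dd <- d_all - d_succ
  }
  qs <- stats::quantile(dd, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  int <- new_interval(qs[1], qs[2], level, "bootstrap-percentile")
  structure(list(delta_deltas = dd, interval = int, n_reps = n_reps,
                 seed = seed, sensitive = qs[1] > 0 || qs[2] < 0,
                 n_avs_failed = n_f, n_avs_success = n_s,
                 degenerate = n_f == 0L || n_s == 0L,
                 endpoint = endpoint_limb),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("bootstrap AVS-failure sensitivity (%s): %d replicates, ",
                     "%d failed / %d successful\n",
                     "delta of differences %.0f%% CI: %.4f to %.4f -> %s\n"),
              x$endpoint, x$n_reps, x$n_avs_failed, x$n_avs_success,
              100 * x$interval$level, x$interval$lower, x$interval$upper,
              if (x$degenerate) "degenerate (single stratum)"
              else if (x$sensitive) "sensitive to AVS failures"
              else "insensitive to AVS failures"))
  invisible(x)
}
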