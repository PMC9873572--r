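test_that("per-patient scoring follows the accuracy rule", {
  expect_equal(score_patient("surgery", "high", "low", TRUE), c(mto = 1L, avs = 0L))
  expect_equal(score_patient("surgery", "high", "low", FALSE), c(mto = 0L, avs = 1L))
  expect_equal(score_patient("surgery", "high", "failed", TRUE), c(mto = 1L, avs = 0L))
  expect_equal(score_patient("medical", "low", "low"), c(mto = 1L, avs = 1L))
  # a medical patient graded high by one test is that test's false positive
  expect_equal(score_patient("medical", "high", "low"), c(mto = 0L, avs = 1L))
  # clinically indicated surgery with two intermediate grades: both negative
  expect_equal(score_patient("surgery", "intermediate", "intermediate", TRUE),
               c(mto = 0L, avs = 0L))
  expect_true(all(is.na(score_patient("deferred", "high", "high"))))
  expect_error(score_patient("surgery", "high", "low"), "endpoint_success")
})

test_that("accuracy tables aggregate scores with the right denominators", {
  co <- scored_cohort(
    management = c("surgery", "medical", "surgery", "deferred"),
    mto_level = c("high", "low", "intermediate", "high"),
    avs_level = c("low", "low", "intermediate", "high"),
    h1 = c(TRUE, NA, TRUE, NA))
  tab <- build_table(co, "h1")
  expect_equal(tab$n, 2)                     # medical + deferred excluded
  expect_equal(tab$n_mto_only, 1)            # high & cured
  expect_equal(tab$n_avs_only, 0)
  expect_equal(tab$n_neither, 1)             # both-intermediate cure missed
  expect_equal(tab$n_both, 0)

  excl <- build_table(co, "h1", exclude_clinical_indication = TRUE)
  expect_equal(excl$n, 1)

  conc <- scored_cohort(management = rep("surgery", 6),
                        mto_level = rep(c("high", "low"), 3),
                        avs_level = rep(c("high", "low"), 3),
                        h1 = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  ctab <- build_table(conc, "h1")
  expect_equal(ctab$n_mto_only + ctab$n_avs_only, 0)
  expect_equal(ctab$n, 6)

  expect_error(build_table(scored_cohort("medical", "low", "low", NA), "h1"),
               "no operated")
})

test_that("difference estimate, interval and p-values are internally consistent", {
  set.seed(31)
  for (i in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, sample(20:120, 1),
                                      c(0.4, 0.25, 0.1, 0.25)))
    tab <- paired_accuracy_table(cnt[1], cnt[2], cnt[3], cnt[4])
    d <- accuracy_difference(tab)
    expect_equal(d$estimate, (cnt[2] - cnt[3]) / sum(cnt))
    expect_gte(d$interval$lower, -1)
    expect_lte(d$interval$upper, 1)
    expect_lte(d$interval$lower, d$estimate)
    expect_gte(d$interval$upper, d$estimate)
    expect_equal(d$p_superiority, exact_mcnemar_p(cnt[2], cnt[3]))
    # swapping the two tests negates the estimate and mirrors the interval
    sw <- accuracy_difference(paired_accuracy_table(cnt[1], cnt[3], cnt[2], cnt[4]))
    expect_equal(sw$estimate, -d$estimate)
    expect_equal(sw$interval$lower, -d$interval$upper, tolerance = 1e-10)
    expect_equal(sw$interval$upper, -d$interval$lower, tolerance = 1e-10)
    # interval inversion consistency at the margin
    if (d$interval$lower > d$margin) expect_lt(d$p_noninferiority, 0.05)
    if (d$interval$lower < d$margin && d$estimate > d$margin)
      expect_gt(d$p_noninferiority, 0.05)
  }
  sym <- accuracy_difference(paired_accuracy_table(30, 8, 8, 20))
  expect_equal(sym$estimate, 0)
  expect_equal(sym$interval$lower, -sym$interval$upper, tolerance = 1e-10)
  expect_equal(sym$p_superiority, 1)
})

test_that("interval shrinks toward the estimate as n grows at fixed proportions", {
  widths <- vapply(c(1, 4, 16, 64), function(k) {
    d <- accuracy_difference(paired_accuracy_table(30 * k, 10 * k, 3 * k, 20 * k))
    d$interval$upper - d$interval$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4], widths[1] / 6)
})

test_that("Newcombe interval covers the true paired difference at nominal rate", {
  set.seed(77)
  pr <- c(0.45, 0.2, 0.1, 0.25)
  d_true <- pr[2] - pr[3]
  m <- stats::rmultinom(1000, 80, pr)
  covered <- vapply(seq_len(1000), function(i) {
    ci <- accuracy_difference(paired_accuracy_table(m[1, i], m[2, i],
                                                    m[3, i], m[4, i]))$interval
    ci$lower <= d_true && d_true <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("diagnostic rates recover engineered sensitivity and FPR fixtures", {
  perfect <- scored_cohort(
    management = c(rep("surgery", 10), rep("medical", 8)),
    mto_level = c(rep("high", 10), rep("low", 8)),
    avs_level = c(rep("high", 10), rep("low", 8)),
    h1 = c(rep(TRUE, 10), rep(NA, 8)))
  dr <- diagnostic_rates(perfect)
  expect_equal(dr$mto$sensitivity$estimate, 1)
  expect_equal(dr$mto$false_positive_rate$estimate, 0)
  expect_equal(dr$avs$sensitivity$estimate, 1)

  fx <- rates_fixture(n_cured = 74, x_mto = 55, x_avs = 48,
                      n_neg = 42, fp_mto = 2, fp_avs = 2)
  dr <- diagnostic_rates(fx)
  expect_equal(dr$mto$sensitivity$x, 55)
  expect_equal(round(100 * dr$mto$sensitivity$estimate, 1), 74.3)
  expect_equal(round(100 * dr$avs$sensitivity$estimate, 1), 64.9)
  expect_equal(round(100 * dr$mto$false_positive_rate$estimate, 1), 4.8)
})

test_that("the hierarchical report is consistent with its per-limb tables", {
  co <- default_cohort_cached()
  rep <- hierarchical_report(co)
  expect_named(rep, c("h1", "h2", "h3", "h4"))
  for (limb in names(rep)) {
    tab <- build_table(co, limb)
    expect_equal(rep[[limb]]$estimate, (tab$n_mto_only - tab$n_avs_only) / tab$n)
    expect_gt(tab$n, 0)
  }
  # identical grades for both tests force all four differences to zero
  same <- scored_cohort(management = rep("surgery", 12),
                        mto_level = rep(c("high", "low", "high"), 4),
                        avs_level = rep(c("high", "low", "high"), 4),
                        h1 = rep(c(TRUE, FALSE), 6))
  for (d in hierarchical_report(same)) expect_equal(d$estimate, 0)
})
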