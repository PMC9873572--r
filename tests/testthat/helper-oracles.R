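# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: brute-force enumeration and resampling only.

# all ways to split k patients over the 4 accuracy categories
compositions4 <- function(k) {
  g <- expand.grid(a = 0:k, b = 0:k, c = 0:k)
  g <- g[g$a + g$b + g$c <= k, ]
  cbind(g$a, g$b, g$c, k - g$a - g$b - g$c)
}

# exact distribution of the stratified-bootstrap statistic
# (difference over all patients minus difference over the AVS-successful
# stratum) for category count vectors cf (failed) and cs (successful)
exact_delta_distribution <- function(cf, cs) {
  kf <- sum(cf); ks <- sum(cs); n <- kf + ks
  A <- compositions4(kf)
  B <- compositions4(ks)
  pA <- apply(A, 1, function(x) stats::dmultinom(x, prob = cf / kf))
  pB <- apply(B, 1, function(x) stats::dmultinom(x, prob = cs / ks))
  dA <- A[, 2] - A[, 3]
  dB <- B[, 2] - B[, 3]
  value <- outer(dA / n, dB * (1 / n - 1 / ks), "+")
  prob <- outer(pA, pB)
  o <- order(value)
  list(value = as.vector(value)[o], prob = as.vector(prob)[o])
}

exact_dist_mean <- function(d) sum(d$value * d$prob)
exact_dist_quantile <- function(d, p) {
  cum <- cumsum(d$prob)
  vapply(p, function(pp) d$value[which(cum >= pp)[1]], numeric(1))
}

# percentile interval of the paired-difference bootstrap for a 2x2
# paired table, by multinomial resampling of the four cells
bootstrap_paired_diff_ci <- function(e, f, g, h, reps = 2e6, level = 0.95,
                                     seed = 1) {
  set.seed(seed)
  n <- e + f + g + h
  m <- stats::rmultinom(reps, n, c(e, f, g, h) / n)
  d <- (m[2, ] - m[3, ]) / n
  unname(stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

# minimal scored cohort: a data frame with exactly the columns the
# accuracy stage consumes
scored_cohort <- function(management, mto_level, avs_level, h1,
                          h2 = h1, h3 = h1, h4 = h1,
                          clinical_level = NA_character_) {
  data.frame(management = management, mto_level = mto_level,
             avs_level = avs_level, h1 = h1, h2 = h2, h3 = h3, h4 = h4,
             clinical_level = clinical_level, stringsAsFactors = FALSE)
}

# a cohort reproducing given sensitivity / false-positive counts:
# n_cured operated patients achieving h1 (x_mto, x_avs of them graded
# high) and n_neg medical patients (fp_mto, fp_avs graded high)
rates_fixture <- function(n_cured, x_mto, x_avs, n_neg, fp_mto, fp_avs) {
  m_lv <- c(rep("high", x_mto), rep("low", n_cured - x_mto),
            rep("high", fp_mto), rep("low", n_neg - fp_mto))
  a_lv <- c(rep("high", x_avs), rep("low", n_cured - x_avs),
            rep("high", fp_avs), rep("low", n_neg - fp_avs))
  scored_cohort(management = c(rep("surgery", n_cured), rep("medical", n_neg)),
                mto_level = m_lv, avs_level = a_lv,
                h1 = c(rep(TRUE, n_cured), rep(NA, n_neg)))
}

default_cohort_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(seed = 20260924))
    cache
  }
})
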