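# Trial-design computations: minimization allocation of investigation
# order, exact discordant-pair power, and design simulation from a table
# of outcome permutations.

#' Initialize a minimization state
#'
#' State for dynamically allocating the order of the two investigations
#' (MTO-first vs AVS-first) while balancing study site, sex and age band
#' (<55 / >=55 years), using the Pocock-Simon range method with a biased
#' coin.
#'
#' @param p_biased Probability of assigning the imbalance-minimizing arm
#'   (default 0.8); ties are resolved 50:50.
#' @return A list of class `minimization_state` holding per-factor-level
#'   arm counts.
#' @export
minimization_state <- function(p_biased = 0.8) {
  stopifnot(p_biased >= 0.5, p_biased <= 1)
  counts <- list(
    site = matrix(0L, 2, 3, dimnames = list(c("mto_first", "avs_first"),
                                            c("A", "B", "C"))),
    sex = matrix(0L, 2, 2, dimnames = list(c("mto_first", "avs_first"),
                                           c("male", "female"))),
    age_band = matrix(0L, 2, 2, dimnames = list(c("mto_first", "avs_first"),
                                                c("<55", ">=55"))))
  structure(list(counts = counts, p_biased = p_biased, n_allocated = 0L),
            class = "minimization_state")
}

#' Allocate the next patient by minimization
#'
#' Computes, for each arm, the total imbalance (summed over the patient's
#' three factor levels) that a hypothetical assignment would produce, and
#' assigns the imbalance-minimizing arm with probability `p_biased`; exact
#' ties are resolved by a fair coin.
#'
#' @param state A [minimization_state()].
#' @param site "A", "B" or "C".
#' @param sex "male" or "female".
#' @param age Age in years (banded at 55).
#' @return List with `arm` ("mto_first" or "avs_first") and the updated
#'   `state`.
#' @export
minimize_allocation <- function(state, site, sex, age) {
  stopifnot(inherits(state, "minimization_state"))
  site <- match.arg(site, c("A", "B", "C"))
  sex <- match.arg(sex, c("male", "female"))
  band <- if (age < 55) "<55" else ">=55"
  levels <- list(site = site, sex = sex, age_band = band)
  imbalance <- vapply(1:2, function(arm) {
    sum(vapply(names(levels), function(f) {
      cnt <- state$counts[[f]][, levels[[f]]]
      cnt[arm] <- cnt[arm] + 1L
      abs(cnt[1] - cnt[2])
    }, numeric(1)))
  }, numeric(1))
  arm <- if (imbalance[1] == imbalance[2]) {
    if (stats::runif(1) < 0.5) 1L else 2L
  } else {
    best <- which.min(imbalance)
    if (stats::runif(1) < state$p_biased) best else 3L - best
  }
  for (f in names(levels))
    state$counts[[f]][arm, levels[[f]]] <- state$counts[[f]][arm, levels[[f]]] + 1L
  state$n_allocated <- state$n_allocated + 1L
  list(arm = rownames(state$counts$site)[arm], state = state)
}

#' Exact power of the two-sided exact sign test on discordant pairs
#'
#' In a within-patient comparison only discordant pairs (exactly one test
#' accurate) are informative. The rejection region of the exact two-sided
#' sign test is the set of counts `b` with
#' `2 * min(P(X <= b), P(X >= b)) <= alpha` under `X ~ Binomial(n, 1/2)`;
#' the power is the probability of that region under
#' `Binomial(n, p_favoured)`.
#'
#' @param n_discordant Number of discordant pairs.
#' @param p_favoured Probability that the favoured test is the accurate
#'   one in a discordant pair.
#' @param alpha Two-sided significance level.
#' @return The exact power.
#' @examples
#' discordant_power(32, 0.8, 0.05)  # > 0.90
#' @export
discordant_power <- function(n_discordant, p_favoured, alpha = 0.05) {
  stopifnot(n_discordant >= 1, n_discordant == round(n_discordant),
            p_favoured >= 0, p_favoured <= 1, alpha > 0, alpha < 1)
  b <- 0:n_discordant
  tail2 <- 2 * pmin(stats::pbinom(b, n_discordant, 0.5),
                    1 - stats::pbinom(b - 1, n_discordant, 0.5))
  reject <- tail2 <= alpha
  sum(stats::dbinom(b[reject], n_discordant, p_favoured))
}

#' Default table of outcome permutations
#'
#' Joint probabilities of the grade pattern (MTO high / not, AVS high /
#' not) and cure after surgery, encoding the design assumptions: half of
#' completed patients proceed to surgery, half of those because exactly
#' one test graded high, and in discordant pairs the favoured test (MTO)
#' is accurate 80% of the time.
#'
#' @param p_favoured Probability that MTO is the accurate test in a
#'   discordant-grade patient (cure probability given MTO-only high).
#' @param p_cure_concordant Cure probability when both tests grade high.
#' @return Data frame of class `permutation_table` with columns
#'   `mto_high`, `avs_high`, `cured`, `prob` (probabilities sum to 1).
#' @export
permutation_table <- function(p_favoured = 0.8, p_cure_concordant = 0.9) {
  cells <- rbind(
    data.frame(mto_high = TRUE,  avs_high = TRUE,  cured = TRUE,
               prob = 32 / 128 * p_cure_concordant),
    data.frame(mto_high = TRUE,  avs_high = TRUE,  cured = FALSE,
               prob = 32 / 128 * (1 - p_cure_concordant)),
    data.frame(mto_high = TRUE,  avs_high = FALSE, cured = TRUE,
               prob = 16 / 128 * p_favoured),
    data.frame(mto_high = TRUE,  avs_high = FALSE, cured = FALSE,
               prob = 16 / 128 * (1 - p_favoured)),
    data.frame(mto_high = FALSE, avs_high = TRUE,  cured = TRUE,
               prob = 16 / 128 * (1 - p_favoured)),
    data.frame(mto_high = FALSE, avs_high = TRUE,  cured = FALSE,
               prob = 16 / 128 * p_favoured),
    data.frame(mto_high = FALSE, avs_high = FALSE, cured = NA,
               prob = 64 / 128))
  structure(cells, class = c("permutation_table", "data.frame"))
}

#' Simulate the paired design from a permutation table
#'
#' Draws cohorts from the joint grade/cure table, applies the surgery rule
#' (operate when either test grades high), scores per-patient accuracy,
#' runs [accuracy_difference()] and records rejections of the superiority
#' and non-inferiority hypotheses.
#'
#' @param perm_table A [permutation_table()] (probabilities must sum to 1,
#'   with at least one surgical cell).
#' @param n_patients Patients per simulated cohort.
#' @param margin Non-inferiority margin.
#' @param alpha Significance level for both tests.
#' @param n_sims Number of simulated cohorts.
#' @param seed Optional seed.
#' @param level Confidence coefficient used in the interval inversion.
#' @return List with `power_superiority`, `power_noninferiority`, their
#'   Monte Carlo standard errors, `expected_n_surgery` and
#'   `expected_n_discordant`.
#' @export
simulate_design <- function(perm_table = permutation_table(),
                            n_patients = 128, margin = -0.17, alpha = 0.05,
                            n_sims = 1000, seed = NULL, level = 0.95) {
  stopifnot(n_sims >= 1)
  if (abs(sum(perm_table$prob) - 1) > 1e-8)
    stop("permutation table probabilities must sum to 1")
  surgical <- perm_table$mto_high | perm_table$avs_high
  if (!any(surgical)) stop("degenerate table: no cell leads to surgery")
  if (!is.null(seed)) set.seed(seed)
  rej_sup <- rej_ni <- logical(n_sims)
  n_surg <- n_disc <- numeric(n_sims)
  draws <- stats::rmultinom(n_sims, n_patients, perm_table$prob)
  acc <- function(high, cured) ifelse(high, cured, !cured)
  for (i in seq_len(n_sims)) {
    k <- draws[, i][surgical]
    pt <- perm_table[surgical, ]
    m <- acc(pt$mto_high, pt$cured)
    a <- acc(pt$avs_high, pt$cured)
    tab <- paired_accuracy_table(
      n_both = sum(k[m & a]), n_mto_only = sum(k[m & !a]),
      n_avs_only = sum(k[!m & a]), n_neither = sum(k[!m & !a]))
    n_surg[i] <- tab$n
    n_disc[i] <- tab$n_mto_only + tab$n_avs_only
    if (tab$n == 0) next
    dc <- accuracy_difference(tab, level = level, margin = margin)
    rej_sup[i] <- dc$p_superiority <= alpha
    rej_ni[i] <- dc$p_noninferiority <= alpha
  }
  ps <- mean(rej_sup)
  pn <- mean(rej_ni)
  list(power_superiority = ps,
       power_noninferiority = pn,
       se_superiority = sqrt(ps * (1 - ps) / n_sims),
       se_noninferiority = sqrt(pn * (1 - pn) / n_sims),
       expected_n_surgery = mean(n_surg),
       expected_n_discordant = mean(n_disc),
       n_sims = n_sims)
}
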