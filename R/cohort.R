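# Cohort data model: eligibility screening, unit conversion, CSV/JSON
# readers and writers, and the calibrated synthetic cohort generator.

#' Eligibility screening for a primary aldosteronism trial
#'
#' Applies the inclusion rules to a screening record. A patient is
#' `eligible` with an elevated aldosterone-to-renin ratio (measured off
#' interfering drugs) plus one positive confirmatory test: post-saline
#' aldosterone above 190 pmol/L, failure to suppress aldosterone by 30%
#' after captopril with persistent renin suppression, or spontaneous
#' hypokalemia with undetectable renin and aldosterone above 550 pmol/L.
#' Without any confirmatory test the patient can be `exceptional` when
#' aldosterone exceeds 450 pmol/L and either renin is below 0.5 pmol/mL/h
#' on an ACE inhibitor / angiotensin receptor blocker, or the patient is
#' under 40 with a definite adenoma on imaging. Otherwise `ineligible`.
#'
#' @param screening A list with (any of) the fields `elevated_arr`
#'   (logical, required), `saline_aldosterone` (pmol/L),
#'   `captopril_fall_pct` (% aldosterone suppression),
#'   `captopril_renin_suppressed` (logical), `spontaneous_hypokalemia`
#'   (logical), `renin_undetectable` (logical), `aldosterone` (pmol/L),
#'   `renin` (pmol/mL/h), `on_acei_arb` (logical), `age` (years),
#'   `definite_adenoma` (logical).
#' @return One of "eligible", "exceptional", "ineligible".
#' @export
check_eligibility <- function(screening) {
  g <- function(f) if (is.null(screening[[f]])) NA else screening[[f]]
  elevated_arr <- isTRUE(g("elevated_arr"))
  saline <- g("saline_aldosterone")
  cap_fall <- g("captopril_fall_pct")
  aldo <- g("aldosterone")
  has_confirm <- !is.na(saline) || !is.na(cap_fall) ||
    (!is.na(g("spontaneous_hypokalemia")) && !is.na(g("renin_undetectable")))
  has_exceptional_inputs <- !is.na(aldo) &&
    (!is.na(g("renin")) || !is.na(g("age")))
  if (!has_confirm && !has_exceptional_inputs)
    stop("insufficient data: no confirmatory test results and no exceptional-path inputs")
  if (elevated_arr && has_confirm) {
    if ((!is.na(saline) && saline > 190) ||
        (!is.na(cap_fall) && cap_fall < 30 && isTRUE(g("captopril_renin_suppressed"))) ||
        (isTRUE(g("spontaneous_hypokalemia")) && isTRUE(g("renin_undetectable")) &&
         !is.na(aldo) && aldo > 550))
      return("eligible")
  }
  if (!has_confirm && elevated_arr && !is.na(aldo) && aldo > 450) {
    if ((!is.na(g("renin")) && g("renin") < 0.5 && isTRUE(g("on_acei_arb"))) ||
        (!is.na(g("age")) && g("age") < 40 && isTRUE(g("definite_adenoma"))))
      return("exceptional")
  }
  "ineligible"
}

#' Convert renin mass to renin activity
#'
#' Multiplies a direct renin concentration (mU/L) by a laboratory
#' conversion factor to express it as plasma renin activity (nmol/L/h).
#' No universal factor exists; supply the one validated for your assay.
#'
#' @param mass Renin mass (mU/L), non-negative.
#' @param factor Conversion factor ((nmol/L/h) per (mU/L)), positive.
#' @return Renin activity in nmol/L/h.
#' @export
renin_mass_to_activity <- function(mass, factor) {
  if (any(is.na(mass)) || any(mass < 0)) stop("'mass' must be non-negative")
  if (any(is.na(factor)) || any(factor <= 0)) stop("'factor' must be positive")
  mass * factor
}

# Bivariate standard normal CDF P(Z1 < a, Z2 < b; rho), by conditioning
# on Z1 and integrating the conditional normal. Accurate to ~1e-10.
pbinorm <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  if (rho > 0.9999) return(stats::pnorm(min(a, b)))
  if (rho < -0.9999) return(max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  f <- function(z) stats::pnorm((b - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Calibrate generator operating characteristics to a concordance target
#'
#' Given the prevalence of true unilateral disease, the two sensitivities
#' and the AVS failure rate, solves for the false-positive rates and the
#' latent grade correlation such that the expected high-grade pattern at
#' the cohort level matches a target Venn structure: marginal
#' probabilities of an MTO-high and an AVS-high grade and the probability
#' that both grade high. The two tests' high indicators are linked by a
#' shared latent detectability variable (a Gaussian copula); the solved
#' correlation is the latent-sharing weight.
#'
#' @param p_unilateral Prevalence of true unilateral disease.
#' @param sens_mto,sens_avs Probability of a high grade given true
#'   unilateral disease (for AVS, conditional on successful cannulation).
#' @param p_avs_failure Probability that AVS fails (independent of truth).
#' @param target Named probabilities `c(mto, avs, both)` for the marginal
#'   and joint high-grade rates; the default is the 67/58/39 pattern per
#'   128 patients.
#' @return List with `spec_mto`, `spec_avs` and `grade_correlation`.
#' @export
calibrate_concordance <- function(p_unilateral, sens_mto, sens_avs,
                                  p_avs_failure,
                                  target = c(mto = 67, avs = 58, both = 39) / 128) {
  pu <- p_unilateral
  f_m <- (target[["mto"]] - pu * sens_mto) / (1 - pu)
  f_a <- (target[["avs"]] / (1 - p_avs_failure) - pu * sens_avs) / (1 - pu)
  if (f_m < 0 || f_m > 1 || f_a < 0 || f_a > 1)
    stop("infeasible configuration: marginal high-grade targets are not ",
         "reachable with the supplied prevalence and sensitivities")
  both_at <- function(rho)
    (1 - p_avs_failure) *
      (pu * pbinorm(stats::qnorm(sens_mto), stats::qnorm(sens_avs), rho) +
       (1 - pu) * pbinorm(stats::qnorm(f_m), stats::qnorm(f_a), rho))
  lo <- both_at(-0.995) - target[["both"]]
  hi <- both_at(0.995) - target[["both"]]
  if (sign(lo) == sign(hi))
    stop("infeasible configuration: grade correlation incompatible with marginals")
  rho <- stats::uniroot(function(r) both_at(r) - target[["both"]],
                        c(-0.995, 0.995), tol = 1e-12)$root
  list(spec_mto = 1 - f_m, spec_avs = 1 - f_a, grade_correlation = rho)
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator. By default the
#' false-positive rates and the latent grade correlation are calibrated
#' (see [calibrate_concordance()]) so that the expected high-grade Venn
#' structure at the cohort level matches 67 MTO-high, 58 AVS-high, 39 both
#' and 42 neither per 128 patients; supply all of `spec_mto`, `spec_avs`
#' and `grade_correlation` to override the calibration.
#'
#' @param n_patients Cohort size, default 128.
#' @param p_unilateral Prevalence of true unilateral disease.
#' @param sens_mto,sens_avs Probability of a high grade given true
#'   unilateral disease (AVS: conditional on successful cannulation).
#' @param spec_mto,spec_avs Probability of a non-high grade given
#'   bilateral disease; `NULL` to calibrate.
#' @param grade_correlation Latent-sharing weight in `[-1, 1]` coupling
#'   the two tests' high-grade indicators; `NULL` to calibrate.
#' @param venn_target Concordance target passed to [calibrate_concordance()].
#' @param p_avs_failure Probability of a failed AVS.
#' @param p_intermediate Probability that a non-high grade is intermediate
#'   rather than low.
#' @param p_refusal Probability that a patient recommended surgery
#'   declines and is managed medically.
#' @param p_clinical_indication Prevalence of a strong clinical indication
#'   for surgery (used by the MDT rule when both grades are intermediate).
#' @param p_biochem_surgery_unilateral,p_biochem_surgery_bilateral Numeric
#'   `c(complete, partial, absent)` probabilities of the biochemical PASO
#'   outcome after surgery, given the true laterality.
#' @param sbp_change_mean,sbp_change_sd Mean and SD of the
#'   Oldham-corrected systolic home-BP change (%) after surgery.
#' @param dbp_change_mean,dbp_change_sd Same for diastolic BP.
#' @param sbp_dbp_corr Correlation between the systolic and diastolic
#'   corrected changes.
#' @param spiro_change_mean,spiro_change_sd Corrected systolic change (%)
#'   after 4 weeks of spironolactone.
#' @param spiro_surgery_correlation Correlation between the spironolactone
#'   and post-surgical corrected systolic changes.
#' @param p_med_withdrawal Probability that all antihypertensives are
#'   withdrawn at follow-up when the post-surgical home BP is controlled.
#' @param p_med_reduction Probability of a dose reduction otherwise.
#' @param medical_sbp_change_mean,medical_sbp_change_sd Corrected systolic
#'   change for medically managed patients (on spironolactone).
#' @param genotype_effect Log-odds shift per SD of BP response linking
#'   tumor genotype to clinical outcome (KCNJ5 enriched among good
#'   responders, CACNA1D among poor responders).
#' @param renin_conversion_factor Renin mass-to-activity factor used when
#'   writing both renin columns (documented placeholder, see
#'   [renin_mass_to_activity()]).
#' @param seed Integer seed; every random draw in [generate_cohort()]
#'   flows from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 128,
                          p_unilateral = 0.62,
                          sens_mto = 0.693,
                          sens_avs = 0.688,
                          spec_mto = NULL,
                          spec_avs = NULL,
                          grade_correlation = NULL,
                          venn_target = c(mto = 67, avs = 58, both = 39) / 128,
                          p_avs_failure = 0.12,
                          p_intermediate = 0.30,
                          p_refusal = 0.06,
                          p_clinical_indication = 0.5,
                          p_biochem_surgery_unilateral = c(0.93, 0.05, 0.02),
                          p_biochem_surgery_bilateral = c(0.60, 0.25, 0.15),
                          sbp_change_mean = -13, sbp_change_sd = 12,
                          dbp_change_mean = -11, dbp_change_sd = 10,
                          sbp_dbp_corr = 0.7,
                          spiro_change_mean = -10, spiro_change_sd = 12,
                          spiro_surgery_correlation = 0.53,
                          p_med_withdrawal = 0.67,
                          p_med_reduction = 0.6,
                          medical_sbp_change_mean = -9,
                          medical_sbp_change_sd = 9,
                          genotype_effect = 0.8,
                          renin_conversion_factor = 0.1,
                          seed = NULL) {
  probs <- c(p_unilateral, sens_mto, sens_avs, p_avs_failure, p_intermediate,
             p_refusal, p_clinical_indication, p_med_withdrawal,
             p_med_reduction, p_biochem_surgery_unilateral,
             p_biochem_surgery_bilateral)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(p_biochem_surgery_unilateral) - 1) > 1e-8 ||
      abs(sum(p_biochem_surgery_bilateral) - 1) > 1e-8)
    stop("biochemical outcome probabilities must sum to 1")
  if (n_patients < 1) stop("'n_patients' must be positive")
  supplied <- c(!is.null(spec_mto), !is.null(spec_avs), !is.null(grade_correlation))
  if (any(supplied) && !all(supplied))
    stop("supply all of spec_mto, spec_avs and grade_correlation, or none")
  if (!any(supplied)) {
    cal <- calibrate_concordance(p_unilateral, sens_mto, sens_avs,
                                 p_avs_failure, venn_target)
    spec_mto <- cal$spec_mto
    spec_avs <- cal$spec_avs
    grade_correlation <- cal$grade_correlation
  }
  if (spec_mto < 0 || spec_mto > 1 || spec_avs < 0 || spec_avs > 1 ||
      abs(grade_correlation) > 1)
    stop("specificities must lie in [0, 1] and grade_correlation in [-1, 1]")
  structure(as.list(environment())[c(
    "n_patients", "p_unilateral", "sens_mto", "sens_avs", "spec_mto",
    "spec_avs", "grade_correlation", "venn_target", "p_avs_failure",
    "p_intermediate", "p_refusal", "p_clinical_indication",
    "p_biochem_surgery_unilateral", "p_biochem_surgery_bilateral",
    "sbp_change_mean", "sbp_change_sd", "dbp_change_mean", "dbp_change_sd",
    "sbp_dbp_corr", "spiro_change_mean", "spiro_change_sd",
    "spiro_surgery_correlation", "p_med_withdrawal", "p_med_reduction",
    "medical_sbp_change_mean", "medical_sbp_change_sd", "genotype_effect",
    "renin_conversion_factor", "seed")],
    class = "cohort_config")
}

side_of <- function(true_laterality) sub("unilateral_", "", true_laterality)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row-wise categorical sampling from a matrix of (unnormalized) weights
sample_rows <- function(prob) {
  cs <- t(apply(prob, 1, cumsum))
  cs <- cs / cs[, ncol(cs)]
  u <- stats::runif(nrow(prob))
  rowSums(u > cs) + 1L
}

oldham_post <- function(baseline, change_pct)
  baseline * (200 + change_pct) / (200 - change_pct)

#' Generate a synthetic cohort
#'
#' Draws a full cohort of patients with raw AVS and MTO measurements,
#' baseline and follow-up visits, management assignment and (hidden) true
#' laterality. Grades are drawn first from the configured operating
#' characteristics through a shared-latent Gaussian copula; raw
#' measurements are then synthesized so that [grade_avs()] and
#' [grade_mto()] reproduce the drawn grade exactly. Follow-up biochemistry
#' is synthesized from a categorical PASO outcome model conditional on
#' management and true laterality, while follow-up blood pressure is
#' generated continuously, jointly with the 4-week spironolactone
#' response, so that Oldham-corrected changes have the configured
#' correlation. The returned table carries grade and outcome columns (via
#' [grade_cohort()] and [classify_cohort()]) and is fully reproducible for
#' a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param criteria A [grading_criteria()] used to attach grade columns.
#' @param paso A [paso_criteria()] used to attach outcome columns.
#' @return Data frame with one row per patient. The column
#'   `true_laterality` is generator-only ground truth and is not consulted
#'   by any analysis function.
#' @export
generate_cohort <- function(config = cohort_config(),
                            criteria = grading_criteria(),
                            paso = paso_criteria()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patients

  site <- sample(c("A", "B", "C"), n, TRUE, prob = c(0.55, 0.3, 0.15))
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.68, 0.32))
  age <- round(clamp(stats::rnorm(n, 51.5, 12), 18, 85))
  ethnicity <- sample(c("White", "Black", "Asian", "Other"), n, TRUE,
                      prob = c(0.586, 0.297, 0.109, 0.008))
  uni <- stats::runif(n) < cfg$p_unilateral
  true_lat <- ifelse(uni,
                     ifelse(stats::runif(n) < 0.5, "unilateral_left", "unilateral_right"),
                     "bilateral")

  # latent high-grade indicators through the shared-detectability copula
  rho <- cfg$grade_correlation
  s <- sqrt(abs(rho))
  z0 <- stats::rnorm(n)
  z_m <- s * z0 + sqrt(1 - abs(rho)) * stats::rnorm(n)
  z_a <- sign(rho) * s * z0 + sqrt(1 - abs(rho)) * stats::rnorm(n)
  p_m <- ifelse(uni, cfg$sens_mto, 1 - cfg$spec_mto)
  p_a <- ifelse(uni, cfg$sens_avs, 1 - cfg$spec_avs)
  m_high <- z_m < stats::qnorm(p_m)
  avs_failed <- stats::runif(n) < cfg$p_avs_failure
  a_high <- !avs_failed & (z_a < stats::qnorm(p_a))

  m_level <- ifelse(m_high, "high",
                    ifelse(stats::runif(n) < cfg$p_intermediate, "intermediate", "low"))
  a_level <- ifelse(avs_failed, "failed",
                    ifelse(a_high, "high",
                           ifelse(stats::runif(n) < cfg$p_intermediate, "intermediate", "low")))
  rnd_side_m <- ifelse(stats::runif(n) < 0.5, "left", "right")
  rnd_side_a <- ifelse(stats::runif(n) < 0.5, "left", "right")
  m_side <- ifelse(m_level %in% c("high", "intermediate"),
                   ifelse(uni, side_of(true_lat), rnd_side_m), "none")
  a_side <- ifelse(a_level %in% c("high", "intermediate"),
                   ifelse(uni, side_of(true_lat), rnd_side_a), "none")

  # --- AVS raw measurements consistent with the drawn grade -------------
  c_ivc <- stats::rlnorm(n, log(350), 0.25)
  si_l <- criteria$si_threshold + stats::rlnorm(n, log(1.5), 0.5)
  si_r <- criteria$si_threshold + stats::rlnorm(n, log(1.5), 0.5)
  fail_left <- avs_failed & stats::runif(n) < 0.5
  si_l[avs_failed & fail_left] <- stats::runif(sum(avs_failed & fail_left), 1.2,
                                               criteria$si_threshold - 0.1)
  si_r[avs_failed & !fail_left] <- stats::runif(sum(avs_failed & !fail_left), 1.2,
                                                criteria$si_threshold - 0.1)
  cort_l <- si_l * c_ivc
  cort_r <- si_r * c_ivc
  r0 <- stats::rlnorm(n, log(8), 0.4)          # non-dominant A/C ratio
  li <- stats::runif(n, 1, criteria$li_low - 0.1)
  ii <- a_level == "intermediate"
  li[ii] <- stats::runif(sum(ii), criteria$li_low, criteria$li_high - 1e-3)
  hh <- a_level == "high"
  li[hh] <- criteria$li_high + stats::rlnorm(sum(hh), log(4), 0.7)
  dom_left <- ifelse(a_side == "none", stats::runif(n) < 0.5, a_side == "left")
  ratio_l <- ifelse(dom_left, r0 * li, r0)
  ratio_r <- ifelse(dom_left, r0, r0 * li)
  ald_l <- ratio_l * cort_l
  ald_r <- ratio_r * cort_r
  ald_ivc <- r0 * 1.3 * c_ivc

  # --- MTO raw measurements consistent with the drawn grade -------------
  bg_l <- stats::rlnorm(n, log(12), 0.15)
  bg_r <- stats::rlnorm(n, log(12), 0.15)
  hu <- suvm <- rep(NA_real_, n)
  upt <- rep(NA, n)
  nod_side <- m_side
  mh <- m_level == "high"
  mi <- m_level == "intermediate"
  ml <- m_level == "low"
  low_nod <- ml & stats::runif(n) < 0.5      # half of low scans have a cold nodule
  nod_side[low_nod] <- ifelse(stats::runif(sum(low_nod)) < 0.5, "left", "right")
  ratio <- rep(NA_real_, n)
  ratio[mh] <- stats::runif(sum(mh), criteria$suv_ratio_threshold + 0.1, 3.2)
  ratio[mi] <- stats::runif(sum(mi), criteria$suv_ratio_threshold + 0.1, 2.6)
  ratio[low_nod] <- stats::runif(sum(low_nod), 0.6, 1.1)
  hu[mh] <- stats::runif(sum(mh), -10, criteria$benign_hu_max - 0.5)
  hu[mi] <- stats::runif(sum(mi), criteria$benign_hu_max + 4, 28)  # indeterminate density
  hu[low_nod] <- stats::runif(sum(low_nod), criteria$benign_hu_max + 2, 30)
  upt[mh] <- TRUE
  upt[mi] <- TRUE
  upt[low_nod] <- FALSE
  has_nod <- mh | mi | low_nod
  bg_contra <- ifelse(nod_side == "left", bg_r, bg_l)
  suvm[has_nod] <- (ratio * bg_contra)[has_nod]
  mto_hu_left <- ifelse(has_nod & nod_side == "left", hu, NA_real_)
  mto_hu_right <- ifelse(has_nod & nod_side == "right", hu, NA_real_)
  mto_suv_left <- ifelse(has_nod & nod_side == "left", suvm, NA_real_)
  mto_suv_right <- ifelse(has_nod & nod_side == "right", suvm, NA_real_)
  mto_up_left <- ifelse(has_nod & nod_side == "left", upt, NA)
  mto_up_right <- ifelse(has_nod & nod_side == "right", upt, NA)

  # --- MDT decision, refusals -------------------------------------------
  clinical_indication <- stats::runif(n) < cfg$p_clinical_indication
  opposite <- m_level == "high" & a_level == "high" & m_side != a_side
  either_high <- m_level == "high" | a_level == "high"
  both_int <- m_level == "intermediate" & a_level == "intermediate"
  management <- ifelse(opposite, "deferred",
                       ifelse(either_high | (both_int & clinical_indication),
                              "surgery", "medical"))
  refused <- management == "surgery" & stats::runif(n) < cfg$p_refusal
  management[refused] <- "medical"

  # --- baseline visit ----------------------------------------------------
  base_ald <- clamp(stats::rlnorm(n, log(650), 0.4), 200, 4000)
  base_renin <- stats::runif(n, 0.05, 0.45)
  base_k <- clamp(stats::rnorm(n, 3.5, 0.35), 2.7, 4.4)
  base_supp <- base_k < 3.2 & stats::runif(n) < 0.7
  base_sbp <- clamp(stats::rnorm(n, 148, 14), 118, 210)
  base_dbp <- clamp(stats::rnorm(n, 90, 10), 62, base_sbp - 25)
  base_ddd <- round(clamp(stats::rlnorm(n, log(3.5), 0.5), 0.5, 12), 1)
  base_ncl <- as.numeric(pmin(1 + stats::rpois(n, 1.2), 6))

  # --- corrected-change model (spironolactone + post-surgery BP) --------
  u <- stats::rnorm(n)
  r <- cfg$spiro_surgery_correlation
  c_surg_sbp <- clamp(cfg$sbp_change_mean + cfg$sbp_change_sd * u, -120, 80)
  c_spiro <- clamp(cfg$spiro_change_mean +
                     cfg$spiro_change_sd * (r * u + sqrt(1 - r^2) * stats::rnorm(n)),
                   -120, 80)
  rb <- cfg$sbp_dbp_corr
  c_surg_dbp <- clamp(cfg$dbp_change_mean +
                        cfg$dbp_change_sd * (rb * u + sqrt(1 - rb^2) * stats::rnorm(n)),
                      -120, 80)
  spiro_sbp_4wk <- oldham_post(base_sbp, c_spiro)

  # --- genotype (unilateral tumors only), linked to BP response ---------
  z_resp <- (c_surg_sbp - cfg$sbp_change_mean) / cfg$sbp_change_sd
  black <- ethnicity == "Black"
  p_k_base <- ifelse(sex == "female", ifelse(black, 0.10, 0.35),
                     ifelse(black, 0.03, 0.20))
  p_c_base <- ifelse(black, 0.45, 0.20)
  w_k <- stats::plogis(stats::qlogis(p_k_base) - cfg$genotype_effect * z_resp)
  w_c <- stats::plogis(stats::qlogis(p_c_base) + cfg$genotype_effect * z_resp)
  w_rest <- pmax(1 - w_k - w_c, 0.05)
  rest <- c(ATP1A1 = 0.25, ATP2B3 = 0.15, CTNNB1_GNAQ = 0.15, CLCN2 = 0.05,
            other = 0.40)
  gp <- cbind(KCNJ5 = w_k, CACNA1D = w_c, outer(w_rest, rest))
  gidx <- sample_rows(gp)
  genotype <- colnames(gp)[gidx]
  genotype[!uni] <- "none"

  # --- follow-up ---------------------------------------------------------
  fu_ald <- fu_renin <- fu_k <- fu_sbp <- fu_dbp <- fu_ddd <- rep(NA_real_, n)
  fu_supp <- rep(NA, n)
  fu_ncl <- rep(NA_real_, n)
  surg <- management == "surgery"
  med <- management == "medical"

  # biochemical outcome category, conditional on truth (surgery only)
  pb <- matrix(rep(cfg$p_biochem_surgery_bilateral, each = n), n, 3)
  pb[uni, ] <- matrix(rep(cfg$p_biochem_surgery_unilateral, each = sum(uni)),
                      sum(uni), 3)
  bcat <- c("complete", "partial", "absent")[sample_rows(pb)]

  i <- surg & bcat == "complete"
  fu_renin[i] <- stats::runif(sum(i), 0.6, 2.5)
  fu_ald[i] <- stats::runif(sum(i), 80, 400)
  fu_k[i] <- stats::runif(sum(i), 3.6, 4.6)
  fu_supp[i] <- FALSE
  i <- surg & bcat == "partial"
  fu_renin[i] <- stats::runif(sum(i), 0.05, 0.35)
  fu_ald[i] <- base_ald[i] * stats::runif(sum(i), 0.10, 0.45)
  fu_k[i] <- stats::runif(sum(i), 3.6, 4.6)
  fu_supp[i] <- FALSE
  i <- surg & bcat == "absent"
  fu_renin[i] <- stats::runif(sum(i), 0.05, 0.40)
  fu_ald[i] <- base_ald[i] * stats::runif(sum(i), 0.55, 1.05)
  fu_k[i] <- stats::runif(sum(i), 3.2, 4.2)
  fu_supp[i] <- fu_k[i] < 3.5 & stats::runif(sum(i)) < 0.5

  fu_sbp[surg] <- oldham_post(base_sbp, c_surg_sbp)[surg]
  fu_dbp[surg] <- pmin(oldham_post(base_dbp, c_surg_dbp),
                       oldham_post(base_sbp, c_surg_sbp) - 20)[surg]
  controlled <- surg & fu_sbp < 135 & fu_dbp < 85
  fu_ddd[surg] <- base_ddd[surg]
  withdraw <- controlled & stats::runif(n) < cfg$p_med_withdrawal
  fu_ddd[withdraw] <- 0
  reduce <- surg & !withdraw & stats::runif(n) < cfg$p_med_reduction
  fu_ddd[reduce] <- round(base_ddd[reduce] * stats::runif(sum(reduce), 0.3, 0.8), 1)
  fu_ncl[surg] <- pmax(0, base_ncl[surg] - ifelse(withdraw[surg], base_ncl[surg],
                                                  ifelse(reduce[surg], 1, 0)))

  c_med <- clamp(cfg$medical_sbp_change_mean +
                   cfg$medical_sbp_change_sd * stats::rnorm(n), -120, 80)
  fu_sbp[med] <- oldham_post(base_sbp, c_med)[med]
  fu_dbp[med] <- pmin(oldham_post(base_dbp, c_med * 0.8),
                      oldham_post(base_sbp, c_med) - 20)[med]
  fu_ald[med] <- base_ald[med] * stats::runif(sum(med), 1.0, 1.5)
  fu_renin[med] <- stats::runif(sum(med), 0.1, 0.9)
  fu_k[med] <- stats::runif(sum(med), 3.4, 4.4)
  fu_supp[med] <- FALSE
  fu_ddd[med] <- base_ddd[med] + 1   # spironolactone added
  fu_ncl[med] <- base_ncl[med] + 1

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    site = site, sex = sex, age = age, ethnicity = ethnicity,
    true_laterality = true_lat, genotype = genotype,
    clinical_indication = clinical_indication, management = management,
    avs_cortisol_left = cort_l, avs_cortisol_right = cort_r,
    avs_cortisol_ivc = c_ivc,
    avs_aldosterone_left = ald_l, avs_aldosterone_right = ald_r,
    avs_aldosterone_ivc = ald_ivc,
    avs_cannulated_left = TRUE, avs_cannulated_right = TRUE,
    mto_background_suvmax_left = bg_l, mto_background_suvmax_right = bg_r,
    mto_hu_left = mto_hu_left, mto_hu_right = mto_hu_right,
    mto_suvmax_left = mto_suv_left, mto_suvmax_right = mto_suv_right,
    mto_uptake_left = mto_up_left, mto_uptake_right = mto_up_right,
    baseline_aldosterone = base_ald, baseline_renin_activity = base_renin,
    baseline_renin_mass = base_renin / cfg$renin_conversion_factor,
    baseline_potassium = base_k,
    baseline_on_potassium_supplements = base_supp,
    baseline_sbp_home = base_sbp, baseline_dbp_home = base_dbp,
    baseline_ddd = base_ddd, baseline_n_classes = base_ncl,
    spiro_sbp_4wk = spiro_sbp_4wk,
    followup_aldosterone = fu_ald, followup_renin_activity = fu_renin,
    followup_renin_mass = fu_renin / cfg$renin_conversion_factor,
    followup_potassium = fu_k,
    followup_on_potassium_supplements = fu_supp,
    followup_sbp_home = fu_sbp, followup_dbp_home = fu_dbp,
    followup_ddd = fu_ddd, followup_n_classes = fu_ncl,
    stringsAsFactors = FALSE)
  cohort <- grade_cohort(cohort, criteria)
  cohort <- classify_cohort(cohort, paso)
  attr(cohort, "config") <- cfg
  cohort
}

# known column types, used to stabilize CSV round trips
.cohort_logical_cols <- c("clinical_indication", "avs_cannulated_left",
                          "avs_cannulated_right", "mto_uptake_left",
                          "mto_uptake_right", "baseline_on_potassium_supplements",
                          "followup_on_potassium_supplements", "h1", "h2", "h3", "h4")
.cohort_character_cols <- c("patient_id", "site", "sex", "ethnicity",
                            "true_laterality", "genotype", "management",
                            "mto_level", "mto_side", "avs_level", "avs_side",
                            "biochem_level", "clinical_level")

#' Write a cohort table to CSV
#'
#' Numeric columns are written with 17 significant digits so that reading
#' the file back reproduces the doubles exactly. When the cohort was
#' generated synthetically a comment header records the generator seed.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (cl in names(out))
    if (is.numeric(out[[cl]]))
      out[[cl]] <- ifelse(is.na(out[[cl]]), NA_character_,
                          sprintf("%.17g", out[[cl]]))
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(cohort, "config")
  if (!is.null(cfg) && !is.null(cfg$seed))
    writeLines(sprintf("# synthetic cohort generated by lateralize; seed=%d",
                       cfg$seed), con)
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path File written by [write_cohort()] (or any CSV using the same
#'   column naming convention).
#' @return Cohort data frame with stable column types.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", na.strings = c("", "NA"),
                       stringsAsFactors = FALSE)
  for (cl in intersect(.cohort_logical_cols, names(x)))
    x[[cl]] <- as.logical(x[[cl]])
  for (cl in intersect(.cohort_character_cols, names(x)))
    x[[cl]] <- as.character(x[[cl]])
  for (cl in setdiff(names(x), c(.cohort_logical_cols, .cohort_character_cols)))
    x[[cl]] <- as.numeric(x[[cl]])
  x
}

#' Write / read a cohort as JSON
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(cohort, path, dataframe = "rows", na = "null",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort_json
#' @export
read_cohort_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (cl in intersect(.cohort_logical_cols, names(x)))
    x[[cl]] <- as.logical(x[[cl]])
  x
}
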