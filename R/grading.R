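# Deterministic grading of adrenal vein sampling (AVS) and metomidate
# PET-CT (MTO) into high / intermediate / low probability of unilateral
# primary aldosteronism, and the MDT rule mapping two grades to a
# management recommendation.

#' Grading criteria for AVS and MTO
#'
#' Thresholds used by [grade_avs()] and [grade_mto()]. Defaults follow the
#' consensus rules: adrenal-to-peripheral cortisol (selectivity index)
#' must be at least 3 on both sides for AVS to count as successful; a
#' lateralization index of at least 4 grades high, below 3 grades low, and
#' the band `[3, 4)` is intermediate; a tumor-to-background SUVmax ratio
#' strictly above 1.25 indicates a functional nodule. The Hounsfield-unit
#' cutoff for a benign (lipid-rich) adenoma on unenhanced CT is not fixed
#' by consensus and is therefore configurable; 10 HU is the usual
#' radiological convention.
#'
#' @param si_threshold Minimum selectivity index (inclusive), default 3.
#' @param li_high Lateralization index grading high (inclusive), default 4.
#' @param li_low Lateralization index below which the grade is low, default 3.
#' @param suv_ratio_threshold SUVmax ratio grading high (exclusive), default 1.25.
#' @param benign_hu_max Maximum Hounsfield units for a benign nodule, default 10.
#' @return A list of class `grading_criteria`.
#' @export
grading_criteria <- function(si_threshold = 3, li_high = 4, li_low = 3,
                             suv_ratio_threshold = 1.25, benign_hu_max = 10) {
  stopifnot(si_threshold > 0, li_high > 0, li_low > 0, li_low <= li_high,
            suv_ratio_threshold > 0)
  structure(list(si_threshold = si_threshold, li_high = li_high,
                 li_low = li_low, suv_ratio_threshold = suv_ratio_threshold,
                 benign_hu_max = benign_hu_max),
            class = "grading_criteria")
}

#' Construct a test grade
#'
#' Three-level probability grade of unilateral disease assigned to one
#' investigation ("failed" is reserved for AVS). Low and failed grades
#' carry no side.
#'
#' @param level "high", "intermediate", "low" or "failed".
#' @param side "left", "right" or "none".
#' @param indices Named list of the ratios behind the grade.
#' @param reason Optional free-text note (e.g. failure reason).
#' @return A list of class `test_grade`.
#' @export
test_grade <- function(level, side = "none", indices = list(), reason = NULL) {
  new_test_grade(level, side, indices, reason)
}

new_test_grade <- function(level, side, indices, reason = NULL) {
  level <- match.arg(level, c("high", "intermediate", "low", "failed"))
  side <- match.arg(side, c("left", "right", "none"))
  if (level %in% c("low", "failed") && side != "none")
    stop("low or failed grades carry no side")
  structure(list(level = level, side = side, indices = indices,
                 reason = reason), class = "test_grade")
}

#' @export
print.test_grade <- function(x, ...) {
  cat(sprintf("grade: %s%s\n", x$level,
              if (x$side != "none") paste0(" (", x$side, ")") else ""))
  if (length(x$indices))
    cat(paste(sprintf("  %s = %.3g", names(x$indices), unlist(x$indices)),
              collapse = "\n"), "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' One adrenal vein sampling run
#'
#' Raw per-site measurements from which an AVS grade is derived. Cortisol
#' in nmol/L, aldosterone in pmol/L; `_ivc` values are peripheral
#' (iliac / infrarenal inferior vena cava).
#'
#' @param cortisol_left,cortisol_right,cortisol_ivc Cortisol per site.
#' @param aldosterone_left,aldosterone_right,aldosterone_ivc Aldosterone per site.
#' @param cannulated_left,cannulated_right Whether each adrenal vein was entered.
#' @return A list of class `avs_run`.
#' @export
avs_run <- function(cortisol_left, cortisol_right, cortisol_ivc,
                    aldosterone_left, aldosterone_right, aldosterone_ivc,
                    cannulated_left = TRUE, cannulated_right = TRUE) {
  vals <- c(cortisol_left, cortisol_right, cortisol_ivc,
            aldosterone_left, aldosterone_right, aldosterone_ivc)
  if (any(!is.na(vals) & vals <= 0))
    stop("all AVS concentrations must be positive where present")
  structure(list(cortisol_left = cortisol_left, cortisol_right = cortisol_right,
                 cortisol_ivc = cortisol_ivc, aldosterone_left = aldosterone_left,
                 aldosterone_right = aldosterone_right,
                 aldosterone_ivc = aldosterone_ivc,
                 cannulated_left = isTRUE(cannulated_left),
                 cannulated_right = isTRUE(cannulated_right)),
            class = "avs_run")
}

#' One metomidate PET-CT scan
#'
#' @param nodules List of nodules, each a list with elements `side`
#'   ("left"/"right"), `hu` (unenhanced CT density, Hounsfield units),
#'   `suvmax` (g/mL) and `uptake` (logical: visible metomidate uptake).
#' @param background_suvmax_left,background_suvmax_right SUVmax of normal
#'   adrenal tissue on each side (g/mL).
#' @return A list of class `mto_scan`.
#' @export
mto_scan <- function(nodules = list(), background_suvmax_left,
                     background_suvmax_right) {
  for (nd in nodules) {
    stopifnot(nd$side %in% c("left", "right"))
    if (!is.na(nd$suvmax) && nd$suvmax <= 0) stop("nodule suvmax must be positive")
  }
  structure(list(nodules = nodules,
                 background_suvmax_left = background_suvmax_left,
                 background_suvmax_right = background_suvmax_right),
            class = "mto_scan")
}

#' Selectivity index of an adrenal vein sample
#'
#' Ratio of adrenal-vein to peripheral cortisol. A value at or above the
#' criteria threshold (default 3) confirms successful cannulation.
#'
#' @param adrenal_cortisol Adrenal-vein cortisol (nmol/L).
#' @param peripheral_cortisol Peripheral (IVC/iliac) cortisol (nmol/L).
#' @return The ratio `adrenal_cortisol / peripheral_cortisol`.
#' @export
selectivity_index <- function(adrenal_cortisol, peripheral_cortisol) {
  if (any(is.na(adrenal_cortisol)) || any(is.na(peripheral_cortisol)) ||
      any(adrenal_cortisol <= 0) || any(peripheral_cortisol <= 0))
    stop("invalid sample: cortisol values must be positive")
  adrenal_cortisol / peripheral_cortisol
}

#' Grade an AVS run
#'
#' The run is `failed` unless both adrenal veins were cannulated with a
#' selectivity index at or above `criteria$si_threshold`. For successful
#' runs the lateralization index (LI) is the larger of the two ratios of
#' side-specific aldosterone/cortisol ratios; `LI >= li_high` grades high
#' with the dominant side, `LI < li_low` grades low (bilateral secretion)
#' and the band between is intermediate.
#'
#' @param run An [avs_run()].
#' @param criteria A [grading_criteria()].
#' @return A `test_grade` with the computed indices.
#' @export
grade_avs <- function(run, criteria = grading_criteria()) {
  stopifnot(inherits(run, "avs_run"))
  needed <- c("cortisol_left", "cortisol_right", "cortisol_ivc",
              "aldosterone_left", "aldosterone_right")
  missing <- vapply(run[needed], function(v) is.null(v) || is.na(v), logical(1))
  if (any(missing))
    return(new_test_grade("failed", "none", list(),
                          reason = paste("missing:", paste(needed[missing], collapse = ", "))))
  si_l <- selectivity_index(run$cortisol_left, run$cortisol_ivc)
  si_r <- selectivity_index(run$cortisol_right, run$cortisol_ivc)
  idx <- list(selectivity_left = si_l, selectivity_right = si_r)
  if (!run$cannulated_left || !run$cannulated_right ||
      si_l < criteria$si_threshold || si_r < criteria$si_threshold)
    return(new_test_grade("failed", "none", idx,
                          reason = "unsuccessful cannulation (selectivity index below threshold)"))
  ac_l <- run$aldosterone_left / run$cortisol_left
  ac_r <- run$aldosterone_right / run$cortisol_right
  li <- max(ac_l / ac_r, ac_r / ac_l)
  dominant <- if (ac_l >= ac_r) "left" else "right"
  idx$lateralization_index <- li
  if (li >= criteria$li_high) new_test_grade("high", dominant, idx)
  else if (li < criteria$li_low) new_test_grade("low", "none", idx)
  else new_test_grade("intermediate", dominant, idx)
}

#' Grade an MTO scan
#'
#' Three features are assessed for the dominant (highest-SUVmax) nodule on
#' each side: benign CT density (`hu <= benign_hu_max`), visible
#' metomidate uptake, and a SUVmax ratio to the contralateral background
#' strictly above `suv_ratio_threshold`. A side meeting all three grades
#' high; if both sides meet the rule the signal is bilateral and the grade
#' is downgraded to intermediate; a side meeting some but not all features
#' grades intermediate; otherwise the grade is low.
#'
#' @param scan An [mto_scan()].
#' @param criteria A [grading_criteria()].
#' @return A `test_grade` with the SUV ratio indices.
#' @export
grade_mto <- function(scan, criteria = grading_criteria()) {
  stopifnot(inherits(scan, "mto_scan"))
  bg <- c(left = scan$background_suvmax_left, right = scan$background_suvmax_right)
  if (any(is.na(bg)) || any(bg <= 0))
    stop("ungradable scan: background SUVmax required on both sides")
  side_info <- lapply(c(left = "left", right = "right"), function(s) {
    nds <- Filter(function(nd) identical(nd$side, s), scan$nodules)
    if (!length(nds)) return(NULL)
    nds[[which.max(vapply(nds, function(nd) nd$suvmax, numeric(1)))]]
  })
  contra <- c(left = "right", right = "left")
  feats <- lapply(c("left", "right"), function(s) {
    nd <- side_info[[s]]
    if (is.null(nd)) return(list(ratio = NA_real_, n_feat = 0L, all = FALSE))
    ratio <- nd$suvmax / bg[[contra[[s]]]]
    f <- c(benign = !is.na(nd$hu) && nd$hu <= criteria$benign_hu_max,
           uptake = isTRUE(nd$uptake),
           ratio = ratio > criteria$suv_ratio_threshold)
    list(ratio = ratio, n_feat = sum(f), all = all(f))
  })
  names(feats) <- c("left", "right")
  idx <- list(suv_ratio_left = feats$left$ratio, suv_ratio_right = feats$right$ratio)
  high <- vapply(feats, function(f) f$all, logical(1))
  best <- if (isTRUE(idx$suv_ratio_right > idx$suv_ratio_left) ||
              (is.na(idx$suv_ratio_left) && !is.na(idx$suv_ratio_right))) "right" else "left"
  if (all(high))       # bilateral uptake: downgrade
    new_test_grade("intermediate", best, idx, reason = "bilateral signal")
  else if (any(high))
    new_test_grade("high", names(which(high)), idx)
  else if (any(vapply(feats, function(f) f$n_feat > 0L, logical(1))))
    new_test_grade("intermediate", best, idx)
  else
    new_test_grade("low", "none", idx)
}

#' Multidisciplinary-team management decision
#'
#' Maps the two grades to a recommendation. Surgery is recommended if
#' either investigation graded high; when both grade high on opposite
#' sides the decision is deferred; when both grade intermediate, surgery
#' is recommended only on a strong clinical indication; otherwise the
#' recommendation is medical therapy. A failed AVS counts as non-high.
#'
#' @param mto,avs `test_grade` objects (AVS may be `failed`).
#' @param clinical_indication Logical: strong clinical indication for
#'   surgery (for example uncontrolled blood pressure or drug intolerance).
#' @return List with `management` ("surgery", "medical" or "deferred") and
#'   `side` ("left", "right" or NA).
#' @export
mdt_decision <- function(mto, avs, clinical_indication = FALSE) {
  stopifnot(inherits(mto, "test_grade"), inherits(avs, "test_grade"))
  m_high <- mto$level == "high"
  a_high <- avs$level == "high"
  if (m_high && a_high && mto$side != avs$side)
    return(list(management = "deferred", side = NA_character_))
  if (m_high || a_high)
    return(list(management = "surgery",
                side = if (m_high) mto$side else avs$side))
  if (mto$level == "intermediate" && avs$level == "intermediate" &&
      isTRUE(clinical_indication))
    return(list(management = "surgery", side = mto$side))
  list(management = "medical", side = NA_character_)
}

# ---- cohort-level wrappers over flat columns ------------------------------

avs_run_from_row <- function(row) {
  avs_run(row$avs_cortisol_left, row$avs_cortisol_right, row$avs_cortisol_ivc,
          row$avs_aldosterone_left, row$avs_aldosterone_right,
          row$avs_aldosterone_ivc,
          cannulated_left = isTRUE(row$avs_cannulated_left),
          cannulated_right = isTRUE(row$avs_cannulated_right))
}

mto_scan_from_row <- function(row) {
  nodules <- list()
  for (s in c("left", "right")) {
    suv <- row[[paste0("mto_suvmax_", s)]]
    if (!is.null(suv) && !is.na(suv))
      nodules[[length(nodules) + 1L]] <-
        list(side = s, hu = row[[paste0("mto_hu_", s)]], suvmax = suv,
             uptake = isTRUE(row[[paste0("mto_uptake_", s)]]))
  }
  mto_scan(nodules, row$mto_background_suvmax_left, row$mto_background_suvmax_right)
}

#' Grade every patient in a cohort table
#'
#' Applies [grade_mto()] and [grade_avs()] to the flat raw-measurement
#' columns of a cohort data frame (one row per patient, columns as written
#' by [generate_cohort()] / [read_cohort()]), appending grade and index
#' columns. The MTO grade is computed from the scan columns alone, before
#' and independently of the AVS columns.
#'
#' @param cohort Cohort data frame with raw AVS and MTO columns.
#' @param criteria A [grading_criteria()].
#' @return `cohort` with columns `mto_level`, `mto_side`, `mto_suv_ratio`,
#'   `avs_level`, `avs_side`, `avs_li`, `avs_si_left`, `avs_si_right`.
#' @export
grade_cohort <- function(cohort, criteria = grading_criteria()) {
  n <- nrow(cohort)
  m_lv <- m_sd <- a_lv <- a_sd <- character(n)
  m_r <- a_li <- a_sl <- a_sr <- numeric(n)
  for (i in seq_len(n)) {
    row <- cohort[i, , drop = FALSE]
    gm <- grade_mto(mto_scan_from_row(row), criteria)
    ga <- grade_avs(avs_run_from_row(row), criteria)
    m_lv[i] <- gm$level; m_sd[i] <- gm$side
    rat <- c(gm$indices$suv_ratio_left, gm$indices$suv_ratio_right)
    m_r[i] <- if (all(is.na(rat))) NA_real_ else max(rat, na.rm = TRUE)
    a_lv[i] <- ga$level; a_sd[i] <- ga$side
    a_li[i] <- if (is.null(ga$indices$lateralization_index)) NA_real_ else ga$indices$lateralization_index
    a_sl[i] <- if (is.null(ga$indices$selectivity_left)) NA_real_ else ga$indices$selectivity_left
    a_sr[i] <- if (is.null(ga$indices$selectivity_right)) NA_real_ else ga$indices$selectivity_right
  }
  cohort$mto_level <- m_lv; cohort$mto_side <- m_sd; cohort$mto_suv_ratio <- m_r
  cohort$avs_level <- a_lv; cohort$avs_side <- a_sd; cohort$avs_li <- a_li
  cohort$avs_si_left <- a_sl; cohort$avs_si_right <- a_sr
  cohort
}
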