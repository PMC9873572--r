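# PASO (primary aldosteronism surgical outcome) classification of
# post-adrenalectomy success, in the biochemical and clinical domains,
# and the four hierarchical endpoints built from them.

#' PASO outcome criteria
#'
#' Thresholds for classifying post-treatment outcomes as complete, partial
#' or absent success in each of the biochemical and clinical domains.
#' Defaults encode the consensus rules: complete clinical success is a
#' home blood pressure below 135/85 mmHg off all antihypertensives;
#' partial clinical success is a fall of at least 20/10 mmHg without more
#' medication, or no worse blood pressure on a reduced medication load.
#' Complete biochemical success is normokalemia without supplements plus a
#' normalized aldosterone-to-renin ratio (ARR) with de-suppressed renin;
#' partial biochemical success is corrected potassium with an aldosterone
#' fall of at least 50% while the ARR criteria are still unmet. All
#' thresholds are configurable so users can align them with local
#' laboratory reference ranges; the defaults are consensus-derived, not a
#' verbatim rule book.
#'
#' @param complete_sbp,complete_dbp Absolute home BP targets (mmHg) for
#'   complete clinical success (strict `<`), defaults 135/85.
#' @param partial_sbp_drop,partial_dbp_drop Minimum BP falls (mmHg) for
#'   partial clinical success (inclusive), defaults 20/10.
#' @param arr_threshold ARR (pmol/L per nmol/L/h) below which the ratio
#'   counts as normalized, default 1000.
#' @param renin_desuppressed_min Minimum renin activity (nmol/L/h) counting
#'   as measurable / de-suppressed, default 0.5 (lower limit of the
#'   reference range).
#' @param aldosterone_fall_min Minimum fractional aldosterone fall for
#'   partial biochemical success, default 0.5.
#' @param potassium_range Normal serum potassium range (mmol/L).
#' @param renin_conversion_factor Factor converting renin mass (mU/L) to
#'   activity (nmol/L/h) when only mass was measured; the default 0.1 is a
#'   documented placeholder, not an assay constant - set it to the factor
#'   of your laboratory.
#' @return A list of class `paso_criteria`.
#' @export
paso_criteria <- function(complete_sbp = 135, complete_dbp = 85,
                          partial_sbp_drop = 20, partial_dbp_drop = 10,
                          arr_threshold = 1000, renin_desuppressed_min = 0.5,
                          aldosterone_fall_min = 0.5,
                          potassium_range = c(3.5, 5.3),
                          renin_conversion_factor = 0.1) {
  stopifnot(complete_sbp > 0, complete_dbp > 0, partial_sbp_drop > 0,
            partial_dbp_drop > 0, arr_threshold > 0,
            renin_desuppressed_min > 0, aldosterone_fall_min > 0,
            aldosterone_fall_min <= 1, length(potassium_range) == 2,
            potassium_range[1] < potassium_range[2],
            renin_conversion_factor > 0)
  structure(list(complete_sbp = complete_sbp, complete_dbp = complete_dbp,
                 partial_sbp_drop = partial_sbp_drop,
                 partial_dbp_drop = partial_dbp_drop,
                 arr_threshold = arr_threshold,
                 renin_desuppressed_min = renin_desuppressed_min,
                 aldosterone_fall_min = aldosterone_fall_min,
                 potassium_range = potassium_range,
                 renin_conversion_factor = renin_conversion_factor),
            class = "paso_criteria")
}

new_outcome3 <- function(level, domain, evaluable = TRUE) {
  if (evaluable) level <- match.arg(level, c("complete", "partial", "absent"))
  else level <- NA_character_
  structure(list(level = level, domain = domain, evaluable = evaluable),
            class = "outcome3")
}

#' @export
print.outcome3 <- function(x, ...) {
  cat(sprintf("%s success: %s\n", x$domain,
              if (x$evaluable) x$level else "not evaluable"))
  invisible(x)
}

visit_field <- function(visit, field) {
  v <- visit[[field]]
  if (is.null(v)) NA else v
}

renin_activity_of <- function(visit, criteria) {
  act <- visit_field(visit, "renin_activity")
  if (!is.na(act)) return(act)
  mass <- visit_field(visit, "renin_mass")
  if (is.na(mass)) return(NA_real_)
  renin_mass_to_activity(mass, criteria$renin_conversion_factor)
}

#' Classify the clinical PASO outcome
#'
#' @param baseline,followup Visits: lists (or one-row data frames) with at
#'   least `sbp_home`, `dbp_home` and `ddd` fields.
#' @param criteria A [paso_criteria()].
#' @return An `outcome3` for the clinical domain; not evaluable when
#'   follow-up blood pressure or medication load is missing.
#' @export
classify_clinical <- function(baseline, followup, criteria = paso_criteria()) {
  sb <- visit_field(baseline, "sbp_home"); db <- visit_field(baseline, "dbp_home")
  sf <- visit_field(followup, "sbp_home"); df <- visit_field(followup, "dbp_home")
  d0 <- visit_field(baseline, "ddd"); d1 <- visit_field(followup, "ddd")
  if (any(is.na(c(sf, df, d1))))
    return(new_outcome3(NA_character_, "clinical", evaluable = FALSE))
  if (sf < criteria$complete_sbp && df < criteria$complete_dbp && d1 == 0)
    return(new_outcome3("complete", "clinical"))
  if (!any(is.na(c(sb, db, d0)))) {
    dropped <- (sb - sf) >= criteria$partial_sbp_drop &&
               (db - df) >= criteria$partial_dbp_drop && d1 <= d0
    reduced <- d1 < d0 && sf <= sb && df <= db
    if (dropped || reduced) return(new_outcome3("partial", "clinical"))
  }
  new_outcome3("absent", "clinical")
}

#' Classify the biochemical PASO outcome
#'
#' @param baseline,followup Visits with `aldosterone`, `potassium`,
#'   `on_potassium_supplements` and renin (`renin_activity` or
#'   `renin_mass`) fields.
#' @param criteria A [paso_criteria()].
#' @return An `outcome3` for the biochemical domain; not evaluable when
#'   follow-up aldosterone, potassium or renin is missing.
#' @export
classify_biochemical <- function(baseline, followup, criteria = paso_criteria()) {
  a0 <- visit_field(baseline, "aldosterone")
  a1 <- visit_field(followup, "aldosterone")
  k1 <- visit_field(followup, "potassium")
  r1 <- renin_activity_of(followup, criteria)
  if (any(is.na(c(a1, k1, r1))))
    return(new_outcome3(NA_character_, "biochemical", evaluable = FALSE))
  supp <- isTRUE(visit_field(followup, "on_potassium_supplements"))
  k_norm <- k1 >= criteria$potassium_range[1] & k1 <= criteria$potassium_range[2]
  arr <- a1 / r1
  if (k_norm && !supp && arr < criteria$arr_threshold &&
      r1 >= criteria$renin_desuppressed_min)
    return(new_outcome3("complete", "biochemical"))
  if (!is.na(a0) && k_norm && a1 <= (1 - criteria$aldosterone_fall_min) * a0)
    return(new_outcome3("partial", "biochemical"))
  new_outcome3("absent", "biochemical")
}

#' Hierarchical endpoint booleans from the two domain outcomes
#'
#' The four co-primary endpoints, in hierarchical order: h1
#' partial-or-complete biochemical, h2 complete biochemical, h3
#' partial-or-complete clinical, h4 complete clinical. Success at one limb
#' does not require success at the previous limb; an unevaluable domain
#' yields `NA` for its two limbs.
#'
#' @param biochem,clinical `outcome3` objects from
#'   [classify_biochemical()] and [classify_clinical()].
#' @return Named logical vector `c(h1, h2, h3, h4)`.
#' @export
hierarchical_endpoints <- function(biochem, clinical) {
  stopifnot(inherits(biochem, "outcome3"), inherits(clinical, "outcome3"))
  if (!biochem$evaluable && !clinical$evaluable)
    stop("no endpoint: both domains unevaluable")
  lim <- function(o, complete_only) {
    if (!o$evaluable) return(NA)
    if (complete_only) o$level == "complete"
    else o$level %in% c("complete", "partial")
  }
  c(h1 = lim(biochem, FALSE), h2 = lim(biochem, TRUE),
    h3 = lim(clinical, FALSE), h4 = lim(clinical, TRUE))
}

visit_from_row <- function(row, prefix) {
  fields <- c("aldosterone", "renin_activity", "renin_mass", "potassium",
              "sbp_home", "dbp_home", "ddd", "n_classes",
              "on_potassium_supplements")
  v <- lapply(fields, function(f) {
    col <- paste0(prefix, "_", f)
    if (col %in% names(row)) row[[col]] else NA
  })
  names(v) <- fields
  v
}

#' Classify outcomes for every patient in a cohort table
#'
#' Applies [classify_biochemical()] and [classify_clinical()] to the
#' `baseline_*` / `followup_*` columns and appends the domain levels and
#' the four hierarchical endpoint columns `h1`..`h4` (NA where a domain is
#' unevaluable, e.g. for deferred patients without follow-up).
#'
#' @param cohort Cohort data frame.
#' @param criteria A [paso_criteria()].
#' @return `cohort` with columns `biochem_level`, `clinical_level`,
#'   `h1`, `h2`, `h3`, `h4`.
#' @export
classify_cohort <- function(cohort, criteria = paso_criteria()) {
  n <- nrow(cohort)
  bl <- cl <- character(n)
  h <- matrix(NA, n, 4, dimnames = list(NULL, c("h1", "h2", "h3", "h4")))
  for (i in seq_len(n)) {
    row <- cohort[i, , drop = FALSE]
    base <- visit_from_row(row, "baseline")
    fu <- visit_from_row(row, "followup")
    b <- classify_biochemical(base, fu, criteria)
    k <- classify_clinical(base, fu, criteria)
    bl[i] <- b$level; cl[i] <- k$level
    if (b$evaluable || k$evaluable) h[i, ] <- hierarchical_endpoints(b, k)
  }
  cohort$biochem_level <- bl
  cohort$clinical_level <- cl
  cohort$h1 <- h[, 1]; cohort$h2 <- h[, 2]; cohort$h3 <- h[, 3]; cohort$h4 <- h[, 4]
  cohort
}
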