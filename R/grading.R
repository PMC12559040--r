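# The adapted 2016 ASE/EACVI decision tree. Two steps: a 4-criterion
# diagnosis step (for subjects with preserved EF and no myocardial disease)
# and a 3-criterion grading step. All cutoff comparisons are strict, exactly
# as the thresholds are printed (E > 50 cm/s, LAVI > 34 mL/m^2, ...); the
# complementary branches of the grading step use <= / >= so ties classify
# deterministically on the non-positive side.

criterion_status <- function(positive) if (positive) "positive" else "negative"

#' Evaluate the diagnosis-step criteria
#'
#' The four criteria of the dysfunction-diagnosis step: elevated average
#' E/e', reduced e' (septal **or** lateral below its cutoff — one criterion,
#' not two), elevated pulmonary arterial pressure (TR for echo, t_vortex for
#' 4D flow), and enlarged left atrium (LAVI). For echocardiography an absent
#' TR marks the pressure criterion `unavailable` (not negative): tricuspid
#' regurgitation is frequently undetectable. The 4D flow surrogate t_vortex
#' is always measurable, so the 4D arm never has unavailable criteria.
#'
#' @param m measurement list for one arm (see [arm_measurements()] fields:
#'   `ef`, `lavi`, `e_peak`, `a_peak`, `e_prime_septal`, `e_prime_lateral`,
#'   `tr_peak` or `t_vortex`), with absent values `NULL`.
#' @param cutoffs a `dd_cutoffs` object of the matching modality.
#' @return Named character vector of statuses in
#'   `{"positive","negative","unavailable"}` for criteria
#'   `avg_E_over_eprime`, `reduced_eprime`, `elevated_pa_pressure`,
#'   `enlarged_la`.
#' @export
evaluate_diagnosis_criteria <- function(m, cutoffs) {
  ee <- e_over_eprime(m)
  if (is.null(m$e_peak)) stop("E peak velocity is missing")
  if (is.null(m$e_prime_septal) && is.null(m$e_prime_lateral)) {
    stop("both septal and lateral e' are missing")
  }
  if (is.null(m$lavi)) stop("LAVI is missing")

  reduced <- (!is.null(m$e_prime_septal) &&
                m$e_prime_septal < cutoffs$e_prime_septal_low) ||
             (!is.null(m$e_prime_lateral) &&
                m$e_prime_lateral < cutoffs$e_prime_lateral_low)

  pa <- if (cutoffs$modality == "echo") {
    if (is.null(m$tr_peak)) "unavailable"
    else criterion_status(m$tr_peak > cutoffs$tr_high)
  } else {
    if (is.null(m$t_vortex)) stop("t_vortex is missing for the 4D flow arm")
    criterion_status(m$t_vortex > cutoffs$tvortex_high)
  }

  c(avg_E_over_eprime = criterion_status(ee > cutoffs$e_over_eprime_high),
    reduced_eprime = criterion_status(reduced),
    elevated_pa_pressure = pa,
    enlarged_la = criterion_status(m$lavi > cutoffs$lavi_high))
}

#' Majority rule over available diagnosis criteria
#'
#' Over the available criteria: more than half positive means diastolic
#' dysfunction, exactly half is indeterminate, fewer than half is normal
#' diastolic function.
#'
#' @param criteria named status vector from [evaluate_diagnosis_criteria()].
#' @return One of `"normal"`, `"indeterminate"`, `"dysfunction"`.
#' @export
diagnose <- function(criteria) {
  avail <- criteria != "unavailable"
  n_avail <- sum(avail)
  if (n_avail < 2) stop("fewer than 2 available diagnosis criteria")
  n_pos <- sum(criteria[avail] == "positive")
  if (n_pos * 2 > n_avail) "dysfunction"
  else if (n_pos * 2 == n_avail) "indeterminate"
  else "normal"
}

#' Grade established diastolic dysfunction
#'
#' The grading step of the tree: E/A <= 0.8 with E <= 50 cm/s is grade 1
#' (impaired relaxation); E/A >= 2.0 is grade 3 (restrictive filling); in
#' between, three criteria (elevated average E/e', elevated pulmonary
#' arterial pressure, enlarged LA) decide — at least two positive gives
#' grade 2 (pseudonormal), at least two negative grade 1, and a 1-vs-1 split
#' with the third unavailable (or fewer than two available) is
#' indeterminate.
#'
#' @inheritParams evaluate_diagnosis_criteria
#' @return A grade label (`"grade1"`, `"grade2"`, `"grade3"` or
#'   `"indeterminate"`).
#' @export
grade_dysfunction <- function(m, cutoffs) {
  ea <- e_over_a(m)
  if (is.null(ea)) stop("E/A undefined (A peak absent or zero); cannot grade")
  if (ea <= cutoffs$ea_low && m$e_peak <= cutoffs$e_high) return("grade1")
  if (ea >= cutoffs$ea_high) return("grade3")
  crit <- evaluate_diagnosis_criteria(m, cutoffs)
  crit <- crit[c("avg_E_over_eprime", "elevated_pa_pressure", "enlarged_la")]
  n_pos <- sum(crit == "positive")
  n_neg <- sum(crit == "negative")
  if (n_pos >= 2) "grade2"
  else if (n_neg >= 2) "grade1"
  else "indeterminate"
}

#' Grade one subject's diastolic function
#'
#' Full routing of the adapted algorithm: subjects with depressed EF (below
#' the modality-specific routing threshold) or known myocardial disease
#' enter the grading step directly; all others pass through the 4-criterion
#' diagnosis step first — normal and indeterminate diagnoses are terminal,
#' and a dysfunction diagnosis proceeds to grading. A subject who reaches
#' grading through a positive diagnosis receives at minimum grade 1 (an
#' indeterminate 3-criterion split cannot demote an established diagnosis).
#'
#' @param record one cohort row (single-row `data.frame` or list with the
#'   cohort columns).
#' @param modality `"echo"` or `"flow4d"`.
#' @param cutoffs a `dd_cutoffs` object; defaults to
#'   `default_cutoffs(modality)`.
#' @return A grade label (see [grade_levels()]).
#' @export
#' @examples
#' rec <- list(subject_id = "s1", myocardial_disease = FALSE,
#'             echo_ef = 62, echo_lavi = 30, echo_e = 70, echo_a = 60,
#'             echo_e_prime_septal = 9, echo_e_prime_lateral = 12,
#'             echo_tr = 2.0, flow_ef = 67, flow_lavi = 43, flow_e = 70,
#'             flow_a = 60, flow_e_prime_septal = 9,
#'             flow_e_prime_lateral = 12, flow_t_vortex = 2)
#' grade_subject(rec, "echo")
grade_subject <- function(record, modality = c("echo", "flow4d"),
                          cutoffs = default_cutoffs(modality)) {
  modality <- match.arg(modality)
  if (cutoffs$modality != modality) {
    stop("cutoff set is for modality '", cutoffs$modality, "'")
  }
  m <- arm_measurements(record, modality)
  if (is.null(m$ef)) stop("EF is missing")
  disease <- isTRUE(as_flag(record[["myocardial_disease"]]))

  if (m$ef < cutoffs$ef_low || disease) {
    return(grade_dysfunction(m, cutoffs))
  }
  dx <- diagnose(evaluate_diagnosis_criteria(m, cutoffs))
  if (dx == "normal") return("normal")
  if (dx == "indeterminate") return("indeterminate")
  g <- grade_dysfunction(m, cutoffs)
  if (g == "indeterminate") "grade1" else g
}

#' Grade every subject of a cohort
#'
#' Vectorised wrapper around [grade_subject()] that also records the
#' evaluated criterion statuses as audit columns, so discordances between
#' modalities can be traced to the responsible criterion.
#'
#' @param cohort cohort `data.frame`.
#' @inheritParams grade_subject
#' @return `data.frame` with `subject_id`, `grade` (ordered factor) and one
#'   `crit_*` status column per diagnosis criterion.
#' @export
grade_cohort <- function(cohort, modality = c("echo", "flow4d"),
                         cutoffs = default_cutoffs(modality)) {
  modality <- match.arg(modality)
  n <- nrow(cohort)
  grades <- character(n)
  crit <- matrix(NA_character_, n, 4,
                 dimnames = list(NULL, c("avg_E_over_eprime", "reduced_eprime",
                                         "elevated_pa_pressure", "enlarged_la")))
  for (i in seq_len(n)) {
    row <- cohort[i, , drop = FALSE]
    grades[i] <- tryCatch(grade_subject(row, modality, cutoffs),
      error = function(e) stop("subject ", row$subject_id, ": ",
                               conditionMessage(e), call. = FALSE))
    crit[i, ] <- tryCatch(
      evaluate_diagnosis_criteria(arm_measurements(row, modality), cutoffs),
      error = function(e) rep(NA_character_, 4))
  }
  out <- data.frame(subject_id = cohort$subject_id,
                    grade = as_grade(grades), stringsAsFactors = FALSE)
  colnames(crit) <- paste0("crit_", colnames(crit))
  cbind(out, as.data.frame(crit, stringsAsFactors = FALSE))
}
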