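# Cohort tables: one row per subject, paired echo / 4D flow measurements.
# Units are fixed per column (E, A, e' in cm/s; TR in m/s; t_vortex in % of
# the cardiac interval; EF in %; LAVI in mL/m^2); readers reject rather than
# convert, since the parameter set mixes cm/s and m/s by design.

cohort_columns <- function() {
  c("subject_id", "myocardial_disease",
    "echo_ef", "echo_lavi", "echo_e", "echo_a",
    "echo_e_prime_septal", "echo_e_prime_lateral", "echo_tr",
    "flow_ef", "flow_lavi", "flow_e", "flow_a",
    "flow_e_prime_septal", "flow_e_prime_lateral", "flow_t_vortex")
}

#' Read / write a paired cohort CSV
#'
#' The CSV dialect is comma-separated, UTF-8, `.` decimal, header required.
#' Required columns are `subject_id`, `myocardial_disease`, the echo
#' measurement columns (`echo_ef`, `echo_lavi`, `echo_e`, `echo_a`,
#' `echo_e_prime_septal`, `echo_e_prime_lateral`, `echo_tr`) and their
#' `flow_*` counterparts with `flow_t_vortex` in place of a TR column; an
#' optional `true_grade` column carries the intended grade of synthetic
#' subjects. Empty cells are missing values; missingness of `echo_tr` is
#' clinically meaningful (tricuspid regurgitation not detectable) and is
#' preserved as `NA`, never as a sentinel number.
#'
#' @param path file path.
#' @param cohort a cohort `data.frame` as returned by [simulate_cohort()] or
#'   [read_cohort()].
#' @return `read_cohort`: a `data.frame` of class `dd_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df$myocardial_disease <- as_flag(df$myocardial_disease)
  num_cols <- setdiff(cohort_columns(), c("subject_id", "myocardial_disease"))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      suppressWarnings(v <- as.numeric(df[[cc]]))
      if (any(!is.na(df[[cc]]) & is.na(v))) {
        stop("non-numeric values in column ", cc)
      }
      df[[cc]] <- v
    }
  }
  if ("true_grade" %in% names(df)) df$true_grade <- as.character(df$true_grade)
  class(df) <- c("dd_cohort", "data.frame")
  df
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out) & !is.na(x))) stop("myocardial_disease must be logical/0/1")
  out
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate one subject record
#'
#' Checks the domain invariants of a single cohort row: EF in \[0, 100\],
#' LAVI positive, velocities non-negative, t_vortex in \[0, 100\] and present
#' for the 4D flow arm; `echo_tr` may legally be absent (non-detectable
#' tricuspid regurgitation). Violations are returned as data, one message per
#' broken rule naming the offending field, so a caller can report all
#' problems at once; an empty character vector means the record is valid.
#'
#' @param record a single-row `data.frame` (or coercible list) with the
#'   cohort columns.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_record <- function(record) {
  r <- as.list(record)
  v <- character(0)
  chk <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  present <- function(f) !is.null(r[[f]]) && length(r[[f]]) == 1 && !is.na(r[[f]])

  if (!present("subject_id") || !nzchar(as.character(r$subject_id))) {
    v <- c(v, "subject_id: must be a non-empty identifier")
  }
  if (!present("myocardial_disease") || !is.logical(as_flag(r$myocardial_disease))) {
    v <- c(v, "myocardial_disease: must be TRUE/FALSE")
  }
  for (arm in c("echo", "flow")) {
    ef <- paste0(arm, "_ef"); lavi <- paste0(arm, "_lavi")
    if (present(ef)) chk(r[[ef]] < 0 || r[[ef]] > 100,
                         paste0(ef, ": EF must lie in [0, 100]"))
    if (present(lavi)) chk(r[[lavi]] <= 0, paste0(lavi, ": LAVI must be > 0"))
    for (f in paste0(arm, c("_e", "_a", "_e_prime_septal", "_e_prime_lateral"))) {
      if (present(f)) chk(r[[f]] < 0, paste0(f, ": velocities must be >= 0"))
    }
  }
  if (present("echo_tr")) chk(r$echo_tr < 0, "echo_tr: velocities must be >= 0")
  if (!present("flow_t_vortex")) {
    v <- c(v, "flow_t_vortex: must be present for the 4D flow arm")
  } else {
    chk(r$flow_t_vortex < 0 || r$flow_t_vortex > 100,
        "flow_t_vortex: must lie in [0, 100]")
  }
  if (present("echo_a")) chk(r$echo_a == 0, "echo_a: zero A makes E/A undefined")
  v
}

#' Validate a whole cohort
#'
#' Applies [validate_record()] row-wise and additionally checks that
#' `subject_id` is unique within the cohort.
#'
#' @param cohort cohort `data.frame`.
#' @return Named list (by `subject_id`) of violation vectors, empty list if
#'   the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  dup <- duplicated(cohort$subject_id)
  for (i in seq_len(nrow(cohort))) {
    v <- validate_record(cohort[i, , drop = FALSE])
    if (dup[i]) v <- c(v, "subject_id: duplicated within cohort")
    if (length(v) > 0) out[[as.character(cohort$subject_id[i])]] <- v
  }
  out
}

# Extract one arm's measurement list from a cohort row. t_vortex is NULL for
# the echo arm; tr is NULL for the flow arm.
arm_measurements <- function(row, modality = c("echo", "flow4d")) {
  modality <- match.arg(modality)
  p <- if (modality == "echo") "echo_" else "flow_"
  g <- function(f) {
    val <- row[[paste0(p, f)]]
    if (is.null(val) || length(val) == 0 || is.na(val)) NULL else as.numeric(val)
  }
  list(
    ef = g("ef"), lavi = g("lavi"), e_peak = g("e"), a_peak = g("a"),
    e_prime_septal = g("e_prime_septal"),
    e_prime_lateral = g("e_prime_lateral"),
    tr_peak = if (modality == "echo") g("tr") else NULL,
    t_vortex = if (modality == "flow4d") g("t_vortex") else NULL
  )
}

# Average e' over available sites; E/e' and E/A helpers. Average e' uses the
# mean of septal and lateral sites when both are present, the available one
# otherwise.
avg_eprime <- function(m) {
  vals <- c(m$e_prime_septal, m$e_prime_lateral)
  if (length(vals) == 0) return(NULL)
  mean(vals)
}

e_over_eprime <- function(m) {
  ep <- avg_eprime(m)
  if (is.null(m$e_peak) || is.null(ep) || ep <= 0) return(NULL)
  m$e_peak / ep
}

e_over_a <- function(m) {
  if (is.null(m$e_peak) || is.null(m$a_peak) || m$a_peak <= 0) return(NULL)
  m$e_peak / m$a_peak
}
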