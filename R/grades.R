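#' Ordered diastolic function grades
#'
#' The five-level ordinal outcome of diastolic function assessment:
#' `normal` (grade 0) < `indeterminate` < `grade1` (impaired relaxation) <
#' `grade2` (pseudonormal) < `grade3` (restrictive). The `indeterminate`
#' category sits between normal and grade 1, matching the row/column order
#' of the 5x5 cross-classification used throughout the package.
#'
#' @return Character vector of the five grade labels, in order.
#' @export
grade_levels <- function() {
  c("normal", "indeterminate", "grade1", "grade2", "grade3")
}

#' Coerce to an ordered grade factor
#'
#' @param x character vector (or factor) of grade labels.
#' @return Ordered factor with levels `grade_levels()`.
#' @export
#' @examples
#' as_grade(c("normal", "grade2"))
as_grade <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% grade_levels())
  if (any(bad)) {
    stop("unknown grade label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = grade_levels(), ordered = TRUE)
}
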