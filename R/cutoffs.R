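#' Construct a grading cutoff set
#'
#' Bundles the complete set of thresholds the decision tree needs for one
#' modality. Velocity-type thresholds (E, E/A, e', E/e') are shared between
#' echocardiography and 4D flow in the default sets; the modalities differ in
#' the volumetric thresholds (EF, LAVI) and in the pulmonary-pressure slot:
#' echocardiography uses the tricuspid regurgitant peak velocity TR (m/s),
#' 4D flow the vortical-flow duration t_vortex (% of cardiac interval).
#'
#' @param modality `"echo"` or `"flow4d"`; controls which pressure slot must
#'   be populated.
#' @param ef_low depressed-EF routing threshold (%%), strict `<`.
#' @param lavi_high enlarged-LA threshold (mL/m^2), strict `>`.
#' @param e_high transmitral E threshold (cm/s), strict `>` (grade-1 branch
#'   uses `<=`).
#' @param ea_low,ea_high E/A branch thresholds (unitless), `<=` and `>=`.
#' @param e_prime_septal_low,e_prime_lateral_low reduced-e' thresholds
#'   (cm/s), strict `<`.
#' @param e_over_eprime_high average E/e' threshold (unitless), strict `>`.
#' @param tr_high TR threshold (m/s), echo only, strict `>`.
#' @param tvortex_high t_vortex threshold (%%), 4D flow only, strict `>`.
#' @return An object of class `dd_cutoffs` (named list).
#' @seealso [default_cutoffs()]
#' @export
grading_cutoffs <- function(modality = c("echo", "flow4d"),
                            ef_low, lavi_high, e_high,
                            ea_low, ea_high,
                            e_prime_septal_low, e_prime_lateral_low,
                            e_over_eprime_high,
                            tr_high = NULL, tvortex_high = NULL) {
  modality <- match.arg(modality)
  x <- list(
    modality = modality,
    ef_low = ef_low, lavi_high = lavi_high, e_high = e_high,
    ea_low = ea_low, ea_high = ea_high,
    e_prime_septal_low = e_prime_septal_low,
    e_prime_lateral_low = e_prime_lateral_low,
    e_over_eprime_high = e_over_eprime_high,
    tr_high = tr_high, tvortex_high = tvortex_high
  )
  if (modality == "echo") {
    if (is.null(tr_high) || !is.null(tvortex_high)) {
      stop("echo cutoffs require tr_high and must not set tvortex_high")
    }
  } else {
    if (is.null(tvortex_high) || !is.null(tr_high)) {
      stop("flow4d cutoffs require tvortex_high and must not set tr_high")
    }
  }
  num <- x[!(names(x) %in% "modality")]
  num <- num[!vapply(num, is.null, logical(1))]
  if (any(!vapply(num, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1)))) {
    stop("all thresholds must be single positive numbers")
  }
  if (x$ea_low >= x$ea_high) stop("ea_low must be < ea_high")
  structure(x, class = "dd_cutoffs")
}

#' Default grading cutoffs per modality
#'
#' The echocardiographic set carries the established 2016 ASE/EACVI
#' thresholds (EF 50%, LAVI 34 mL/m^2, E 50 cm/s, E/A 0.8 and 2.0, septal e'
#' 7 cm/s, lateral e' 10 cm/s, E/e' 14, TR 2.8 m/s). The 4D flow set keeps
#' the velocity thresholds unchanged (no significant inter-modality bias),
#' replaces the volumetric thresholds by their bias-adjusted equivalents
#' (EF 55%, LAVI 47 mL/m^2) and the TR threshold by the surrogate
#' t_vortex > 15%.
#'
#' @param modality `"echo"` or `"flow4d"`.
#' @return A `dd_cutoffs` object.
#' @export
#' @examples
#' default_cutoffs("echo")
#' default_cutoffs("flow4d")
default_cutoffs <- function(modality = c("echo", "flow4d")) {
  modality <- match.arg(modality)
  if (modality == "echo") {
    grading_cutoffs("echo",
      ef_low = 50, lavi_high = 34, e_high = 50,
      ea_low = 0.8, ea_high = 2.0,
      e_prime_septal_low = 7, e_prime_lateral_low = 10,
      e_over_eprime_high = 14, tr_high = 2.8)
  } else {
    grading_cutoffs("flow4d",
      ef_low = 55, lavi_high = 47, e_high = 50,
      ea_low = 0.8, ea_high = 2.0,
      e_prime_septal_low = 7, e_prime_lateral_low = 10,
      e_over_eprime_high = 14, tvortex_high = 15)
  }
}

#' @export
print.dd_cutoffs <- function(x, ...) {
  cat("Diastolic grading cutoffs (", x$modality, ")\n", sep = "")
  cat(sprintf("  EF < %g %%   LAVI > %g mL/m^2\n", x$ef_low, x$lavi_high))
  cat(sprintf("  E > %g cm/s   E/A in (%g, %g)\n", x$e_high, x$ea_low, x$ea_high))
  cat(sprintf("  septal e' < %g cm/s   lateral e' < %g cm/s   E/e' > %g\n",
              x$e_prime_septal_low, x$e_prime_lateral_low, x$e_over_eprime_high))
  if (x$modality == "echo") {
    cat(sprintf("  TR > %g m/s\n", x$tr_high))
  } else {
    cat(sprintf("  t_vortex > %g %%\n", x$tvortex_high))
  }
  invisible(x)
}

#' Write / read a cutoff set as flat YAML
#'
#' @param x a `dd_cutoffs` object.
#' @param path file path.
#' @return `write_cutoffs` returns `path` invisibly; `read_cutoffs` returns a
#'   `dd_cutoffs` object.
#' @export
write_cutoffs <- function(x, path) {
  stopifnot(inherits(x, "dd_cutoffs"))
  y <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(grading_cutoffs, y)
}
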