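#' Bland-Altman comparison of paired echo / 4D flow values
#'
#' Classical method-comparison analysis for one grading parameter measured
#' by both modalities. The bias is defined as `mean(echo - flow)` — so the
#' negative printed biases for EF and LAVI mean 4D flow exceeds
#' echocardiography — with 95% limits of agreement `bias +/- 1.96 * SD` of
#' the differences. The zero-bias test is chosen by a Shapiro-Wilk gate on
#' the differences at alpha = 0.05: one-sample t-test when normality is not
#' rejected, Wilcoxon signed-rank test otherwise. Pearson's correlation of
#' the paired values is reported alongside.
#'
#' Constant differences (zero spread) are a legal degenerate case: the
#' limits of agreement collapse onto the bias, the normality p-value is
#' undefined (`NA`), the bias p-value is 1 when the constant is zero and 0
#' otherwise, and the result is flagged.
#'
#' @param echo_values,flow_values equal-length numeric vectors of paired
#'   measurements, no missing pairs, `n >= 3`.
#' @return Object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `bias_p`, `normality_p`, `test_used`
#'   (`"t_test"`, `"wilcoxon"` or `"none"` when degenerate), `r` (`NA` and
#'   flagged if either series has zero variance), `n`, `degenerate`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50, 60, 10)
#' bland_altman(x, x + 5 + rnorm(50, 0, 3))
bland_altman <- function(echo_values, flow_values) {
  if (length(echo_values) != length(flow_values)) {
    stop("paired series must have equal length")
  }
  keep <- !(is.na(echo_values) | is.na(flow_values))
  if (any(!keep)) stop("missing pairs are not allowed; drop them first")
  n <- length(echo_values)
  if (n < 3) stop("need at least 3 pairs")

  d <- echo_values - flow_values
  bias <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0

  if (degenerate) {
    normality_p <- NA_real_
    bias_p <- if (bias == 0) 1 else 0
    test_used <- "none"
  } else {
    normality_p <- stats::shapiro.test(d)$p.value
    if (normality_p >= 0.05) {
      test_used <- "t_test"
      bias_p <- stats::t.test(d)$p.value
    } else {
      test_used <- "wilcoxon"
      bias_p <- suppressWarnings(stats::wilcox.test(d)$p.value)
    }
  }

  r <- if (stats::sd(echo_values) == 0 || stats::sd(flow_values) == 0) {
    NA_real_
  } else {
    stats::cor(echo_values, flow_values)
  }

  structure(list(
    bias = bias, sd_diff = sd_d,
    loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
    bias_p = bias_p, normality_p = normality_p, test_used = test_used,
    r = r, n = n, degenerate = degenerate
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman comparison (echo - 4D flow), n =", x$n, "\n")
  cat(sprintf("  bias %s  [LoA %s, %s]\n",
              format(x$bias, digits = digits),
              format(x$loa_low, digits = digits),
              format(x$loa_high, digits = digits)))
  cat(sprintf("  zero-bias test: %s, p = %s (Shapiro-Wilk p = %s)\n",
              x$test_used, format.pval(x$bias_p, digits = digits),
              format.pval(x$normality_p, digits = digits)))
  cat(sprintf("  Pearson r = %s\n", format(x$r, digits = digits)))
  if (x$degenerate) cat("  note: zero spread of differences (degenerate)\n")
  invisible(x)
}

#' Transfer an echocardiographic cutoff to the 4D flow scale
#'
#' With bias in the `echo - 4D` convention, a threshold on the echo scale is
#' equivalent to `echo_cutoff - bias` on the 4D flow scale: e.g. the EF
#' cutoff 50% with bias -5 becomes 55%, and LAVI 34 mL/m^2 with bias -13
#' becomes 47 mL/m^2.
#'
#' @param echo_cutoff threshold on the echocardiographic scale.
#' @param bias mean of `(echo - flow)` from [bland_altman()].
#' @return The equivalent 4D flow-scale threshold.
#' @export
#' @examples
#' bias_adjust_cutoff(50, -5)   # 55
#' bias_adjust_cutoff(34, -13)  # 47
bias_adjust_cutoff <- function(echo_cutoff, bias) {
  echo_cutoff - bias
}

#' Derive bias-adjusted 4D flow grading cutoffs from a paired cohort
#'
#' Cutoff-selection rule 1: echo-equivalent parameters get their echo cutoff
#' transferred to the 4D flow scale through the observed Bland-Altman bias;
#' parameters with no relevant bias keep the echo cutoff unchanged. The
#' default policy adjusts only the volumetric parameters (EF, LAVI) — the
#' significantly biased ones — and keeps all velocity thresholds; `"auto"`
#' instead adjusts every parameter whose zero-bias test is significant at
#' alpha = 0.05. Adjusted cutoffs are rounded to `digits` (default integer,
#' the precision volumetric thresholds are stated at). The t_vortex
#' threshold comes from cutoff-selection rule 2 (see [surrogate_cutoff()])
#' and is passed in via `tvortex_high`.
#'
#' @param cohort paired cohort `data.frame`.
#' @param echo_cutoffs echo `dd_cutoffs` to transfer (default
#'   [default_cutoffs]`("echo")`).
#' @param policy `"default"` (adjust EF + LAVI), `"auto"` (adjust where the
#'   bias is significant), or a named character vector over
#'   `c("ef","lavi","e","e_prime_septal","e_prime_lateral")` with values
#'   `"adjust"`/`"keep"`.
#' @param tvortex_high t_vortex threshold (%%) for the returned 4D set.
#' @param digits rounding for adjusted cutoffs.
#' @return List with `cutoffs` (4D `dd_cutoffs`), `bland_altman` (per
#'   parameter), and `adjusted` (logical per parameter).
#' @export
calibrate_cutoffs <- function(cohort, echo_cutoffs = default_cutoffs("echo"),
                              policy = "default", tvortex_high = 15,
                              digits = 0) {
  params <- c(ef = "ef", lavi = "lavi", e = "e",
              e_prime_septal = "e_prime_septal",
              e_prime_lateral = "e_prime_lateral")
  echo_thr <- c(ef = echo_cutoffs$ef_low, lavi = echo_cutoffs$lavi_high,
                e = echo_cutoffs$e_high,
                e_prime_septal = echo_cutoffs$e_prime_septal_low,
                e_prime_lateral = echo_cutoffs$e_prime_lateral_low)

  ba <- lapply(params, function(p) {
    e <- cohort[[paste0("echo_", p)]]
    f <- cohort[[paste0("flow_", p)]]
    keep <- !(is.na(e) | is.na(f))
    bland_altman(e[keep], f[keep])
  })

  adjusted <- if (identical(policy, "default")) {
    stats::setNames(names(params) %in% c("ef", "lavi"), names(params))
  } else if (identical(policy, "auto")) {
    vapply(ba, function(b) b$bias_p < 0.05, logical(1))
  } else {
    if (is.null(names(policy)) || !all(names(params) %in% names(policy))) {
      stop("named policy must cover: ", paste(names(params), collapse = ", "))
    }
    vapply(names(params), function(p) {
      if (!policy[[p]] %in% c("adjust", "keep")) {
        stop("policy values must be 'adjust' or 'keep'")
      }
      policy[[p]] == "adjust"
    }, logical(1))
  }

  thr <- echo_thr
  for (p in names(params)) {
    if (adjusted[[p]]) {
      thr[[p]] <- round(bias_adjust_cutoff(echo_thr[[p]], ba[[p]]$bias), digits)
    }
  }

  cutoffs <- grading_cutoffs("flow4d",
    ef_low = thr[["ef"]], lavi_high = thr[["lavi"]], e_high = thr[["e"]],
    ea_low = echo_cutoffs$ea_low, ea_high = echo_cutoffs$ea_high,
    e_prime_septal_low = thr[["e_prime_septal"]],
    e_prime_lateral_low = thr[["e_prime_lateral"]],
    e_over_eprime_high = echo_cutoffs$e_over_eprime_high,
    tvortex_high = tvortex_high)

  list(cutoffs = cutoffs, bland_altman = ba, adjusted = adjusted)
}
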