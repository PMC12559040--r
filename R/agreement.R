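#' Build the 5x5 grade cross-classification
#'
#' Cross-tabulates two ordinal grade series over the fixed category order
#' `normal < indeterminate < grade1 < grade2 < grade3`. Rows index method A
#' (conventionally 4D flow), columns method B (echocardiography).
#'
#' @param grades_a,grades_b equal-length grade vectors (labels or factors),
#'   no missing values.
#' @return 5x5 integer matrix of class `grade_table`.
#' @export
build_contingency <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b)) stop("grade series lengths differ")
  if (length(grades_a) == 0) stop("empty grade series")
  a <- as_grade(grades_a); b <- as_grade(grades_b)
  if (anyNA(a) || anyNA(b)) stop("missing grades are not allowed")
  t <- table(a, b)
  m <- matrix(as.integer(t), 5, 5, dimnames = dimnames(t))
  class(m) <- c("grade_table", class(m))
  m
}

#' @export
print.grade_table <- function(x, ...) {
  m <- unclass(x)
  cat("Grade cross-classification (rows = method A, cols = method B), n =",
      sum(m), "\n")
  print(stats::addmargins(as.table(m)))
  invisible(x)
}

# shared checks for table-based statistics
as_square_counts <- function(t) {
  m <- unclass(t)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square count matrix")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  m
}

#' Cohen's weighted kappa with asymptotic CI
#'
#' Chance-corrected ordinal agreement with disagreement weights
#' `v_ij = |i - j| / (k - 1)` (linear, the default) or its square
#' (quadratic): `kappa = 1 - sum(v * p_obs) / sum(v * p_exp)` with expected
#' proportions from the products of the margins. The confidence interval
#' uses the large-sample variance of weighted kappa (Fleiss, Cohen &
#' Everitt form) with a normal approximation.
#'
#' @param t square count matrix (e.g. from [build_contingency()]).
#' @param weights `"linear"` or `"quadratic"`.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class `weighted_kappa`: list with `kappa`, `se`, `ci`,
#'   `weights`, `n`, `n_discordant`, `p_observed`, `p_expected` (weighted
#'   agreement proportions).
#' @export
#' @examples
#' weighted_kappa(fixture_table4())
weighted_kappa <- function(t, weights = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  m <- as_square_counts(t)
  k <- nrow(m)
  n <- sum(m)
  if (n == 0) stop("empty table")
  p <- m / n
  ri <- rowSums(p); cj <- colSums(p)
  if (sum(ri > 0) < 2 || sum(cj > 0) < 2) {
    stop("need at least two categories with nonzero margin in each dimension")
  }
  v <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (weights == "quadratic") v <- v^2
  exp_dis <- sum(v * outer(ri, cj))
  if (exp_dis == 0) stop("expected weighted disagreement is 0; kappa undefined")
  obs_dis <- sum(v * p)
  kap <- 1 - obs_dis / exp_dis

  # Fleiss-Cohen-Everitt large-sample variance, in agreement weights w = 1 - v
  w <- 1 - v
  po <- sum(w * p)
  pe <- sum(w * outer(ri, cj))
  wbar_row <- as.vector(w %*% cj)   # wbar_i. = sum_j w_ij * q_j
  wbar_col <- as.vector(ri %*% w)   # wbar_.j = sum_i p_i * w_ij
  cross <- outer(wbar_row, wbar_col, "+")
  ssq <- sum(p * (w * (1 - pe) - cross * (1 - po))^2) -
    (po * pe - 2 * pe + po)^2
  se <- sqrt(max(0, ssq) / (n * (1 - pe)^4))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, kap - z * se), min(1, kap + z * se))

  structure(list(kappa = kap, se = se, ci = ci, weights = weights, n = n,
                 n_discordant = n - sum(diag(m)),
                 p_observed = po, p_expected = pe),
            class = "weighted_kappa")
}

#' @export
print.weighted_kappa <- function(x, ...) {
  cat(sprintf("Cohen's weighted kappa (%s weights): %.2f (%.2f, %.2f)\n",
              x$weights, x$kappa, x$ci[1], x$ci[2]))
  cat(sprintf("  n = %d, discordant = %d\n", x$n, x$n_discordant))
  invisible(x)
}

#' Bowker test of symmetry
#'
#' Generalisation of McNemar's test to a k x k table: under the null of a
#' symmetric disagreement pattern (no systematic over- or under-grading by
#' either method), `chi^2 = sum_(i<j) (n_ij - n_ji)^2 / (n_ij + n_ji)` over
#' the off-diagonal pairs with at least one discordant count; the degrees
#' of freedom equal the number of such pairs (zero-sum pairs are excluded).
#'
#' @param t square count matrix.
#' @return Object of class `bowker_test`: list with `statistic`, `df`,
#'   `p.value`, `no_discordance` (TRUE if every off-diagonal pair is empty,
#'   in which case p = 1 by convention).
#' @export
#' @examples
#' bowker_symmetry(fixture_table4())
bowker_symmetry <- function(t) {
  m <- as_square_counts(t)
  if (sum(m) == 0) stop("empty table")
  k <- nrow(m)
  chi2 <- 0; df <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      s <- m[i, j] + m[j, i]
      if (s > 0) {
        chi2 <- chi2 + (m[i, j] - m[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  none <- df == 0L
  p <- if (none) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(statistic = chi2, df = df, p.value = p,
                 no_discordance = none),
            class = "bowker_test")
}

#' @export
print.bowker_test <- function(x, ...) {
  cat(sprintf("Bowker symmetry test: chi^2 = %.3f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p.value))
  if (x$no_discordance) cat("  note: no discordant pairs; p = 1 by convention\n")
  invisible(x)
}

#' Accuracy with exact (Clopper-Pearson) 95% CI
#'
#' Proportion of correct binary predictions as a rounded percentage with
#' the exact two-sided binomial confidence interval, rounded to integer
#' percent as such accuracies are conventionally printed.
#'
#' @param n_correct,n_total counts, `0 <= n_correct <= n_total`,
#'   `n_total > 0`.
#' @return List with `accuracy` (%), `ci` (integer %, length 2), and the
#'   unrounded `accuracy_raw`, `ci_raw` (proportions).
#' @export
#' @examples
#' accuracy_ci(68, 69)  # 99% (92%, 100%)
accuracy_ci <- function(n_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_correct < 0 || n_correct > n_total) stop("need 0 <= n_correct <= n_total")
  bt <- stats::binom.test(n_correct, n_total)
  list(accuracy = round(100 * n_correct / n_total),
       ci = round(100 * as.numeric(bt$conf.int)),
       accuracy_raw = n_correct / n_total,
       ci_raw = as.numeric(bt$conf.int))
}

#' Two-way absolute-agreement single-measure ICC
#'
#' ICC(A,1) of McGraw & Wong: two-way model, single measure, absolute
#' agreement, computed from the two-way mean squares
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` with k = 2
#' raters, with the standard F-based 95% confidence interval. Absolute
#' agreement penalises systematic offsets between raters, unlike a
#' consistency ICC.
#'
#' @param ratings n x 2 numeric matrix or data.frame (subjects x raters),
#'   complete, `n >= 5`.
#' @param conf_level confidence level (default 0.95).
#' @return List with `icc`, `ci`, `n`, `k`.
#' @export
icc_absolute_single <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (ncol(x) != 2) stop("ratings must have exactly 2 columns (raters)")
  if (anyNA(x)) stop("ratings must be complete")
  n <- nrow(x); k <- 2
  if (n < 5) stop("need at least 5 subjects")

  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) stop("zero between-subject variance; ICC undefined")

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)

  list(icc = icc, ci = c(lower, upper), n = n, k = k)
}

#' Full grade-agreement analysis between two modalities
#'
#' Convenience wrapper: builds the 5x5 cross-classification, computes the
#' weighted kappa with CI and the Bowker symmetry test, and (when audit
#' criterion columns from [grade_cohort()] are supplied) attributes each
#' discordant subject to the criteria whose status differs between the
#' modalities.
#'
#' @param grades_a,grades_b grade vectors (A = 4D flow rows, B = echo
#'   columns).
#' @param weights kappa weighting scheme.
#' @param audit_a,audit_b optional `data.frame`s from [grade_cohort()] with
#'   matching rows, used for the discordance breakdown.
#' @return Object of class `dd_agreement`: list with `table`, `kappa`,
#'   `symmetry`, `n`, `n_discordant`, and optionally `discordance`
#'   (`data.frame` of subject, grades, differing criteria).
#' @export
grade_agreement <- function(grades_a, grades_b,
                            weights = c("linear", "quadratic"),
                            audit_a = NULL, audit_b = NULL) {
  weights <- match.arg(weights)
  tab <- build_contingency(grades_a, grades_b)
  kap <- weighted_kappa(tab, weights)
  sym <- bowker_symmetry(tab)
  out <- list(table = tab, kappa = kap, symmetry = sym, n = sum(tab),
              n_discordant = kap$n_discordant)
  if (!is.null(audit_a) && !is.null(audit_b)) {
    ga <- as_grade(grades_a); gb <- as_grade(grades_b)
    disc <- which(ga != gb)
    cc <- grep("^crit_", names(audit_a), value = TRUE)
    rows <- lapply(disc, function(i) {
      differs <- cc[vapply(cc, function(col)
        !identical(audit_a[[col]][i], audit_b[[col]][i]), logical(1))]
      data.frame(subject_id = audit_a$subject_id[i],
                 grade_a = as.character(ga[i]), grade_b = as.character(gb[i]),
                 differing_criteria = paste(sub("^crit_", "", differs),
                                            collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    out$discordance <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(0), grade_a = character(0),
                 grade_b = character(0), differing_criteria = character(0))
  }
  structure(out, class = "dd_agreement")
}

#' @export
print.dd_agreement <- function(x, ...) {
  print(x$table)
  print(x$kappa)
  print(x$symmetry)
  if (!is.null(x$discordance) && nrow(x$discordance) > 0) {
    cat("Discordant subjects:\n")
    print(x$discordance, row.names = FALSE)
  }
  invisible(x)
}
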