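#' Peak tricuspid pressure gradient from TR velocity
#'
#' Simplified Bernoulli conversion of the tricuspid regurgitant peak
#' velocity (m/s) to the peak tricuspid pressure gradient
#' `pTR = 4 * TR^2` (mmHg).
#'
#' @param tr tricuspid regurgitant peak velocity, m/s, non-negative.
#' @return Peak pressure gradient, mmHg.
#' @export
#' @examples
#' tr_to_ptr(2.8)  # 31.36 mmHg
tr_to_ptr <- function(tr) {
  if (any(is.na(tr)) || any(tr < 0)) stop("tr must be non-negative")
  4 * tr^2
}

#' Segmented (hockey-stick) linear model of t_vortex on pTR
#'
#' Fits the flat-then-linear relationship between the peak tricuspid
#' pressure gradient pTR (mmHg) and the duration of vortical blood flow
#' along the main pulmonary artery t_vortex (% of the cardiac interval):
#' t_vortex is 0 up to a threshold `ptr0` and increases linearly with
#' non-negative `slope` above it,
#' `t_vortex = slope * max(0, pTR - ptr0)`.
#'
#' The sum of squared residuals is minimised by profiling the breakpoint:
#' for each candidate `ptr0` the slope has the closed-form least-squares
#' solution on the hinge covariate (clamped at 0 if negative, flagged), and
#' the flat-segment points contribute their zero-prediction residuals. The
#' breakpoint is located on a grid of `grid_size` candidates spanning the
#' observed pTR range and refined by bounded one-dimensional minimisation
#' (golden-section with parabolic interpolation) within the best grid
#' bracket to tolerance `tol`, making the result grid-independent.
#'
#' Fit quality is reported as `r_fit = sqrt(1 - SSE/SST)` (square root of
#' the coefficient of determination about the mean of t_vortex).
#'
#' @param ptr numeric vector of peak tricuspid pressure gradients, mmHg.
#' @param tvortex numeric vector of vortical-flow durations, %.
#' @param grid_size number of breakpoint candidates across the pTR range.
#' @param tol refinement tolerance for the breakpoint, mmHg.
#' @return Object of class `segfit`: list with `ptr0`, `slope`, `r_fit`,
#'   `sse`, `sst`, `n`, `fitted.values`, `residuals`, `data`,
#'   `slope_clamped`, `grid_size`, `tol`.
#' @seealso [predict.segfit()], [surrogate_cutoff()], [segmented_model()]
#' @export
#' @examples
#' ptr <- seq(5, 60, length.out = 69)
#' tv <- 1.19 * pmax(0, ptr - 18.4)
#' fit_segmented(ptr, tv)
fit_segmented <- function(ptr, tvortex, grid_size = 200, tol = 1e-8) {
  if (length(ptr) != length(tvortex)) stop("ptr and tvortex lengths differ")
  keep <- !(is.na(ptr) | is.na(tvortex))
  ptr <- ptr[keep]; tvortex <- tvortex[keep]
  n <- length(ptr)
  if (n < 4) stop("need at least 4 points")
  if (sum(tvortex > 0) < 2) stop("need at least 2 points with t_vortex > 0")
  if (stats::sd(ptr) == 0) stop("degenerate input: all pTR values identical")

  profile_slope <- function(p0) {
    h <- pmax(0, ptr - p0)
    s2 <- sum(h^2)
    if (s2 == 0) return(0)
    max(0, sum(tvortex * h) / s2)
  }
  sse_at <- function(p0) {
    h <- pmax(0, ptr - p0)
    s <- profile_slope(p0)
    sum((tvortex - s * h)^2)
  }

  grid <- seq(min(ptr), max(ptr), length.out = grid_size)
  sses <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_size, i + 1L)]
  ptr0 <- if (lo < hi) stats::optimize(sse_at, c(lo, hi), tol = tol)$minimum
          else grid[i]
  if (sse_at(grid[i]) < sse_at(ptr0)) ptr0 <- grid[i]

  h <- pmax(0, ptr - ptr0)
  raw_slope <- if (sum(h^2) > 0) sum(tvortex * h) / sum(h^2) else 0
  slope <- max(0, raw_slope)
  fitted <- slope * h
  res <- tvortex - fitted
  sse <- sum(res^2)
  sst <- sum((tvortex - mean(tvortex))^2)
  r_fit <- if (sst > 0) sqrt(max(0, 1 - sse / sst)) else NA_real_

  structure(list(
    ptr0 = ptr0, slope = slope, r_fit = r_fit, sse = sse, sst = sst, n = n,
    fitted.values = fitted, residuals = res,
    data = data.frame(ptr = ptr, tvortex = tvortex),
    slope_clamped = raw_slope < 0, grid_size = grid_size, tol = tol
  ), class = "segfit")
}

#' Construct a segmented model from known parameters
#'
#' Builds a `segfit` object directly from a breakpoint and slope (e.g. a
#' published fit), so [predict.segfit()] and [surrogate_cutoff()] can be
#' evaluated without refitting.
#'
#' @param ptr0 breakpoint, mmHg.
#' @param slope slope above the breakpoint, %/mmHg, non-negative.
#' @param n optional number of points behind the fit (for reporting).
#' @return A `segfit` object without data/residual components.
#' @export
#' @examples
#' m <- segmented_model(18.4, 1.19)
#' predict(m, newdata = tr_to_ptr(2.8))
segmented_model <- function(ptr0, slope, n = NA_integer_) {
  stopifnot(is.numeric(ptr0), is.numeric(slope), slope >= 0)
  structure(list(ptr0 = ptr0, slope = slope, r_fit = NA_real_,
                 sse = NA_real_, sst = NA_real_, n = n,
                 fitted.values = NULL, residuals = NULL, data = NULL,
                 slope_clamped = FALSE, grid_size = NA, tol = NA),
            class = "segfit")
}

#' Predict t_vortex from pTR
#'
#' Evaluates the fitted piecewise-linear response: 0 below the breakpoint,
#' `slope * (ptr - ptr0)` above; continuous, non-decreasing and never
#' negative.
#'
#' @param object a `segfit` object.
#' @param newdata numeric vector of pTR values (mmHg); defaults to the
#'   fitting data.
#' @param ... unused.
#' @return Predicted t_vortex (%).
#' @export
predict.segfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("no data stored; supply newdata")
    newdata <- object$data$ptr
  }
  object$slope * pmax(0, newdata - object$ptr0)
}

#' @export
coef.segfit <- function(object, ...) {
  c(ptr0 = object$ptr0, slope = object$slope)
}

#' @export
residuals.segfit <- function(object, ...) object$residuals

#' @export
fitted.segfit <- function(object, ...) object$fitted.values

#' @export
print.segfit <- function(x, digits = 4, ...) {
  cat("Segmented linear model: t_vortex = slope * max(0, pTR - pTR_0)\n")
  cat(sprintf("  pTR_0 = %s mmHg   slope = %s %%/mmHg",
              format(x$ptr0, digits = digits),
              format(x$slope, digits = digits)))
  if (!is.na(x$r_fit)) cat(sprintf("   R = %s", format(x$r_fit, digits = 3)))
  cat("\n")
  if (!is.na(x$n)) cat("  n =", x$n, "points\n")
  if (isTRUE(x$slope_clamped)) cat("  note: slope clamped at 0\n")
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  rsd <- if (!is.null(object$residuals) && object$n > 2) {
    sqrt(object$sse / (object$n - 2))
  } else NA_real_
  structure(list(fit = object, residual_sd = rsd,
                 n_flat = if (!is.null(object$data))
                   sum(object$data$ptr < object$ptr0) else NA),
            class = "summary.segfit")
}

#' @export
print.summary.segfit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$residual_sd)) {
    cat(sprintf("  residual SD = %s %% (df = %d)\n",
                format(x$residual_sd, digits = 3), x$fit$n - 2L))
    cat(sprintf("  points below breakpoint: %d of %d\n", x$n_flat, x$fit$n))
  }
  invisible(x)
}

#' @export
plot.segfit <- function(x, ...,
                        xlab = "pTR (mmHg)",
                        ylab = "t_vortex (% of cardiac interval)") {
  if (is.null(x$data)) stop("no data stored in this model")
  graphics::plot(x$data$ptr, x$data$tvortex, xlab = xlab, ylab = ylab, ...)
  xs <- seq(min(x$data$ptr), max(x$data$ptr), length.out = 200)
  graphics::lines(xs, predict(x, xs), lwd = 2)
  graphics::abline(v = x$ptr0, lty = 3)
  invisible(x)
}

#' Simulate responses from a segmented model
#'
#' Draws new t_vortex vectors at the fitting pTR values from the fitted
#' piecewise-linear mean plus Gaussian residuals (SD = residual SD of the
#' fit), floored at 0 to respect the domain of a duration percentage.
#'
#' @param object a fitted `segfit` with stored data.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return `data.frame` with `nsim` columns of simulated responses.
#' @export
simulate.segfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$data)) stop("no data stored in this model")
  if (!is.null(seed)) set.seed(seed)
  rsd <- sqrt(object$sse / (object$n - 2))
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, pmax(0, mu + stats::rnorm(object$n, 0, rsd))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Surrogate t_vortex grading cutoff with bootstrap CI
#'
#' Cutoff-selection rule 2: the t_vortex threshold equivalent to an
#' echocardiographic TR threshold is the model prediction at
#' `pTR = 4 * tr_cutoff^2`. The 95% confidence interval is a nonparametric
#' subject-level bootstrap: subjects are resampled with replacement, the
#' segmented model refitted per resample, and the percentile interval of
#' the re-predicted cutoff reported.
#'
#' @param fit a fitted `segfit` with stored data.
#' @param tr_cutoff echocardiographic TR threshold, m/s (default 2.8).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the resampling.
#' @param grid_size breakpoint grid used for the bootstrap refits.
#' @return List with `cutoff` (%), `ci` (length-2 percentile interval),
#'   `ptr_cutoff`, `n_boot`, `degenerate` (TRUE when the fit has zero
#'   slope, giving a 0 cutoff).
#' @export
surrogate_cutoff <- function(fit, tr_cutoff = 2.8, n_boot = 2000, seed = 1,
                             grid_size = 100) {
  stopifnot(inherits(fit, "segfit"))
  ptr_cut <- tr_to_ptr(tr_cutoff)
  est <- predict(fit, ptr_cut)
  degenerate <- fit$slope == 0
  ci <- c(NA_real_, NA_real_)
  if (!is.null(fit$data) && n_boot > 0) {
    set.seed(seed)
    n <- fit$n
    boots <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(
        fit_segmented(fit$data$ptr[idx], fit$data$tvortex[idx],
                      grid_size = grid_size, tol = 1e-6),
        error = function(e) NULL)
      boots[b] <- if (is.null(bf)) NA_real_ else predict(bf, ptr_cut)
    }
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(cutoff = est, ci = ci, ptr_cutoff = ptr_cut, n_boot = n_boot,
       degenerate = degenerate)
}
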