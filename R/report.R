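#' Per-parameter method-comparison report
#'
#' Mirrors the printed comparison tables: one row per grading parameter
#' (EF, LAVI, E, E/A, septal e', lateral e', E/e') with per-modality
#' mean +/- SD, Bland-Altman bias, zero-bias p-value, Pearson r and its
#' conventional magnitude label ("high" 0.70-0.90, "very high" > 0.90);
#' plus a criterion-accuracy table giving, for every binary grading
#' criterion, the accuracy (with exact 95% CI) of the 4D flow criterion at
#' its cutoff predicting the echocardiographic criterion at the echo
#' cutoff. The pulmonary-pressure criterion (TR vs t_vortex) is evaluated
#' on subjects with detectable TR and additionally on all subjects with
#' non-detectable regurgitation interpreted as TR below cutoff.
#'
#' @param cohort paired cohort `data.frame`.
#' @param echo_cutoffs,flow_cutoffs `dd_cutoffs` for the two arms (defaults
#'   [default_cutoffs()]).
#' @return Object of class `dd_parameter_report`: list with `parameters`
#'   and `accuracy` data.frames.
#' @export
parameter_report <- function(cohort,
                             echo_cutoffs = default_cutoffs("echo"),
                             flow_cutoffs = default_cutoffs("flow4d")) {
  col <- function(arm, p) cohort[[paste0(arm, "_", p)]]
  derived <- function(arm) {
    e <- col(arm, "e"); a <- col(arm, "a")
    es <- col(arm, "e_prime_septal"); el <- col(arm, "e_prime_lateral")
    list(ea = e / a, ee = e / ((es + el) / 2))
  }
  d_echo <- derived("echo"); d_flow <- derived("flow")
  pairs <- list(
    ef = list(col("echo", "ef"), col("flow", "ef")),
    lavi = list(col("echo", "lavi"), col("flow", "lavi")),
    e = list(col("echo", "e"), col("flow", "e")),
    e_a = list(d_echo$ea, d_flow$ea),
    e_prime_septal = list(col("echo", "e_prime_septal"),
                          col("flow", "e_prime_septal")),
    e_prime_lateral = list(col("echo", "e_prime_lateral"),
                           col("flow", "e_prime_lateral")),
    e_over_eprime = list(d_echo$ee, d_flow$ee)
  )

  r_label <- function(r) {
    if (is.na(r)) "undefined"
    else if (abs(r) > 0.90) "very high"
    else if (abs(r) >= 0.70) "high"
    else "below high"
  }

  rows <- lapply(names(pairs), function(p) {
    e <- pairs[[p]][[1]]; f <- pairs[[p]][[2]]
    keep <- !(is.na(e) | is.na(f))
    ba <- bland_altman(e[keep], f[keep])
    data.frame(parameter = p,
               echo_mean = mean(e[keep]), echo_sd = stats::sd(e[keep]),
               flow_mean = mean(f[keep]), flow_sd = stats::sd(f[keep]),
               bias = ba$bias, bias_p = ba$bias_p, r = ba$r,
               r_label = r_label(ba$r), n = ba$n,
               stringsAsFactors = FALSE)
  })
  parameters <- do.call(rbind, rows)

  acc_row <- function(name, echo_pos, flow_pos) {
    keep <- !(is.na(echo_pos) | is.na(flow_pos))
    a <- accuracy_ci(sum(echo_pos[keep] == flow_pos[keep]), sum(keep))
    data.frame(criterion = name, accuracy = a$accuracy,
               ci_low = a$ci[1], ci_high = a$ci[2], n = sum(keep),
               stringsAsFactors = FALSE)
  }
  ec <- echo_cutoffs; fc <- flow_cutoffs
  tr <- col("echo", "tr"); tv <- col("flow", "t_vortex")
  det <- !is.na(tr)
  accuracy <- rbind(
    acc_row("ef_low", col("echo", "ef") < ec$ef_low,
            col("flow", "ef") < fc$ef_low),
    acc_row("lavi_high", col("echo", "lavi") > ec$lavi_high,
            col("flow", "lavi") > fc$lavi_high),
    acc_row("e_high", col("echo", "e") > ec$e_high,
            col("flow", "e") > fc$e_high),
    acc_row("ea_low", d_echo$ea > ec$ea_low, d_flow$ea > fc$ea_low),
    acc_row("ea_high", d_echo$ea < ec$ea_high, d_flow$ea < fc$ea_high),
    acc_row("e_prime_septal_low",
            col("echo", "e_prime_septal") < ec$e_prime_septal_low,
            col("flow", "e_prime_septal") < fc$e_prime_septal_low),
    acc_row("e_prime_lateral_low",
            col("echo", "e_prime_lateral") < ec$e_prime_lateral_low,
            col("flow", "e_prime_lateral") < fc$e_prime_lateral_low),
    acc_row("e_over_eprime_high", d_echo$ee > ec$e_over_eprime_high,
            d_flow$ee > fc$e_over_eprime_high),
    acc_row("pa_pressure_detectable_tr",
            tr[det] > ec$tr_high, tv[det] > fc$tvortex_high),
    acc_row("pa_pressure_all",
            ifelse(det, tr > ec$tr_high, FALSE), tv > fc$tvortex_high)
  )

  structure(list(parameters = parameters, accuracy = accuracy),
            class = "dd_parameter_report")
}

#' @export
print.dd_parameter_report <- function(x, digits = 3, ...) {
  cat("Parameter comparison (bias = echo - 4D flow):\n")
  p <- x$parameters
  p$echo <- sprintf("%.1f +/- %.1f", p$echo_mean, p$echo_sd)
  p$flow <- sprintf("%.1f +/- %.1f", p$flow_mean, p$flow_sd)
  print(data.frame(parameter = p$parameter, echo = p$echo, `4dflow` = p$flow,
                   bias = round(p$bias, 2), p = signif(p$bias_p, 2),
                   r = round(p$r, 2), label = p$r_label,
                   check.names = FALSE), row.names = FALSE)
  cat("\nCriterion prediction accuracy (4D flow vs echo):\n")
  a <- x$accuracy
  a$accuracy <- sprintf("%d%% (%d%%, %d%%)", a$accuracy, a$ci_low, a$ci_high)
  print(a[, c("criterion", "accuracy", "n")], row.names = FALSE)
  invisible(x)
}
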