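# Construct a complete, valid subject record; override any field by name.
# Defaults describe an unremarkable subject with normal diastolic function
# on both arms.
make_record <- function(...) {
  rec <- list(
    subject_id = "S001", myocardial_disease = FALSE,
    echo_ef = 62, echo_lavi = 28, echo_e = 75, echo_a = 60,
    echo_e_prime_septal = 10, echo_e_prime_lateral = 13, echo_tr = 2.2,
    flow_ef = 67, flow_lavi = 41, flow_e = 75, flow_a = 60,
    flow_e_prime_septal = 10, flow_e_prime_lateral = 13, flow_t_vortex = 1.5)
  over <- list(...)
  rec[names(over)] <- over
  rec
}

# Measurement list for one arm straight from named arguments.
make_m <- function(ef = 62, lavi = 28, e_peak = 75, a_peak = 60,
                   e_prime_septal = 10, e_prime_lateral = 13,
                   tr_peak = NULL, t_vortex = NULL) {
  list(ef = ef, lavi = lavi, e_peak = e_peak, a_peak = a_peak,
       e_prime_septal = e_prime_septal, e_prime_lateral = e_prime_lateral,
       tr_peak = tr_peak, t_vortex = t_vortex)
}

# A small cohort data.frame from a list of records.
make_cohort <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

# Random valid 5x5 count table for oracle-equivalence checks.
random_table5 <- function(n = 200) {
  m <- matrix(stats::rmultinom(1, n, prob = runif(25, 0.2, 1)), 5, 5)
  dimnames(m) <- list(grade_levels(), grade_levels())
  m
}

# Independent direct-summation oracles (element-by-element loops, no shared
# code with the package implementations).
oracle_weighted_kappa <- function(m, quadratic = FALSE) {
  n <- sum(m); k <- nrow(m)
  obs <- 0; exp <- 0
  for (i in 1:k) for (j in 1:k) {
    v <- abs(i - j) / (k - 1)
    if (quadratic) v <- v^2
    obs <- obs + v * m[i, j] / n
    exp <- exp + v * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
  }
  1 - obs / exp
}

oracle_bowker <- function(m) {
  chi <- 0; df <- 0
  for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    s <- m[i, j] + m[j, i]
    if (s > 0) { chi <- chi + (m[i, j] - m[j, i])^2 / s; df <- df + 1 }
  }
  list(chi = chi, df = df)
}
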