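test_that("contingency construction counts pairs in fixed category order", {
  g <- c("normal", "grade1", "grade2", "normal", "grade3", "indeterminate")
  t <- build_contingency(g, g)
  expect_equal(sum(diag(t)), 6L)
  expect_equal(sum(t) - sum(diag(t)), 0L)
  expect_equal(rownames(t), grade_levels())
  t2 <- build_contingency(c("normal", "grade1"), c("indeterminate", "grade1"))
  expect_equal(t2["normal", "indeterminate"], 1L)
  expect_error(build_contingency(character(0), character(0)), "empty")
  expect_error(build_contingency(g, g[-1]), "length")
})

test_that("the reference table has the published margins and discordance", {
  t <- fixture_table4()
  expect_equal(unname(rowSums(t)), c(50, 10, 16, 11, 7))
  expect_equal(unname(colSums(t)), c(51, 9, 13, 13, 8))
  expect_equal(sum(t), 94L)
  expect_equal(sum(diag(t)), 73L)
  expect_equal(sum(t) - sum(diag(t)), 21L)
})

test_that("linear-weighted kappa matches the reference analysis", {
  k <- weighted_kappa(fixture_table4(), "linear")
  expect_equal(round(k$kappa, 2), 0.84)
  expect_equal(round(k$ci, 2), c(0.78, 0.91))
  expect_equal(k$n_discordant, 21L)
  # quadratic weights would overstate the printed agreement
  kq <- weighted_kappa(fixture_table4(), "quadratic")
  expect_gt(kq$kappa, 0.90)
})

test_that("kappa limiting cases and invariances", {
  diag_t <- diag(c(10, 5, 8, 4, 3))
  expect_equal(weighted_kappa(diag_t)$kappa, 1)
  ones <- matrix(1, 5, 5)
  expect_equal(weighted_kappa(ones)$kappa, 0)
  # transpose symmetry for symmetric weights
  set.seed(41)
  for (i in 1:10) {
    m <- random_table5()
    expect_equal(weighted_kappa(m)$kappa, weighted_kappa(t(m))$kappa)
  }
  # moving mass from the diagonal to a distance-2 cell lowers kappa
  m <- fixture_table4()
  m2 <- unclass(m)
  m2[1, 1] <- m2[1, 1] - 5L
  m2[1, 3] <- m2[1, 3] + 5L
  expect_lt(weighted_kappa(m2)$kappa, weighted_kappa(m)$kappa)
  expect_error(weighted_kappa(diag(c(5, 0, 0, 0, 0))), "margin")
})

test_that("Bowker symmetry test matches the reference analysis", {
  b <- bowker_symmetry(fixture_table4())
  expect_equal(b$statistic, (6 - 7)^2 / 13 + (4 - 1)^2 / 5 + (2 - 1)^2 / 3)
  expect_equal(round(b$statistic, 2), 2.21)
  expect_equal(b$df, 3L)
  expect_equal(round(b$p.value, 2), 0.53)
})

test_that("Bowker limiting cases and symmetric-matrix invariance", {
  sym <- matrix(2, 5, 5)
  b <- bowker_symmetry(sym)
  expect_equal(b$statistic, 0)
  expect_equal(b$p.value, 1)
  # single discordant pair
  m <- diag(rep(4L, 5)); m[2, 4] <- 12L; m[4, 2] <- 9L
  b1 <- bowker_symmetry(m)
  expect_equal(b1$statistic, 9 / 21)
  expect_equal(b1$df, 1L)
  # adding a symmetric matrix leaves the discordant differences intact (it
  # inflates the pair totals, so the statistic can only shrink towards the
  # null) and never creates asymmetry: a symmetric table stays at chi^2 = 0
  set.seed(42)
  for (i in 1:10) {
    m <- random_table5()
    s <- matrix(sample(0:4, 25, TRUE), 5, 5)
    s <- s + t(s)
    d0 <- m - t(m)
    d2 <- (m + s) - t(m + s)
    expect_equal(d2, d0)
    expect_lte(bowker_symmetry(m + s)$statistic, bowker_symmetry(m)$statistic)
    sym2 <- s + diag(sample(0:5, 5, TRUE))
    expect_equal(bowker_symmetry(sym2)$statistic, 0)
  }
  # purely diagonal additions leave the statistic exactly unchanged
  m <- random_table5()
  expect_equal(bowker_symmetry(m + diag(rep(7L, 5)))$statistic,
               bowker_symmetry(m)$statistic)
  # all-diagonal table: no discordant pairs, p = 1 by convention, flagged
  d <- diag(rep(3L, 5))
  bd <- bowker_symmetry(d)
  expect_true(bd$no_discordance)
  expect_equal(bd$p.value, 1)
})

test_that("kappa and Bowker match direct-summation oracles on random tables", {
  set.seed(43)
  for (i in 1:100) {
    m <- random_table5()
    expect_equal(weighted_kappa(m, "linear")$kappa,
                 oracle_weighted_kappa(m), tolerance = 1e-10)
    expect_equal(weighted_kappa(m, "quadratic")$kappa,
                 oracle_weighted_kappa(m, quadratic = TRUE),
                 tolerance = 1e-10)
    ob <- oracle_bowker(m)
    b <- bowker_symmetry(m)
    expect_equal(b$statistic, ob$chi, tolerance = 1e-10)
    expect_equal(b$df, as.integer(ob$df))
  }
})

test_that("exact binomial accuracy intervals match the printed values", {
  a <- accuracy_ci(68, 69)
  expect_equal(a$accuracy, 99)
  expect_equal(a$ci, c(92, 100))
  a2 <- accuracy_ci(92, 94)
  expect_equal(a2$accuracy, 98)
  expect_equal(a2$ci, c(93, 100))
  a3 <- accuracy_ci(50, 50)
  expect_equal(a3$accuracy, 100)
  expect_equal(a3$ci[2], 100)
  expect_error(accuracy_ci(5, 0))
  expect_error(accuracy_ci(6, 5))
})

test_that("accuracy CI brackets the estimate and widens with smaller n", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- rbinom(1, n, 0.9)
    a <- accuracy_ci(x, n)
    expect_lte(a$ci_raw[1], a$accuracy_raw)
    expect_gte(a$ci_raw[2], a$accuracy_raw)
  }
  wide <- accuracy_ci(9, 10)$ci_raw
  narrow <- accuracy_ci(90, 100)$ci_raw
  expect_gt(diff(wide), diff(narrow))
})

test_that("ICC(A,1) behaves as an absolute-agreement index", {
  x <- cbind(a = c(1, 3, 5, 7, 9, 11), b = c(1, 3, 5, 7, 9, 11))
  expect_equal(icc_absolute_single(x)$icc, 1)
  # a pure offset is penalised
  y <- cbind(a = c(1, 3, 5, 7, 9, 11), b = c(1, 3, 5, 7, 9, 11) + 4)
  expect_lt(icc_absolute_single(y)$icc, 1)
  expect_gt(icc_absolute_single(y)$icc, 0)
  expect_error(icc_absolute_single(cbind(rep(2, 6), rep(2, 6))),
               "between-subject")
})

test_that("ICC(A,1) recovers the analytic value from known variance
           components", {
  set.seed(45)
  n <- 500
  subj <- rnorm(n, 0, 3)        # var_s = 9
  rater <- c(0, 1.5)            # var_r = mean squared offset
  err_sd <- 1.5                 # var_e = 2.25
  x <- cbind(subj + rater[1] + rnorm(n, 0, err_sd),
             subj + rater[2] + rnorm(n, 0, err_sd))
  # population ICC(A,1) = sigma_s^2 / (sigma_s^2 + sigma_c^2 + sigma_e^2);
  # sigma_c^2 = sum((c_j - mean(c))^2) / (k - 1) = 1.125 for offsets (0, 1.5)
  sig_c2 <- stats::var(rater)
  expected <- 9 / (9 + sig_c2 + err_sd^2)
  got <- icc_absolute_single(x)
  expect_lt(abs(got$icc - expected), 0.05)
  expect_true(got$ci[1] <= got$icc && got$icc <= got$ci[2])
})

test_that("parameter report summarises a self-identical cohort exactly", {
  cohort <- make_cohort(lapply(1:30, function(i) {
    r <- make_record(subject_id = sprintf("P%02d", i))
    set.seed(i)
    for (p in c("ef", "lavi", "e", "a", "e_prime_septal", "e_prime_lateral")) {
      v <- abs(rnorm(1, 40, 12)) + 5
      r[[paste0("echo_", p)]] <- v
      r[[paste0("flow_", p)]] <- v
    }
    r$echo_tr <- runif(1, 1.8, 3.4)
    vf <- segmented_model(18.4, 1.19)
    r$flow_t_vortex <- unname(predict(vf, tr_to_ptr(r$echo_tr + 0.05)))
    r
  }))
  # identical arms compared under echo-equivalent thresholds on both sides
  fc_echo_eq <- grading_cutoffs("flow4d", ef_low = 50, lavi_high = 34,
                                e_high = 50, ea_low = 0.8, ea_high = 2.0,
                                e_prime_septal_low = 7,
                                e_prime_lateral_low = 10,
                                e_over_eprime_high = 14, tvortex_high = 15)
  rep <- parameter_report(cohort, flow_cutoffs = fc_echo_eq)
  expect_equal(rep$parameters$bias, rep(0, 7))
  expect_equal(rep$parameters$r, rep(1, 7))
  expect_true(all(rep$accuracy$accuracy[1:8] == 100))
  # constant column flags r as undefined
  c2 <- cohort
  c2$echo_ef <- 60
  c2$flow_ef <- 60
  rep2 <- parameter_report(c2, flow_cutoffs = fc_echo_eq)
  expect_true(is.na(rep2$parameters$r[rep2$parameters$parameter == "ef"]))
  expect_equal(rep2$parameters$r_label[rep2$parameters$parameter == "ef"],
               "undefined")
})

test_that("grade_agreement traces discordance to the differing criteria", {
  set.seed(46)
  cohort <- simulate_cohort(cohort_config(), seed = 46)
  ge <- grade_cohort(cohort, "echo")
  gf <- grade_cohort(cohort, "flow4d")
  ag <- grade_agreement(gf$grade, ge$grade, audit_a = gf, audit_b = ge)
  expect_s3_class(ag, "dd_agreement")
  expect_equal(sum(ag$table), nrow(cohort))
  expect_equal(nrow(ag$discordance), ag$n_discordant)
  expect_true(all(c("subject_id", "differing_criteria") %in%
                    names(ag$discordance)))
})
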