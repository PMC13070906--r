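test_that("identical config and seed give byte-identical cohorts", {
  cfg <- quick_config(n = 200)
  a <- generate_cohort(cfg, seed = 3)
  b <- generate_cohort(cfg, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(cfg, seed = 4)
  expect_false(identical(a$time_to_recurrence, c$time_to_recurrence))
})

test_that("empty cohort keeps a valid schema", {
  coh <- generate_cohort(quick_config(n = 0), seed = 1)
  expect_s3_class(coh, "tn_cohort")
  expect_equal(nrow(coh), 0)
  expect_true(all(c("patient_id", "age", "il6", "time_to_recurrence",
                    "event", "latent_class") %in% names(coh)))
})

test_that("cohort respects record invariants", {
  coh <- generate_cohort(quick_config(n = 2000), seed = 5)
  expect_true(all(coh$age > 0))
  expect_true(all(coh$il6 > 0))
  expect_true(all(coh$time_to_recurrence > 0))
  expect_true(all(coh$event %in% c(0, 1)))
  expect_true(all(coh$v1_involved + coh$v2v3_involved >= 1))
  expect_false(any(duplicated(coh$patient_id)))
  # event/censoring accounting
  expect_equal(sum(coh$event == 1) + sum(coh$event == 0), nrow(coh))
})

test_that("empirical prevalences converge to configured values", {
  cfg <- quick_config(n = 100000)
  coh <- generate_cohort(cfg, seed = 1)
  p <- 0.464
  se <- sqrt(p * (1 - p) / cfg$n)
  expect_lt(abs(mean(coh$hypertension) - p), 3 * se)
  p2 <- 0.179
  expect_lt(abs(mean(coh$v1_involved) - p2),
            3 * sqrt(p2 * (1 - p2) / cfg$n))
})

test_that("mean age of the default cohort matches the study population", {
  cfg <- cached_calibrated_config(n = 56)
  coh <- generate_cohort(cfg, seed = 42)
  expect_lt(abs(mean(coh$age) - 67.18), 3 * 14.79 / sqrt(56))
})

test_that("configuration validation names the offending field", {
  expect_error(cohort_config(class_mix = 1.5), "class_mix")
  expect_error(cohort_config(censoring_window = c(2, 1)), "censoring_window")
  expect_error(cohort_config(baseline_hazards = c(-1, 1, 1, 1)),
               "baseline_hazards")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})

test_that("survival calibration solves the closed-form single-epoch case", {
  cfg <- cohort_config(baseline_knots = 1,
                       log_hr_map = list(early = numeric(0), late = numeric(0)))
  cfg <- calibrate_marginal_survival(
    data.frame(time = 1, survival = exp(-1)), cfg)
  expect_equal(cfg$baseline_hazards, 1.0, tolerance = 1e-9)
})

test_that("survival-1 targets give zero hazards and bad targets error", {
  cfg <- cohort_config()
  out <- calibrate_marginal_survival(
    data.frame(time = c(1, 2, 3.5, 5), survival = c(1, 1, 1, 1)), cfg)
  expect_equal(out$baseline_hazards, rep(0, 4))
  expect_error(calibrate_marginal_survival(
    data.frame(time = c(1, 2, 3.5, 5), survival = c(0.5, 0.9, 0.4, 0.3)), cfg),
    "infeasible")
})

test_that("calibrated marginal survival passes through the printed targets", {
  cfg <- cached_calibrated_config()
  expect_equal(marginal_survival(cfg, c(1, 2, 3.21, 5)),
               c(0.821, 0.684, 0.5, 0.452), tolerance = 1e-8)
})

test_that("post-calibration Kaplan-Meier matches targets at n = 5000", {
  coh <- cached_cohort(5000, seed = 42)
  km <- km_estimate(coh$time_to_recurrence, coh$event)
  s <- survival_at(km, c(1, 2, 5))$estimate
  expect_lt(max(abs(s - c(0.821, 0.684, 0.452))), 0.02)
})

test_that("resistant-class IL-6 draws match the configured arithmetic mean", {
  cfg <- cached_calibrated_config()
  set.seed(42)
  rec <- data.frame(latent_class = rep("resistant", 5000),
                    hypertension = rbinom(5000, 1, 0.464))
  rec <- sample_biomarkers(rec, cfg)
  tau2 <- cfg$il6_coupling^2 + cfg$il6_params$log_sd^2
  sd_theory <- 45 * sqrt(exp(tau2) - 1)
  expect_lt(abs(mean(rec$il6) - 45), 3 * sd_theory / sqrt(5000))
  # norepinephrine: hypertension-conditional means
  expect_lt(abs(mean(rec$norepinephrine[rec$hypertension == 1]) - 483), 25)
  expect_lt(abs(mean(rec$norepinephrine[rec$hypertension == 0]) - 297), 15)
})

test_that("degenerate IL-6 distribution collapses to the class mean", {
  cfg <- quick_config(n = 50)
  cfg$il6_params$log_sd <- 0
  cfg$il6_coupling <- 0
  coh <- generate_cohort(cfg, seed = 1)
  sens <- coh$latent_class == "sensitive"
  expect_equal(coh$il6[sens], rep(12, sum(sens)), tolerance = 1e-12)
})

test_that("MCAR masking hits the requested rate and spares outcomes", {
  coh <- generate_cohort(quick_config(n = 1000), seed = 2)
  same <- inject_missingness(coh, 0)
  expect_identical(as.data.frame(same), as.data.frame(coh))
  masked <- inject_missingness(coh, 0.2, seed = 9, fields = "il6")
  frac <- mean(is.na(masked$il6))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
  expect_false(anyNA(masked$time_to_recurrence))
  expect_error(inject_missingness(coh, 0.2, fields = "time_to_recurrence"),
               "may not be masked")
  expect_error(inject_missingness(coh, 1), "missing_rate")
})

test_that("cohort CSV writer round-trips", {
  coh <- generate_cohort(quick_config(n = 30), seed = 8)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$time_to_recurrence, coh$time_to_recurrence)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$il6, coh$il6, tolerance = 1e-12)
})

test_that("hazard-recovery: correctly specified epoch Cox recovers the log-HRs", {
  cfg <- cached_calibrated_config()
  map <- list(hypertension = "early", v1_involved = "late",
              latent_resistant = "both")
  truth <- c(log(2.15), log(3.02), log(4.12))
  for (s in 1:5) {
    coh <- generate_cohort(cfg, seed = s)
    coh$latent_resistant <- as.integer(coh$latent_class == "resistant")
    fit <- epoch_cox(coh, cutpoint = 2, covariate_epoch_map = map)
    expect_true(fit$converged)
    expect_true(all(abs(fit$terms$coef - truth) < 3 * fit$terms$se),
                label = sprintf("seed %d recovery", s))
  }
})
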