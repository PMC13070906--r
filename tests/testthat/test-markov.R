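test_that("probability/rate conversions satisfy the standard identities", {
  expect_equal(prob_to_rate(0), 0)
  expect_equal(prob_to_rate(0.5, 1), log(2), tolerance = 1e-12)
  for (p in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(rate_to_prob(prob_to_rate(p, 2), 2), p, tolerance = 1e-12)
  }
  expect_error(prob_to_rate(1), "infinite")
})

test_that("reintervention calibration matches the closed form and round-trips", {
  pbc <- markov_spec(arm = "PBC")
  pbc <- calibrate_transitions(
    0.321, data.frame(time = c(1, 2, 5), survival = c(0.821, 0.684, 0.452)),
    pbc)
  expect_equal(pbc$p_reintervention, 1 - 0.679^(1 / 5), tolerance = 1e-12)
  expect_lt(abs(cumulative_reintervention(pbc, 5) - 0.321), 1e-9)
  gkrs <- calibrate_transitions(
    0.547, data.frame(time = c(1, 2, 5), survival = c(0.75, 0.58, 0.35)),
    markov_spec(arm = "GKRS"))
  expect_lt(abs(cumulative_reintervention(gkrs, 5) - 0.547), 1e-9)
  # zero target
  z <- calibrate_transitions(0, data.frame(time = 5, survival = 0.5),
                             markov_spec())
  expect_equal(z$p_reintervention, 0)
  expect_error(calibrate_transitions(
    0.3, data.frame(time = c(1, 2), survival = c(0.5, 0.9)), markov_spec()),
    "infeasible")
})

test_that("a full-health identity chain accrues one QALY per cycle", {
  M <- diag(4)
  spec <- markov_spec(transitions = M, utilities = c(PainFree = 1, Recurred = 1,
                                                     PostReintervention = 1,
                                                     Dead = 0),
                      state_costs = c(PainFree = 0, Recurred = 0,
                                      PostReintervention = 0, Dead = 0),
                      event_costs = c(reintervention = 0),
                      discount_rate_qalys = 0)
  tr <- run_cohort_trace(spec)
  expect_equal(tr$discounted_qaly, 10)
  expect_equal(tr$discounted_cost, 0)
})

test_that("hand-enumerated two-state trace reproduces the occupancy rewards", {
  M <- matrix(0, 4, 4)
  M[1, 1] <- 0.5; M[1, 4] <- 0.5
  M[2, 2] <- 1; M[3, 3] <- 1; M[4, 4] <- 1
  spec <- markov_spec(horizon = 2, transitions = M,
                      utilities = c(PainFree = 1, Recurred = 0,
                                    PostReintervention = 0, Dead = 0),
                      state_costs = c(PainFree = 0, Recurred = 0,
                                      PostReintervention = 0, Dead = 0),
                      event_costs = c(reintervention = 0),
                      half_cycle_correction = FALSE)
  tr <- run_cohort_trace(spec)
  # occupancy sequence 1, 0.5, 0.25; end-of-cycle accrual: 0.5 + 0.25
  expect_equal(unname(tr$occupancy[, "PainFree"]), c(1, 0.5, 0.25))
  expect_equal(tr$discounted_qaly, 0.75)
})

test_that("invalid transition rows are rejected by name", {
  M <- diag(4); M[1, 1] <- 0.9
  expect_error(markov_spec(transitions = M), "PainFree")
  M2 <- diag(4); M2[4, 4] <- 0.5; M2[4, 1] <- 0.5
  expect_error(markov_spec(transitions = M2), "absorbing")
})

test_that("occupancy is conserved and death is monotone on calibrated arms", {
  arms <- default_cua_arms()
  for (tr in list(run_cohort_trace(arms$new), run_cohort_trace(arms$comp))) {
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(diff(tr$occupancy[, "Dead"]) >= -1e-15))
  }
})

test_that("discounting can only lower accrued QALYs", {
  arms <- default_cua_arms()
  tr0 <- run_cohort_trace(arms$new)
  expect_equal(tr0$discounted_qaly, tr0$undiscounted_qaly)
  s3 <- arms$new
  s3$discount_rate_qalys <- 0.03
  s3$discount_rate_costs <- 0.03
  tr3 <- run_cohort_trace(s3)
  expect_lt(tr3$discounted_qaly, tr3$undiscounted_qaly)
  expect_lt(tr3$discounted_cost, tr0$discounted_cost)
})

test_that("value calibration reproduces the printed arm totals", {
  arms <- default_cua_arms()
  tn <- run_cohort_trace(arms$new)
  tc <- run_cohort_trace(arms$comp)
  expect_lt(abs(tn$discounted_cost - 14230) / 14230, 0.005)
  expect_lt(abs(tn$discounted_qaly - 9.7) / 9.7, 0.005)
  expect_lt(abs(tc$discounted_cost - 16075) / 16075, 0.005)
  expect_lt(abs(tc$discounted_qaly - 8.9) / 8.9, 0.005)
})

test_that("traced cost is exactly linear in the cost inputs", {
  arms <- default_cua_arms()
  base <- run_cohort_trace(arms$new)
  doubled <- arms$new
  doubled$state_costs <- doubled$state_costs * 2
  doubled$event_costs <- doubled$event_costs * 2
  tr2 <- run_cohort_trace(doubled)
  expect_equal(tr2$discounted_cost, 2 * base$discounted_cost, tolerance = 1e-12)
  expect_equal(tr2$discounted_qaly, base$discounted_qaly)
})

test_that("unreachable QALY targets raise a calibration error with the bound", {
  spec <- markov_spec(death_prob = 0.02)
  spec <- calibrate_transitions(
    0.321, data.frame(time = c(1, 2, 5), survival = c(0.821, 0.684, 0.452)),
    spec)
  expect_error(calibrate_values(spec, 14230, 10), "unreachable")
  expect_error(calibrate_values(spec, 14230, 9.7), "unreachable")
})

test_that("arm comparison classifies dominance, equivalence and trade-off", {
  arms <- default_cua_arms()
  tn <- run_cohort_trace(arms$new); tc <- run_cohort_trace(arms$comp)
  ce <- compare_arms(tn, tc)
  expect_equal(ce$delta_cost, -1845, tolerance = 0.01)
  expect_equal(ce$delta_qaly, 0.8, tolerance = 1e-4)
  expect_equal(ce$status, "dominant")
  expect_true(is.na(ce$icer))
  same <- compare_arms(tn, tn)
  expect_equal(same$status, "equivalent")
  expect_true(is.na(same$icer))
  # synthetic trade-off: make the new arm more costly and more effective
  t_hi <- tn; t_hi$discounted_cost <- tc$discounted_cost + 1000
  t_hi$discounted_qaly <- tc$discounted_qaly + 0.5
  trd <- compare_arms(t_hi, tc)
  expect_equal(trd$status, "tradeoff")
  expect_equal(trd$icer, 2000)
  # mismatched horizons are refused
  bad <- tc; bad$spec$horizon <- 12L
  expect_error(compare_arms(tn, bad), "horizon")
})

test_that("one-way sensitivity analysis degenerates and separates correctly", {
  arms <- default_cua_arms()
  base_cost <- arms$new$state_costs[["Recurred"]]
  tab <- one_way_sa(arms$new, arms$comp,
                    list("new.state_costs.Recurred" = c(base_cost, base_cost)),
                    wtp = 30000)
  expect_equal(tab$nmb_low, tab$nmb_base, tolerance = 1e-9)
  expect_equal(tab$nmb_high, tab$nmb_base, tolerance = 1e-9)
  # varying a cost parameter must not move the QALY difference
  lo_spec <- arms$new; lo_spec$state_costs[["Recurred"]] <- base_cost / 2
  ce_base <- compare_arms(run_cohort_trace(arms$new), run_cohort_trace(arms$comp))
  ce_lo <- compare_arms(run_cohort_trace(lo_spec), run_cohort_trace(arms$comp))
  expect_equal(ce_lo$delta_qaly, ce_base$delta_qaly, tolerance = 1e-12)
  # hand-recomputed bound matches the table entry
  tab2 <- one_way_sa(arms$new, arms$comp,
                     list("new.state_costs.Recurred" = c(base_cost / 2,
                                                         base_cost * 2)),
                     wtp = 30000)
  nmb_lo_hand <- 30000 * ce_lo$delta_qaly - ce_lo$delta_cost
  expect_equal(tab2$nmb_low, nmb_lo_hand, tolerance = 1e-9)
  expect_error(one_way_sa(arms$new, arms$comp,
                          list("new.state_costs.Recurred" = c(0, 1)), 30000),
               "bracket")
})

test_that("degenerate PSA distributions give a flat CEAC of one", {
  arms <- default_cua_arms()
  res <- psa(arms$new, arms$comp,
             distributions = list(
               "new.state_costs.Recurred" =
                 list(dist = "discrete",
                      values = arms$new$state_costs[["Recurred"]], probs = 1)),
             n_draws = 20, seed = 4, wtp_grid = c(0, 20000, 50000))
  expect_true(all(res$ceac$prob_new_optimal == 1))
})

test_that("two-point PSA matches the exhaustive enumeration oracle", {
  arms <- default_cua_arms()
  c_new <- arms$new$state_costs[["Recurred"]]
  u_comp <- arms$comp$utilities[["Recurred"]]
  dists <- list(
    "new.state_costs.Recurred" = list(dist = "discrete",
                                      values = c(c_new, c_new * 40),
                                      probs = c(0.5, 0.5)),
    "comp.utilities.Recurred" = list(dist = "discrete",
                                     values = c(u_comp, 1), probs = c(0.5, 0.5)))
  wtp <- 20000
  # enumerate the 4 outcomes exactly
  win <- matrix(NA, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    sn <- arms$new; sc <- arms$comp
    sn$state_costs[["Recurred"]] <- dists[[1]]$values[i]
    sc$utilities[["Recurred"]] <- dists[[2]]$values[j]
    tn <- run_cohort_trace(sn); tc <- run_cohort_trace(sc)
    win[i, j] <- (wtp * tn$discounted_qaly - tn$discounted_cost) >=
      (wtp * tc$discounted_qaly - tc$discounted_cost)
  }
  p_exact <- mean(win)
  res <- psa(arms$new, arms$comp, dists, n_draws = 400, seed = 11,
             wtp_grid = wtp)
  p_mc <- res$ceac$prob_new_optimal
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(0.25 / 400) + 1e-12)
  expect_true(all(res$ceac$prob_new_optimal >= 0 &
                    res$ceac$prob_new_optimal <= 1))
  # reproducible under a fixed seed
  res2 <- psa(arms$new, arms$comp, dists, n_draws = 400, seed = 11,
              wtp_grid = wtp)
  expect_identical(res$samples, res2$samples)
})

test_that("markov spec YAML serialisation round-trips", {
  arms <- default_cua_arms()
  f <- tempfile(fileext = ".yaml")
  write_markov_spec(arms$new, f)
  back <- read_markov_spec(f)
  expect_equal(back$p_recurrence, arms$new$p_recurrence, tolerance = 1e-12)
  expect_equal(back$utilities, arms$new$utilities, tolerance = 1e-12)
  tr1 <- run_cohort_trace(arms$new); tr2 <- run_cohort_trace(back)
  expect_equal(tr2$discounted_cost, tr1$discounted_cost, tolerance = 1e-10)
})
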