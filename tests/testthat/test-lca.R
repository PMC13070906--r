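test_that("single-class model has the closed-form Bernoulli likelihood", {
  set.seed(4)
  X <- matrix(rbinom(200 * 4, 1, c(0.2, 0.5, 0.7, 0.9)), 200, 4, byrow = TRUE)
  colnames(X) <- paste0("item", 1:4)
  fit <- lca_em(X, K = 1, restarts = 1, seed = 1)
  p <- colMeans(X)
  ll <- sum(X %*% log(p) + (1 - X) %*% log(1 - p))
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-10)
  expect_equal(as.vector(fit$rho), unname(p), tolerance = 1e-9)
  expect_equal(fit$pi, 1)
  expect_equal(fit$bic, -2 * ll + 4 * log(200), tolerance = 1e-8)
})

test_that("perfectly separated patterns recover the analytic two-class mix", {
  X <- rbind(matrix(0, 40, 4), matrix(1, 40, 4))
  colnames(X) <- paste0("item", 1:4)
  fit <- lca_em(X, K = 2, restarts = 5, seed = 2)
  expect_equal(sort(fit$pi), c(0.5, 0.5), tolerance = 1e-6)
  expect_true(all(pmin(fit$rho, 1 - fit$rho) <= 1e-5))
  expect_equal(fit$log_likelihood, 80 * log(0.5), tolerance = 1e-3)
  # posterior rows are proper distributions
  expect_equal(rowSums(fit$posterior), rep(1, 80), tolerance = 1e-12)
})

test_that("log-likelihood and BIC are invariant to label permutation", {
  set.seed(9)
  X <- cbind(a = rbinom(150, 1, 0.3), b = rbinom(150, 1, 0.6),
             c = rbinom(150, 1, 0.5))
  fit <- lca_em(X, K = 2, restarts = 5, seed = 3)
  # recompute the mixture likelihood with classes swapped (independent formula)
  mix_ll <- function(pi_k, rho) {
    lik <- sapply(seq_along(pi_k), function(k) {
      pi_k[k] * exp(X %*% log(rho[k, ]) + (1 - X) %*% log(1 - rho[k, ]))
    })
    sum(log(rowSums(lik)))
  }
  expect_equal(mix_ll(fit$pi, fit$rho),
               mix_ll(rev(fit$pi), fit$rho[2:1, ]), tolerance = 1e-10)
  expect_equal(mix_ll(fit$pi, fit$rho), fit$log_likelihood, tolerance = 1e-8)
})

test_that("BIC selects one class for independent fair coins", {
  set.seed(12)
  X <- matrix(rbinom(500 * 4, 1, 0.5), 500, 4)
  colnames(X) <- paste0("item", 1:4)
  sel <- select_K(X, K_max = 2, restarts = 8, seed = 5)
  expect_equal(sel$K_best, 1)
})

test_that("BIC selects two classes for a strongly separated mixture", {
  set.seed(13)
  z <- rbinom(600, 1, 0.5)
  p <- ifelse(outer(z, rep(1, 5)) == 1, 0.85, 0.15)
  X <- matrix(rbinom(600 * 5, 1, p), 600, 5)
  colnames(X) <- paste0("item", 1:5)
  sel <- select_K(X, K_max = 3, restarts = 8, seed = 6)
  expect_equal(sel$K_best, 2)
})

test_that("degenerate K triggers a warning", {
  X <- rbind(matrix(0, 10, 3), matrix(1, 10, 3))
  colnames(X) <- paste0("i", 1:3)
  expect_warning(lca_em(X, K = 3, restarts = 2, seed = 1), "degenerate")
})

test_that("discretization follows the >= threshold convention", {
  coh <- generate_cohort(quick_config(n = 5), seed = 2)
  coh$il6[1] <- 20          # boundary case codes 1
  coh$age <- c(69.9, 70, 80, 50, 71)
  ind <- discretize_features(coh)
  expect_equal(unname(ind[1, "il6_ge_cut"]), 1L)
  expect_equal(unname(ind[, "age_ge_cut"]), c(0L, 1L, 1L, 0L, 1L))
  expect_equal(unname(ind[, "hypertension"]), coh$hypertension)
  coh$il6[2] <- NA
  expect_error(discretize_features(coh), "imputation")
})

test_that("calibrated cohorts yield two classes recovered near the Bayes ceiling", {
  cfg <- cached_calibrated_config(2000)
  coh <- generate_cohort(cfg, seed = 42)
  ind <- discretize_features(coh)
  # IL-6 indicator prevalence tracks the resistant mixing fraction
  expect_lt(abs(mean(ind[, "il6_ge_cut"]) - cfg$class_mix), 0.05)
  sel <- select_K(ind, K_max = 3, restarts = 20, seed = 42)
  expect_equal(sel$K_best, 2)
  m2 <- sel$models[[2]]
  expect_equal(rowSums(m2$posterior), rep(1, 2000), tolerance = 1e-12)
  res_class <- which.max(m2$rho[, "il6_ge_cut"])
  agree <- mean(ifelse(m2$map == res_class, "resistant", "sensitive") ==
                  coh$latent_class)
  ceiling <- class_recovery_ceiling(cfg)$accuracy
  expect_gt(agree, 0.8)
  expect_gt(agree, ceiling - 0.03)   # EM sits at the information-theoretic limit
  expect_lte(agree, ceiling + 0.03)
})

test_that("five-year survival separates the true classes as calibrated", {
  coh <- cached_cohort(5000, seed = 42)
  s5 <- vapply(c("sensitive", "resistant"), function(cl) {
    sub <- coh[coh$latent_class == cl, ]
    survival_at(km_estimate(sub$time_to_recurrence, sub$event), 5)$estimate
  }, numeric(1))
  expect_lt(abs(s5[["sensitive"]] - 0.689), 0.03)
  expect_lt(abs(s5[["resistant"]] - 0.214), 0.03)
})

test_that("class-outcome association delegates exactly to cox_fit", {
  coh <- cached_cohort(2000, seed = 3)
  fit <- class_outcome_association(coh$latent_class, coh$time_to_recurrence,
                                   coh$event)
  direct <- cox_fit(coh$time_to_recurrence, coh$event,
                    cbind(resistant_class =
                            as.numeric(coh$latent_class == "resistant")))
  expect_equal(fit$terms$coef, direct$terms$coef)
  expect_equal(fit$terms$se, direct$terms$se)
})

test_that("random labels show no association with outcome", {
  coh <- cached_cohort(5000, seed = 42)
  set.seed(77)
  labels <- sample(c("resistant", "sensitive"), nrow(coh), replace = TRUE)
  fit <- class_outcome_association(labels, coh$time_to_recurrence, coh$event)
  expect_lt(abs(fit$terms$coef), 3 * fit$terms$se)
})
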