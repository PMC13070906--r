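test_that("tiny-data coefficient maximises the partial likelihood (grid oracle)", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(time, event, cbind(x = x))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, efron_loglik_1d, numeric(1), time = time,
               event = event, x = x)
  expect_lt(abs(fit$terms$coef - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$log_likelihood, max(ll), tolerance = 1e-6)
})

test_that("mirror-identical groups give a zero coefficient", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- rep(1, 8)
  x <- rep(c(0, 1), each = 4)
  fit <- cox_fit(time, event, cbind(x = x))
  expect_equal(fit$terms$coef, 0, tolerance = 1e-8)
})

test_that("estimates, SEs and log-likelihood match coxph with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(99)
  n <- 300
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  tt <- round(rexp(n, 0.2 * exp(0.7 * x1 - 0.3 * x2)), 1) + 0.1
  cc <- runif(n, 0.5, 8)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  mine <- cox_fit(time, ev, cbind(x1 = x1, x2 = x2))
  ref <- survival::coxph(survival::Surv(time, ev) ~ x1 + x2, ties = "efron")
  expect_equal(mine$terms$coef, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(mine$terms$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  expect_equal(mine$log_likelihood, ref$loglik[2], tolerance = 1e-7)
  expect_equal(mine$null_log_likelihood, ref$loglik[1], tolerance = 1e-7)
  # invariant: hr = exp(coef), CI brackets hr
  expect_equal(mine$terms$hr, exp(mine$terms$coef))
  expect_true(all(mine$terms$hr_ci_low < mine$terms$hr &
                    mine$terms$hr < mine$terms$hr_ci_high))
})

test_that("counting-process episodes match coxph with start/stop", {
  skip_if_not_installed("survival")
  coh <- cached_cohort(2000, seed = 3)
  coh$latent_resistant <- as.integer(coh$latent_class == "resistant")
  ep <- epoch_split(coh, 2)
  ep$h_e <- ep$hypertension * (ep$epoch == "early")
  ep$v_l <- ep$v1_involved * (ep$epoch == "late")
  mine <- epoch_cox(coh, 2,
                    covariate_epoch_map = list(hypertension = "early",
                                               v1_involved = "late",
                                               latent_resistant = "both"))
  ref <- survival::coxph(
    survival::Surv(start, stop, event) ~ h_e + v_l + latent_resistant,
    data = ep, ties = "efron")
  expect_equal(mine$terms$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$terms$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("score vanishes at the optimum and beats the null likelihood", {
  coh <- cached_cohort(2000, seed = 3)
  fit <- epoch_cox(coh, 2)
  expect_true(fit$converged)
  expect_lt(fit$max_score, 1e-6)
  expect_gte(fit$log_likelihood, fit$null_log_likelihood)
})

test_that("epoch splitting follows the counting-process definitions", {
  df <- data.frame(time = c(3.0, 1.5), event = c(1, 1), x = c(1, 0))
  ep <- epoch_split(df, 2)
  a <- ep[ep$id == 1, ]
  expect_equal(a$start, c(0, 2))
  expect_equal(a$stop, c(2, 3))
  expect_equal(a$event, c(0, 1))
  expect_equal(a$epoch, c("early", "late"))
  b <- ep[ep$id == 2, ]
  expect_equal(nrow(b), 1)
  expect_equal(b$stop, 1.5)
  expect_equal(b$event, 1)
  # event conservation on a sizeable cohort
  coh <- cached_cohort(2000, seed = 3)
  ep2 <- epoch_split(coh, 2)
  expect_equal(sum(ep2$event), sum(coh$event))
  expect_error(epoch_split(df, -1), "positive")
})

test_that("a cutpoint beyond follow-up reduces epoch_cox to a plain fit", {
  coh <- cached_cohort(2000, seed = 3)
  fit_ep <- epoch_cox(coh, cutpoint = 100,
                      covariate_epoch_map = list(hypertension = "early"))
  fit_plain <- cox_fit(coh$time_to_recurrence, coh$event,
                       cbind(`hypertension:early` = coh$hypertension))
  expect_equal(fit_ep$terms$coef, fit_plain$terms$coef, tolerance = 1e-10)
  expect_equal(fit_ep$terms$se, fit_plain$terms$se, tolerance = 1e-10)
})

test_that("time rescaling leaves binary-covariate fits and log-rank unchanged", {
  set.seed(5)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  tt <- rexp(n, 0.3 * exp(0.5 * x))
  cc <- runif(n, 0.5, 6)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  f1 <- cox_fit(time, ev, cbind(x = x))
  f2 <- cox_fit(time * 365.25, ev, cbind(x = x))
  expect_equal(f1$terms$coef, f2$terms$coef, tolerance = 1e-8)
  l1 <- log_rank(time, ev, x)
  l2 <- log_rank(time * 365.25, ev, x)
  expect_equal(l1$statistic, l2$statistic, tolerance = 1e-10)
})

test_that("degenerate inputs are signalled", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), cbind(x = c(1, 1, 1))),
               "constant")
  expect_error(cox_fit(c(1, 2), c(0, 0), cbind(x = c(0, 1))), "event")
  # perfect separation of event order: monotone likelihood, no convergence
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- cox_fit(time, rep(1, 8), cbind(x = x))
  expect_false(fit$converged)
})

test_that("Wald intervals achieve nominal coverage", {
  beta <- log(2)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.25 * exp(beta * x))
    cc <- runif(n, 0.5, 8)
    time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
    fit <- cox_fit(time, ev, cbind(x = x))
    lo <- fit$terms$coef - 1.96 * fit$terms$se
    hi <- fit$terms$coef + 1.96 * fit$terms$se
    if (lo <= beta && beta <= hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.91)
  expect_lte(hits / reps, 0.99)
})
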