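# Shared fixtures, built in code.

# Calibration of the default config costs a couple of seconds (Monte-Carlo
# coupling search), so memoise one copy per session.
.fixture_env <- new.env(parent = emptyenv())

cached_calibrated_config <- function(n = 5000) {
  key <- paste0("cfg", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- calibrated_cohort_config(n = n, seed = 42)
  }
  .fixture_env[[key]]
}

cached_cohort <- function(n = 5000, seed = 42) {
  key <- paste0("coh", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(cached_calibrated_config(n), seed = seed)
  }
  .fixture_env[[key]]
}

# Small, fast config with hazards fixed by hand (no calibration step).
quick_config <- function(n = 100, ...) {
  cohort_config(n = n, baseline_hazards = c(0.2, 0.22, 0.25, 0.12),
                il6_coupling = 0.4, ...)
}

# Independent product-limit recomputation: brute-force risk sets.
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  S <- 1
  out <- data.frame(time = ut, survival = NA_real_, var_term = NA_real_)
  vt <- 0
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_r <- sum(times >= t)
    d <- sum(times == t & events == 1)
    S <- S * (1 - d / n_r)
    vt <- vt + d / (n_r * (n_r - d))
    out$survival[i] <- S
    out$var_term[i] <- vt
  }
  out$se <- out$survival * sqrt(out$var_term)
  out
}

# Independent Efron log partial likelihood for a single covariate
# (right-censored data, no late entry); used as a grid-search oracle.
efron_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    dead <- which(time == t & event == 1)
    d <- length(dead)
    wr <- exp(beta * x[risk])
    wd <- exp(beta * x[dead])
    ll <- ll + sum(beta * x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum(wr) - (l / d) * sum(wd))
    }
  }
  ll
}
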