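#' Product-limit (Kaplan-Meier) estimate of recurrence-free survival
#'
#' From-scratch product-limit estimator with Greenwood variance and
#' complementary log-log confidence bands.  Right-continuous step convention;
#' at tied times, events precede censorings (both are counted in the risk set
#' at that time).
#'
#' @param times positive follow-up times (years).
#' @param events 0/1 event indicators (1 = recurrence observed).
#' @param conf_level confidence level for the log-log band.
#' @return a `tn_km` object: `event_times`, `survival`, `greenwood_se`,
#'   `n_at_risk`, `n_events`, `ci_low`, `ci_high`, `n`, `ci_method`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(0, 1, 1))
#' survival_at(km, 2.5)   # 0.5 by the step convention
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (anyNA(times) || anyNA(events)) stop("missing values in times or events")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")

  ut <- sort(unique(times[events == 1]))
  n <- length(times)
  if (length(ut) == 0) {
    return(structure(list(event_times = numeric(0), survival = numeric(0),
                          greenwood_se = numeric(0), n_at_risk = integer(0),
                          n_events = integer(0), ci_low = numeric(0),
                          ci_high = numeric(0), n = n, conf_level = conf_level,
                          ci_method = "log-log"),
                     class = "tn_km"))
  }
  n_at_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  frac <- 1 - n_events / n_at_risk
  S <- cumprod(frac)
  gw <- cumsum(n_events / (n_at_risk * (n_at_risk - n_events)))
  gw[n_at_risk == n_events] <- Inf   # S = 0: variance of log undefined
  se <- S * sqrt(gw)
  se[S == 0] <- 0
  ci <- loglog_ci(S, se, conf_level)
  structure(list(event_times = ut, survival = S, greenwood_se = se,
                 n_at_risk = as.integer(n_at_risk),
                 n_events = as.integer(n_events),
                 ci_low = ci$low, ci_high = ci$high, n = n,
                 conf_level = conf_level, ci_method = "log-log"),
            class = "tn_km")
}

# Complementary log-log confidence band; guarantees limits in [0, 1].
loglog_ci <- function(S, se, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  low <- high <- rep(NA_real_, length(S))
  ok <- S > 0 & S < 1 & is.finite(se) & se > 0
  se_v <- se[ok] / (S[ok] * abs(log(S[ok])))
  low[ok] <- S[ok]^exp(z * se_v)
  high[ok] <- S[ok]^exp(-z * se_v)
  low[S == 0] <- 0
  high[S == 0] <- 0
  low[S == 1] <- 1
  high[S == 1] <- 1
  list(low = low, high = high)
}

#' @export
print.tn_km <- function(x, ...) {
  cat(sprintf("Product-limit estimate: %d subjects, %d event times\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    med <- km_median(x)
    cat(sprintf("  median: %s\n",
                if (med$reached) sprintf("%.3f y (%d%% CI %.3f-%.3f)",
                                         med$median, round(100 * x$conf_level),
                                         med$ci_low, med$ci_high)
                else "not reached"))
  }
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' Step-function evaluation: the value at the latest event time `<= t`,
#' carried forward beyond the last event time; 1 before the first event.
#'
#' @param curve a `tn_km` object.
#' @param t non-negative times.
#' @return data.frame with `time`, `estimate`, `ci_low`, `ci_high`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "tn_km"))
  if (any(t < 0)) stop("t must be >= 0")
  idx <- findInterval(t, curve$event_times)
  est <- ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
  lo <- ifelse(idx == 0, 1, curve$ci_low[pmax(idx, 1)])
  hi <- ifelse(idx == 0, 1, curve$ci_high[pmax(idx, 1)])
  data.frame(time = t, estimate = est, ci_low = lo, ci_high = hi)
}

#' Median survival time with Brookmeyer-Crowley confidence interval
#'
#' The median is the smallest event time with `S(t) <= 0.5`.  The confidence
#' interval inverts the pointwise log-log band: it is the set of times at
#' which 0.5 is inside the band (Brookmeyer-Crowley construction).
#'
#' @param curve a `tn_km` object.
#' @return list with `median`, `ci_low`, `ci_high` and logical `reached`;
#'   when the curve never drops to 0.5 the median is `NA` and
#'   `reached` is `FALSE` (a signalled outcome, not an error).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "tn_km"))
  quantile_km(curve, 0.5)
}

quantile_km <- function(curve, p) {
  drop <- which(curve$survival <= p)
  if (!length(drop)) {
    return(list(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                reached = FALSE))
  }
  est <- curve$event_times[drop[1]]
  lo_idx <- which(curve$ci_low <= p)        # upper band still above p earlier
  hi_idx <- which(curve$ci_high < p)        # even upper limit below p
  list(median = est,
       ci_low = if (length(lo_idx)) curve$event_times[lo_idx[1]] else NA_real_,
       ci_high = if (length(hi_idx)) curve$event_times[hi_idx[1]] else NA_real_,
       reached = TRUE)
}

#' Write a survival curve as CSV
#'
#' Columns: `time`, `n_risk`, `n_event`, `survival`, `se`, `ci_low`,
#' `ci_high`.
#'
#' @param curve a `tn_km` object.
#' @param path output file.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(time = curve$event_times, n_risk = curve$n_at_risk,
                   n_event = curve$n_events, survival = curve$survival,
                   se = curve$greenwood_se, ci_low = curve$ci_low,
                   ci_high = curve$ci_high)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Two-sample log-rank test
#'
#' Standard observed-minus-expected hypergeometric statistic on one degree of
#' freedom, comparing recurrence-free survival between two groups.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group two-level grouping vector.
#' @return a `tn_logrank` list: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
log_rank <- function(times, events, group) {
  if (length(unique(group)) != 2) stop("exactly two non-empty groups required")
  g <- as.integer(factor(group)) - 1L   # 0/1
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at <- times >= t
    n_t <- sum(at)
    n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n_t
    if (n_t > 1) {
      V <- V + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = c(sum(events) - O, O),
                 expected = c(sum(events) - E, E)),
            class = "tn_logrank")
}

#' @export
print.tn_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with a two-sided p-value from the t transform
#' on `n - 2` degrees of freedom.  Used for the IL-6 vs pain-free-time
#' association; by default callers restrict to uncensored subjects.
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-zero variance).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}
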