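#' Simplified multiple imputation by chained equations
#'
#' Fills MCAR gaps in covariate columns with `m` completed cohorts.  Each
#' incomplete column is modelled on the other covariates plus the outcome
#' (log follow-up time and event flag): logistic regression for binary
#' columns, linear regression for continuous ones, in a chained-equations
#' sweep.  Proper imputation noise is injected by drawing the coefficients
#' from their approximate posterior (and, for linear models, the residual
#' variance from its scaled inverse-chi-square posterior) before drawing the
#' imputed values.  Intentionally simpler than full MICE: no predictive mean
#' matching.
#'
#' @param cohort a `tn_cohort` with `NA`s on covariates only.
#' @param m number of imputations (>= 1).
#' @param seed integer seed (sub-stream offset 7, one sub-sub-stream per
#'   imputation).
#' @param n_sweeps chained-equation sweeps per imputation.
#' @return object of class `tn_imputations`: list of `m` completed cohorts
#'   plus the index of imputed cells.
#' @export
impute_missing <- function(cohort, m = 5, seed = attr(cohort, "seed"),
                           n_sweeps = 5) {
  if (m < 1) stop("m must be >= 1")
  if (anyNA(cohort$time_to_recurrence) || anyNA(cohort$event)) {
    stop("time/event columns may not be missing")
  }
  candidates <- intersect(c("age", "symptom_duration", "il6", "dmn_score",
                            "norepinephrine", "hypertension", "diabetes"),
                          names(cohort))
  has_na <- candidates[vapply(candidates, function(f) anyNA(cohort[[f]]),
                              logical(1))]
  if (!length(has_na)) {
    sets <- rep(list(cohort), m)
    return(structure(list(completed = sets, imputed_fields = character(0), m = m),
                     class = "tn_imputations"))
  }
  binary <- intersect(has_na, c("hypertension", "diabetes"))
  predictors_of <- function(target) setdiff(candidates, target)

  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    completed[[imp]] <- with_substream(seed, 7 * 1000 + imp, {
      df <- as.data.frame(cohort)
      df$log_time <- log(df$time_to_recurrence)
      # initialise by resampling observed values
      for (f in has_na) {
        na_i <- is.na(df[[f]])
        df[[f]][na_i] <- sample(df[[f]][!na_i], sum(na_i), replace = TRUE)
      }
      for (sweep in seq_len(n_sweeps)) {
        for (f in has_na) {
          na_i <- is.na(cohort[[f]])
          preds <- c(predictors_of(f), "log_time", "event")
          fml <- reformulate(preds, response = f)
          if (f %in% binary) {
            fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
            b <- draw_coefs(coef(fit), vcov(fit))
            Xn <- model.matrix(delete.response(terms(fit)),
                               df[na_i, , drop = FALSE])
            p <- plogis(as.vector(Xn %*% b))
            df[[f]][na_i] <- rbinom(sum(na_i), 1, p)
          } else {
            fit <- lm(fml, data = df)
            s2 <- draw_sigma2(fit)
            b <- draw_coefs(coef(fit), vcov(fit) / summary(fit)$sigma^2 * s2)
            Xn <- model.matrix(delete.response(terms(fit)),
                               df[na_i, , drop = FALSE])
            df[[f]][na_i] <- as.vector(Xn %*% b) + rnorm(sum(na_i), 0, sqrt(s2))
          }
        }
      }
      df$log_time <- NULL
      structure(df, class = class(cohort),
                config_fingerprint = attr(cohort, "config_fingerprint"),
                seed = attr(cohort, "seed"))
    })
  }
  structure(list(completed = completed, imputed_fields = has_na, m = m),
            class = "tn_imputations")
}

draw_coefs <- function(b, V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(b)
  b + as.vector(t(L) %*% rnorm(length(b)))
}

draw_sigma2 <- function(fit) {
  df_res <- fit$df.residual
  df_res * summary(fit)$sigma^2 / rchisq(1, df_res)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; total
#' variance is `W + (1 + 1/m) B` with `W` the mean within-imputation
#' variance and `B` the between-imputation variance.
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @return list with `estimate`, `within`, `between`, `total_variance`,
#'   `se`, `df` (Rubin's small-sample degrees of freedom) and `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (length(variances) != m) stop("estimates and variances differ in length")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1) var(estimates) else 0
  total <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  list(estimate = qbar, within = W, between = B, total_variance = total,
       se = sqrt(total), df = df, m = m)
}

#' Pooled epoch-Cox analysis over multiply-imputed cohorts
#'
#' Fits [epoch_cox()] on each completed cohort and pools each term's log
#' hazard ratio by [rubin_pool()].
#'
#' @param imputations a `tn_imputations` object.
#' @param ... passed to [epoch_cox()].
#' @return data.frame with pooled `coef`, `se`, `hr` and CI per term.
#' @export
pooled_epoch_cox <- function(imputations, ...) {
  fits <- lapply(imputations$completed, function(coh) epoch_cox(coh, ...))
  terms <- fits[[1]]$terms$term
  rows <- lapply(seq_along(terms), function(j) {
    est <- vapply(fits, function(f) f$terms$coef[j], numeric(1))
    v <- vapply(fits, function(f) f$terms$se[j]^2, numeric(1))
    p <- rubin_pool(est, v)
    data.frame(term = terms[j], epoch = fits[[1]]$terms$epoch[j],
               coef = p$estimate, se = p$se, hr = exp(p$estimate),
               hr_ci_low = exp(p$estimate - 1.96 * p$se),
               hr_ci_high = exp(p$estimate + 1.96 * p$se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
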