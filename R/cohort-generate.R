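#' Generate a synthetic salvage-therapy cohort
#'
#' Draws a cohort of synthetic patients from a [cohort_config()].  Recurrence
#' times follow the per-patient piecewise-exponential hazard
#' `lambda(t) = lambda_piece(t) * exp(sum_j beta_epoch,j x_j)` with covariate
#' effects switching at the epoch cutpoint, and are censored administratively
#' by a uniform draw on the censoring window.  Biomarkers are attached by
#' [sample_biomarkers()]; the latent class and the latent recurrence-time
#' quantile are kept as generator-truth columns (hidden from estimators by
#' default in the pipeline).
#'
#' @param cfg a calibrated [cohort_config()].
#' @param seed integer seed; defaults to `cfg$seed`.  Identical
#'   `(cfg, seed)` pairs give byte-identical cohorts.
#' @return a `tn_cohort` data.frame, one row per patient, with attributes
#'   `config_fingerprint` and `seed`.
#' @examples
#' cfg <- cohort_config(n = 20, baseline_hazards = c(0.2, 0.2, 0.25, 0.25),
#'                      il6_coupling = 0.4)
#' coh <- generate_cohort(cfg, seed = 7)
#' table(coh$event)
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  cfg <- validate_cohort_config(cfg)
  if (is.null(cfg$baseline_hazards)) {
    stop("baseline hazards are not set; run calibrate_marginal_survival() first")
  }
  if (is.null(cfg$il6_coupling)) {
    stop("IL-6 coupling is not set; run calibrate_il6_coupling() or supply a value")
  }
  n <- cfg$n
  prev <- cfg$covariate_prevalences

  cov <- with_substream(seed, 1, {
    latent_class <- ifelse(runif(n) < cfg$class_mix, "resistant", "sensitive")
    age <- rnorm_pos(n,
                     mean = unname(cfg$age_mean[latent_class]),
                     sd = cfg$age_sd, lower = 18)
    sex <- ifelse(runif(n) < prev["female"], "female", "male")
    hypertension <- as.integer(runif(n) <
                                 class_prevalence(cfg, "hypertension", latent_class))
    diabetes <- as.integer(runif(n) < prev["diabetes"])
    v2v3_involved <- as.integer(runif(n) <
                                  class_prevalence(cfg, "v2v3_involved", latent_class))
    v1_involved <- 1L - v2v3_involved  # every patient has >= 1 division involved
    tn_type <- ifelse(runif(n) < prev["tn1"], "TN1", "TN2")
    symptom_duration <- rnorm_pos(n, cfg$symptom_duration_mean,
                                  cfg$symptom_duration_sd, lower = 0.1)
    data.frame(latent_class, age, sex, hypertension, diabetes,
               v1_involved, v2v3_involved, tn_type, symptom_duration,
               stringsAsFactors = FALSE)
  })

  # Recurrence times by inverse-CDF on the subject-specific cumulative hazard.
  u <- with_substream(seed, 2, runif(n))
  resistant <- as.integer(cov$latent_class == "resistant")
  t_latent <- invert_cum_hazard(cfg, -log(u), cov$hypertension,
                                cov$v1_involved, resistant)

  cens <- with_substream(seed, 3, {
    runif(n, cfg$censoring_window[1], cfg$censoring_window[2])
  })

  coh <- cov
  coh$latent_quantile <- qnorm(u)   # large -> short latent recurrence time
  coh$time_to_recurrence <- pmin(t_latent, cens)
  coh$event <- as.integer(t_latent <= cens)

  coh <- with_substream(seed, 4, {
    sample_biomarkers(coh, cfg)
  })

  coh <- with_substream(seed, 5, {
    coh$immediate_relief <- as.integer(runif(n) < cfg$response_prob)
    coh$facial_numbness <- as.integer(runif(n) < cfg$complication_prob)
    coh
  })

  coh <- cbind(patient_id = sprintf("P%05d", seq_len(n)), coh,
               stringsAsFactors = FALSE)
  rownames(coh) <- NULL
  structure(coh,
            class = c("tn_cohort", "data.frame"),
            config_fingerprint = object_fingerprint(cfg),
            seed = as.integer(seed))
}

# Invert H(t) = E for each subject; piecewise-linear in t within segments.
invert_cum_hazard <- function(cfg, E, hyp, v1, resistant) {
  seg <- hazard_segments(cfg)
  lp_e <- cfg$log_hr_map$early
  lp_l <- cfg$log_hr_map$late
  x <- cbind(hypertension = hyp, v1_involved = v1, latent_resistant = resistant)
  eta_early <- as.vector(x[, names(lp_e), drop = FALSE] %*% lp_e)
  eta_late <- as.vector(x[, names(lp_l), drop = FALSE] %*% lp_l)
  n <- length(E)
  t_out <- rep(Inf, n)
  H <- numeric(n)
  for (i in seq_len(nrow(seg))) {
    mult <- seg$rate[i] * exp(if (seg$epoch[i] == "early") eta_early else eta_late)
    width <- seg$hi[i] - seg$lo[i]
    H_next <- H + mult * width           # Inf * 0 avoided: last seg has Inf width
    if (is.infinite(width)) H_next <- ifelse(mult > 0, Inf, H)
    hit <- is.infinite(t_out) & E <= H_next & mult > 0
    t_out[hit] <- seg$lo[i] + (E[hit] - H[hit]) / mult[hit]
    H <- H_next
  }
  t_out
}

#' Attach class-conditional biomarkers to patient records
#'
#' Samples serum IL-6 (lognormal, arithmetic class means preserved exactly
#' after mean-correction for the coupling and residual variance), optional
#' norepinephrine (lognormal, hypertension-conditional means) and a unitless
#' default-mode-network hyperconnectivity score (Gaussian, shifted upward in
#' the resistant class).  IL-6 is coupled to the latent recurrence-time
#' quantile (`latent_quantile` column; standard normal, large values mean
#' short recurrence times), so the marginal correlation between IL-6 and
#' observed pain-free time is tunable via `cfg$il6_coupling`.
#'
#' Uses the current RNG state; [generate_cohort()] calls it inside the
#' biomarker sub-stream.
#'
#' @param records data.frame with a `latent_class` column; optional
#'   `latent_quantile` (defaults to fresh standard-normal draws) and
#'   `hypertension` (defaults to 0) columns.
#' @param cfg a [cohort_config()] with `il6_coupling` set.
#' @return `records` with `il6`, `norepinephrine` (if enabled) and
#'   `dmn_score` columns added or replaced.
#' @export
sample_biomarkers <- function(records, cfg) {
  if (is.null(records$latent_class)) stop("records must carry a latent_class column")
  n <- nrow(records)
  gamma <- cfg$il6_coupling
  if (is.null(gamma)) stop("cfg$il6_coupling is not set")
  q <- records$latent_quantile
  if (is.null(q)) q <- rnorm(n)
  sd_log <- cfg$il6_params$log_sd
  res <- records$latent_class == "resistant"
  m <- ifelse(res, cfg$il6_params$mean["resistant"], cfg$il6_params$mean["sensitive"])
  # lognormal mean-correction: E[exp(gamma*q + sd*eps)] = exp((gamma^2+sd^2)/2)
  mu <- log(m) - (gamma^2 + sd_log^2) / 2
  records$il6 <- exp(mu + gamma * q + sd_log * rnorm(n))

  ne <- cfg$norepinephrine
  if (isTRUE(ne$enabled)) {
    hyp <- records$hypertension
    if (is.null(hyp)) hyp <- rep(0L, n)
    m_ne <- ifelse(hyp == 1, ne$mean["hypertensive"], ne$mean["normotensive"])
    mu_ne <- log(m_ne) - ne$log_sd^2 / 2
    records$norepinephrine <- exp(mu_ne + ne$log_sd * rnorm(n))
  }
  records$dmn_score <- rnorm(n, mean = ifelse(res, cfg$dmn_shift, 0), sd = 1)
  records
}

#' Apply MCAR missingness to covariate columns
#'
#' Masks the designated covariate columns completely at random at the given
#' rate.  Outcome columns (`time_to_recurrence`, `event`), identifiers and
#' generator-truth columns may never be masked.
#'
#' @param cohort a `tn_cohort` data.frame.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed (sub-stream offset 6 of the cohort RNG scheme).
#' @param fields columns eligible for masking.
#' @return the cohort with `NA`s injected; attribute `missing_fields` records
#'   the masked columns.
#' @export
inject_missingness <- function(cohort, rate,
                               seed = attr(cohort, "seed"),
                               fields = c("il6", "dmn_score",
                                          "symptom_duration", "hypertension",
                                          "diabetes", "norepinephrine")) {
  check_prob(rate, "missing_rate", open_right = TRUE)
  protected <- c("patient_id", "time_to_recurrence", "event",
                 "latent_class", "latent_quantile")
  bad <- intersect(fields, protected)
  if (length(bad)) {
    stop(sprintf("columns may not be masked: %s", paste(bad, collapse = ", ")))
  }
  fields <- intersect(fields, names(cohort))
  if (rate == 0 || nrow(cohort) == 0) return(cohort)
  out <- with_substream(seed, 6, {
    for (f in fields) {
      cohort[[f]][runif(nrow(cohort)) < rate] <- NA
    }
    cohort
  })
  attr(out, "missing_fields") <- fields
  out
}

#' Write / read a cohort as CSV
#'
#' One row per patient, header included, missing values as empty cells.
#'
#' @param cohort a `tn_cohort`.
#' @param path file path.
#' @return `read_cohort` returns a `tn_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = c(patient_id = "character"))
  structure(df, class = c("tn_cohort", "data.frame"))
}

#' @export
print.tn_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TN salvage cohort: %d patients (%d recurrences, %d censored)\n",
              nrow(x), sum(x$event == 1, na.rm = TRUE),
              sum(x$event == 0, na.rm = TRUE)))
  NextMethod()
}
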