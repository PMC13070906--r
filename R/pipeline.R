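#' Pipeline configuration
#'
#' Bundles the sub-configurations of the full analysis chain: cohort
#' generation, optional missingness + multiple imputation, epoch survival
#' analysis, latent class analysis, and the two-arm cost-utility model.
#'
#' @param cohort a (preferably calibrated) [cohort_config()].
#' @param imputation list: `m` (imputations) and `enabled`.
#' @param survival list: `epoch_cutpoint`.
#' @param lca list: `K_max`, `restarts`, `thresholds`.
#' @param cua list with `death_prob` for [default_cua_arms()], or `arms`
#'   holding pre-built specs.
#' @param psa_draws Monte-Carlo draws for the probabilistic sensitivity
#'   analysis (0 disables it).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = calibrated_cohort_config(),
                            imputation = list(enabled = FALSE, m = 5),
                            survival = list(epoch_cutpoint = 2),
                            lca = list(K_max = 3, restarts = 20,
                                       thresholds = list(age = 70, il6 = 20,
                                                         dmn = NULL)),
                            cua = list(death_prob = 0.002),
                            psa_draws = 0) {
  if (imputation$m < 1) stop("imputation m must be >= 1")
  structure(list(cohort = cohort, imputation = imputation,
                 survival = survival, lca = lca, cua = cua,
                 psa_draws = psa_draws),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: generate cohort -> (optional MCAR masking + multiple imputation)
#' -> Kaplan-Meier, median, log-rank by hypertension -> epoch-partitioned
#' Cox -> discretize + latent class analysis + class-outcome hazard ratio ->
#' two-arm Markov cost-utility comparison (+ optional PSA) -> report bundle.
#' Deterministic given the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed; defaults to the cohort config seed.
#' @return a `report_bundle` list: `table1`, `table2`, `table3`, `km`
#'   (overall curve), `km_median`, `logrank_hypertension`, `lca`,
#'   `class_hr`, `ce_result`, `psa` (or NULL), `cohort`, `manifest`.
#' @export
run_pipeline <- function(config, seed = config$cohort$seed) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- stage("generate", {
    if (config$cohort$n == 0) stop("cohort size n = 0; nothing to analyse")
    generate_cohort(config$cohort, seed = seed)
  })
  analysis <- cohort
  imput <- NULL
  if (isTRUE(config$imputation$enabled) && config$cohort$missing_rate > 0) {
    analysis <- stage("missingness",
                      inject_missingness(cohort, config$cohort$missing_rate,
                                         seed = seed))
    imput <- stage("imputation",
                   impute_missing(analysis, m = config$imputation$m,
                                  seed = seed))
    analysis <- imput$completed[[1]]
  }

  km <- stage("kaplan-meier",
              km_estimate(analysis$time_to_recurrence, analysis$event))
  med <- km_median(km)
  lr <- stage("log-rank",
              log_rank(analysis$time_to_recurrence, analysis$event,
                       analysis$hypertension))
  cut <- config$survival$epoch_cutpoint
  cox <- stage("epoch-cox", {
    if (!is.null(imput)) {
      pooled_epoch_cox(imput, cutpoint = cut)
    } else {
      epoch_cox(analysis, cutpoint = cut)$terms
    }
  })

  lca_res <- stage("latent-class", {
    ind <- discretize_features(analysis, thresholds = config$lca$thresholds)
    sel <- select_K(ind, K_max = config$lca$K_max,
                    restarts = config$lca$restarts, seed = seed)
    sel
  })
  class_hr <- stage("class-association", {
    best <- lca_res$models[[lca_res$K_best]]
    if (best$K < 2) {
      NULL
    } else {
      # align estimated classes: the class with the higher IL-6 item-response
      # probability plays the resistant role
      res_class <- which.max(best$rho[, "il6_ge_cut"])
      labels <- ifelse(best$map == res_class, "resistant", "sensitive")
      class_outcome_association(labels, analysis$time_to_recurrence,
                                analysis$event)
    }
  })

  arms <- stage("cua-calibration", {
    if (!is.null(config$cua$arms)) config$cua$arms
    else default_cua_arms(death_prob = config$cua$death_prob)
  })
  traces <- list(new = run_cohort_trace(arms$new),
                 comp = run_cohort_trace(arms$comp))
  ce <- stage("cua-compare", compare_arms(traces$new, traces$comp))
  psa_res <- NULL
  if (config$psa_draws > 0) {
    psa_res <- stage("psa", psa(
      arms$new, arms$comp,
      distributions = default_psa_distributions(arms),
      n_draws = config$psa_draws, seed = seed))
  }

  bundle <- list(
    table1 = table1_analogue(cohort),
    table2 = cox,
    table3 = table3_analogue(traces, arms),
    km = km, km_median = med, logrank_hypertension = lr,
    lca = lca_res, class_hr = class_hr,
    ce_result = ce, psa = psa_res,
    cohort = cohort,
    manifest = list(seed = as.integer(seed),
                    config_fingerprint = object_fingerprint(config),
                    cohort_fingerprint = attr(cohort, "config_fingerprint"),
                    n = nrow(cohort),
                    package_version = as.character(utils::packageVersion("tnsalvage"))))
  class(bundle) <- "report_bundle"
  bundle
}

# Default PSA parameter uncertainty: Beta on transition probabilities and
# utilities (moment-matched around the base value), Gamma on costs.
default_psa_distributions <- function(arms) {
  beta_around <- function(p, kappa = 100) {
    list(dist = "beta", shape1 = p * kappa, shape2 = (1 - p) * kappa)
  }
  gamma_around <- function(mu, cv = 0.2) {
    shape <- 1 / cv^2
    list(dist = "gamma", shape = shape, rate = shape / mu)
  }
  list(
    "new.p_reintervention" = beta_around(arms$new$p_reintervention),
    "comp.p_reintervention" = beta_around(arms$comp$p_reintervention),
    "new.state_costs.Recurred" = gamma_around(arms$new$state_costs[["Recurred"]]),
    "comp.state_costs.Recurred" = gamma_around(arms$comp$state_costs[["Recurred"]]),
    "new.utilities.Recurred" = beta_around(arms$new$utilities[["Recurred"]]),
    "comp.utilities.Recurred" = beta_around(arms$comp$utilities[["Recurred"]]))
}

# Baseline-characteristics analogue: count (percent) for flags,
# mean +/- sd for continuous variables.
table1_analogue <- function(cohort) {
  n <- nrow(cohort)
  pct <- function(x) {
    k <- sum(x, na.rm = TRUE)
    sprintf("%d (%.1f%%)", k, 100 * k / n)
  }
  msd <- function(x) sprintf("%.2f ± %.2f", mean(x, na.rm = TRUE),
                             sd(x, na.rm = TRUE))
  data.frame(
    variable = c("Age (years)", "Symptom duration (years)", "Female",
                 "Hypertension", "Diabetes", "V2/V3 involvement",
                 "V1 involvement", "TN1 diagnosis", "TN2 diagnosis",
                 "Immediate relief (BNI I-III)", "Facial numbness"),
    value = c(msd(cohort$age), msd(cohort$symptom_duration),
              pct(cohort$sex == "female"), pct(cohort$hypertension == 1),
              pct(cohort$diabetes == 1), pct(cohort$v2v3_involved == 1),
              pct(cohort$v1_involved == 1), pct(cohort$tn_type == "TN1"),
              pct(cohort$tn_type == "TN2"),
              pct(cohort$immediate_relief == 1),
              pct(cohort$facial_numbness == 1)),
    stringsAsFactors = FALSE)
}

table3_analogue <- function(traces, arms) {
  reint5 <- function(spec) cumulative_reintervention(spec, 5)
  new <- c(cost = traces$new$discounted_cost, qaly = traces$new$discounted_qaly,
           reintervention_5y = reint5(arms$new))
  comp <- c(cost = traces$comp$discounted_cost,
            qaly = traces$comp$discounted_qaly,
            reintervention_5y = reint5(arms$comp))
  data.frame(metric = c("Cost", "QALYs", "5-year reintervention rate"),
             new = unname(new), comparator = unname(comp),
             difference = unname(new - comp), stringsAsFactors = FALSE)
}

#' Write / read a report bundle
#'
#' Serialises all bundle artifacts under a directory: cohort and curves as
#' CSV, models and results as JSON, plus a manifest with per-file md5
#' checksums.  `read_bundle` refuses directories without a manifest and
#' flags checksum mismatches (e.g. hand-edited cells).
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `write_bundle` returns `dir`; `read_bundle` returns the
#'   re-loaded artifact list.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_cohort(bundle$cohort, p("cohort.csv"))
  utils::write.csv(bundle$table1, p("table1.csv"), row.names = FALSE)
  utils::write.csv(bundle$table2, p("table2.csv"), row.names = FALSE)
  utils::write.csv(bundle$table3, p("table3.csv"), row.names = FALSE)
  write_curve(bundle$km, p("km_overall.csv"))
  best <- bundle$lca$models[[bundle$lca$K_best]]
  write_lca_json(best, p("lca_model.json"))
  utils::write.csv(bundle$lca$bic_table, p("lca_bic.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(bundle$ce_result), p("ce_result.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$class_hr)) {
    write_cox_json(bundle$class_hr, p("class_hr.json"))
  }
  if (!is.null(bundle$psa)) {
    utils::write.csv(bundle$psa$ceac, p("ceac.csv"), row.names = FALSE)
  }
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- bundle$manifest
  manifest$checksums <- as.list(tools::md5sum(file.path(dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a report bundle: manifest.json missing")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in names(manifest$checksums)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop(sprintf("bundle file missing: %s", f))
    sum_now <- unname(tools::md5sum(path))
    if (!identical(sum_now, manifest$checksums[[f]])) {
      stop(sprintf("checksum mismatch for %s: bundle has been modified", f))
    }
  }
  list(manifest = manifest,
       cohort = read_cohort(file.path(dir, "cohort.csv")),
       table1 = utils::read.csv(file.path(dir, "table1.csv")),
       table2 = utils::read.csv(file.path(dir, "table2.csv")),
       table3 = utils::read.csv(file.path(dir, "table3.csv")),
       km = utils::read.csv(file.path(dir, "km_overall.csv")),
       ce_result = jsonlite::read_json(file.path(dir, "ce_result.json"),
                                       simplifyVector = TRUE))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Analysis bundle: n = %d (seed %d)\n",
              x$manifest$n, x$manifest$seed))
  med <- x$km_median
  cat(sprintf("  median pain-free interval: %s\n",
              if (med$reached) sprintf("%.2f y", med$median) else "not reached"))
  cat(sprintf("  LCA: K_best = %d\n", x$lca$K_best))
  print(x$ce_result)
  invisible(x)
}
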