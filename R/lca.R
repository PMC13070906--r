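#' Discretize cohort features into binary LCA indicators
#'
#' Recodes the default six subtyping items mirroring the study's radar axes:
#' hypertension, V1 involvement, age >= 70 y, IL-6 >= 20 pg/mL, DMN
#' hyperconnectivity score above the class-pooled mean + 0.5 SD, and TN type 2.
#' Convention: `value >= threshold` codes 1.  Missing values are rejected;
#' impute first (see [impute_missing()]).
#'
#' @param cohort a `tn_cohort` data.frame.
#' @param thresholds named list of cutoffs for the continuous items: `age`,
#'   `il6`, `dmn` (NULL for `dmn` means data-derived pooled mean + 0.5 SD).
#' @return a `tn_indicators` object: binary matrix with `item_names` and
#'   `thresholds_used` attributes.
#' @export
discretize_features <- function(cohort,
                                thresholds = list(age = 70, il6 = 20,
                                                  dmn = NULL)) {
  need <- c("hypertension", "v1_involved", "age", "il6", "dmn_score", "tn_type")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop(sprintf("cohort lacks columns: %s",
                                 paste(miss, collapse = ", ")))
  if (anyNA(cohort[, need])) {
    stop("missing values present; run imputation before discretization")
  }
  dmn_cut <- thresholds$dmn
  if (is.null(dmn_cut)) {
    dmn_cut <- mean(cohort$dmn_score) + 0.5 * sd(cohort$dmn_score)
  }
  X <- cbind(
    hypertension = as.integer(cohort$hypertension == 1),
    v1_involved = as.integer(cohort$v1_involved == 1),
    age_ge_cut = as.integer(cohort$age >= thresholds$age),
    il6_ge_cut = as.integer(cohort$il6 >= thresholds$il6),
    dmn_high = as.integer(cohort$dmn_score >= dmn_cut),
    tn2 = as.integer(cohort$tn_type == "TN2"))
  structure(X, class = c("tn_indicators", class(X)),
            item_names = colnames(X),
            thresholds_used = list(age = thresholds$age, il6 = thresholds$il6,
                                   dmn = dmn_cut))
}

#' Latent class analysis by EM for binary indicators
#'
#' Fits a K-class finite mixture of independent Bernoulli items by
#' expectation-maximisation, taking the best of `restarts` seeded random
#' initialisations.  The log-likelihood is asserted non-decreasing at every
#' iteration; item-response probabilities are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param indicators binary matrix (subjects x items), e.g. from
#'   [discretize_features()].
#' @param K number of latent classes (>= 1).
#' @param restarts number of random restarts (>= 1).
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed; restart r uses sub-stream offset `8 + r`.
#' @param max_iter EM iteration cap per restart.
#' @return a `tn_lca` object: `K`, `pi` (class weights), `rho` (K x items
#'   response probabilities), `posterior`, `log_likelihood`, `bic`,
#'   `n_restarts`, `seed`, `map` (modal assignment; posterior ties go to the
#'   lower-index class).
#' @export
lca_em <- function(indicators, K, restarts = 20, tol = 1e-8, seed = 1L,
                   max_iter = 1000) {
  X <- unclass(as.matrix(indicators))
  if (!all(X %in% c(0, 1))) stop("indicators must be binary (impute first)")
  if (K < 1) stop("K must be >= 1")
  if (restarts < 1) stop("restarts must be >= 1")
  n <- nrow(X)
  J <- ncol(X)
  n_patterns <- nrow(unique(X))
  if (K > n_patterns) {
    warning(sprintf("degenerate model: K = %d exceeds the %d distinct response patterns",
                    K, n_patterns), call. = FALSE)
  }

  if (K == 1) {
    rho <- matrix(pmin(pmax(colMeans(X), 1e-6), 1 - 1e-6), 1, J,
                  dimnames = list("class1", colnames(X)))
    ll <- sum(X %*% t(log(rho)) + (1 - X) %*% t(log(1 - rho)))
    post <- matrix(1, n, 1)
    return(new_tn_lca(K, pi = 1, rho = rho, posterior = post, ll = ll,
                      n = n, J = J, restarts = restarts, seed = seed))
  }

  # collapse to unique response patterns: the likelihood depends on the data
  # only through pattern counts, so EM cost is O(#patterns x K) per iteration
  pat_id <- apply(X, 1, paste, collapse = "")
  first <- !duplicated(pat_id)
  Xp <- X[first, , drop = FALSE]
  w <- as.vector(table(factor(pat_id, levels = pat_id[first])))
  pat_index <- match(pat_id, pat_id[first])

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_substream(seed, 8 + r, lca_em_once(Xp, w, K, tol, max_iter))
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  new_tn_lca(K, pi = best$pi, rho = best$rho,
             posterior = best$post[pat_index, , drop = FALSE],
             ll = best$ll, n = n, J = J, restarts = restarts, seed = seed)
}

lca_em_once <- function(Xp, w, K, tol, max_iter) {
  n <- sum(w)
  J <- ncol(Xp)
  rho <- matrix(runif(K * J, 0.2, 0.8), K, J)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step in log space (per pattern)
    logp <- Xp %*% t(log(rho)) + (1 - Xp) %*% t(log(1 - rho))
    logp <- logp + rep(log(pi_k), each = nrow(Xp))
    mx <- do.call(pmax, as.data.frame(logp))
    pr <- exp(logp - mx)
    rs <- rowSums(pr)
    ll <- sum(w * (mx + log(rs)))
    if (ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
      stop("EM log-likelihood decreased; this should be impossible")
    }
    post <- pr / rs
    # M-step with pattern weights
    wpost <- post * w
    nk <- colSums(wpost)
    pi_k <- nk / n
    rho <- t(wpost) %*% Xp / nk
    rho <- pmin(pmax(rho, 1e-6), 1 - 1e-6)
    if (is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
  }
  dimnames(rho) <- list(paste0("class", seq_len(K)), colnames(Xp))
  list(pi = pi_k, rho = rho, post = post, ll = ll)
}

new_tn_lca <- function(K, pi, rho, posterior, ll, n, J, restarts, seed) {
  n_params <- (K - 1) + K * J
  structure(list(K = K, pi = pi, rho = rho, posterior = posterior,
                 log_likelihood = ll,
                 bic = -2 * ll + n_params * log(n),
                 n_params = n_params, n = n,
                 n_restarts = restarts, seed = as.integer(seed),
                 map = max.col(posterior, ties.method = "first")),
            class = "tn_lca")
}

#' @export
print.tn_lca <- function(x, ...) {
  cat(sprintf("Latent class model: K = %d, logLik = %.2f, BIC = %.2f\n",
              x$K, x$log_likelihood, x$bic))
  cat("  class weights:", paste(signif(x$pi, 4), collapse = ", "), "\n")
  cat("  item-response probabilities:\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' BIC-based selection of the number of latent classes
#'
#' Fits `K = 1..K_max` latent class models and returns the BIC minimiser.
#'
#' @inheritParams lca_em
#' @param K_max largest class count to try.
#' @return list with `K_best`, `bic_table` (data.frame of K, log_likelihood,
#'   n_params, bic) and `models` (the fitted `tn_lca` objects).
#' @export
select_K <- function(indicators, K_max = 3, restarts = 20, seed = 1L,
                     tol = 1e-8) {
  if (K_max < 1) stop("K_max must be >= 1")
  models <- lapply(seq_len(K_max), function(K) {
    lca_em(indicators, K, restarts = restarts, tol = tol, seed = seed)
  })
  tab <- data.frame(K = seq_len(K_max),
                    log_likelihood = vapply(models, `[[`, 0, "log_likelihood"),
                    n_params = vapply(models, `[[`, 0, "n_params"),
                    bic = vapply(models, `[[`, 0, "bic"))
  list(K_best = tab$K[which.min(tab$bic)], bic_table = tab, models = models)
}

#' Theoretical ceiling on latent-class recovery
#'
#' Exact Bayes accuracy of modal class assignment from the default indicator
#' set, computed by enumeration over the informative items (age, IL-6, DMN
#' score), which are conditionally independent given class in the generator.
#' EM-estimated modal assignments cannot beat this ceiling; on calibrated
#' cohorts they approach it to within sampling noise, which is what the
#' recovery tests assert.
#'
#' @param cfg a [cohort_config()] with `il6_coupling` set and class-independent
#'   hazard covariates (the default).
#' @param thresholds as in [discretize_features()] (`dmn = NULL` uses the
#'   population pooled mean + 0.5 SD).
#' @return list with `accuracy` (overall Bayes accuracy), and the per-class
#'   item probabilities used.
#' @export
class_recovery_ceiling <- function(cfg,
                                   thresholds = list(age = 70, il6 = 20,
                                                     dmn = NULL)) {
  mix <- cfg$class_mix
  tau <- sqrt(cfg$il6_coupling^2 + cfg$il6_params$log_sd^2)
  p_age <- pnorm(thresholds$age, cfg$age_mean[c("sensitive", "resistant")],
                 cfg$age_sd, lower.tail = FALSE)
  mu <- log(cfg$il6_params$mean[c("sensitive", "resistant")]) - tau^2 / 2
  p_il6 <- pnorm(log(thresholds$il6), mu, tau, lower.tail = FALSE)
  dmn_cut <- thresholds$dmn
  if (is.null(dmn_cut)) {
    pm <- mix * cfg$dmn_shift
    psd <- sqrt(1 + mix * (1 - mix) * cfg$dmn_shift^2)
    dmn_cut <- pm + 0.5 * psd
  }
  p_dmn <- pnorm(dmn_cut, c(0, cfg$dmn_shift), 1, lower.tail = FALSE)
  probs <- rbind(age = p_age, il6 = p_il6, dmn = p_dmn)
  colnames(probs) <- c("sensitive", "resistant")
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (d in 0:1) {
    pat <- c(a, b, d)
    lik <- apply(probs, 2, function(p) prod(p^pat * (1 - p)^(1 - pat)))
    acc <- acc + max((1 - mix) * lik["sensitive"], mix * lik["resistant"])
  }
  list(accuracy = unname(acc), item_probs = probs)
}

#' Association between latent class and recurrence-free survival
#'
#' Delegates to [cox_fit()] with the class indicator as the sole covariate;
#' the treatment-resistant class is the exposure (coded 1).
#'
#' @param labels class labels (factor or character); `exposure` names the
#'   resistant class.
#' @param times,events follow-up times and 0/1 event indicators.
#' @param exposure label treated as the exposed (resistant) class.
#' @param ... passed to [cox_fit()].
#' @return a `tn_cox` object with a single `resistant_class` term.
#' @export
class_outcome_association <- function(labels, times, events,
                                      exposure = "resistant", ...) {
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required")
  if (!exposure %in% lev) stop(sprintf("exposure level '%s' not present", exposure))
  x <- cbind(resistant_class = as.numeric(labels == exposure))
  cox_fit(times, events, x, ...)
}

#' Serialize a latent class model to JSON / posteriors to CSV
#'
#' @param model a `tn_lca` object.
#' @param path output JSON path.
#' @param posterior_path optional CSV path for the posterior matrix.
#' @export
write_lca_json <- function(model, path, posterior_path = NULL) {
  jsonlite::write_json(
    list(K = model$K, pi = model$pi,
         rho = as.data.frame(model$rho),
         log_likelihood = model$log_likelihood, bic = model$bic,
         n_restarts = model$n_restarts, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(posterior_path)) {
    utils::write.csv(as.data.frame(model$posterior), posterior_path,
                     row.names = FALSE)
  }
  invisible(path)
}
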