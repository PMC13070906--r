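#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"

# Sub-stream seed derivation: one seeded generator per cohort, with documented
# offsets per field block so that adding a later field never perturbs earlier
# draws.  Offsets: 1 covariates, 2 recurrence times, 3 censoring, 4 biomarkers,
# 5 response/complication flags, 6 missingness, 7 imputation, 8 LCA restarts,
# 9 PSA.
substream_seed <- function(seed, offset) {
  # double arithmetic: offsets up to ~1e6 stay exact well below 2^53
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483629)
}

# Evaluate expr under a temporary RNG state; restores the caller's state.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, offset))
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open_right = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_config(field, "must be numeric and non-missing")
  hi_ok <- if (open_right) all(x < 1) else all(x <= 1)
  if (!all(x >= 0) || !hi_ok) {
    stop_config(field, sprintf("probabilities must lie in [0,1%s", if (open_right) ")" else "]"))
  }
  invisible(x)
}

# md5 fingerprint of an arbitrary R object (serialised to a temp file).
object_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Truncated-normal draws by rejection (lower bound only); used for age and
# symptom duration, where the truncation mass is negligible (< 1e-3).
rnorm_pos <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}
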