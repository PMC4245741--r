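#' Configuration for the synthetic trial-data generator
#'
#' Defaults emulate the source trial: a two-arm wait-list RCT with 20
#' intervention and 16 control completers, right-skewed service-use counts
#' and 3-month utility means of about 0.65 versus 0.45, with a 12% drop-out
#' rate (41 randomised, 36 completing follow-up), completely at random.
#'
#' @param n_per_arm named counts, `c(control = 16, intervention = 20)`.
#' @param seed integer seed; generation is deterministic given the config.
#' @param targets a `trial_inputs` supplying the arm summaries to match
#'   (defaults to the shipped fixtures).
#' @param baseline_utility_means per-arm baseline utility means; defaults to
#'   the values back-solved from the reported AUC QALYs (derived, the trial
#'   never reported them).
#' @param dropout_rate probability a patient misses follow-up, in \[0, 1).
#' @param count_model `"poisson_gamma"` (negative binomial matched to the
#'   target mean/variance, falling back to Poisson with a message when the
#'   variance does not exceed the mean) or `"poisson"`.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_arm = c(control = 16, intervention = 20),
                             seed = 1,
                             targets = load_trial_inputs(),
                             baseline_utility_means = c(control = 0.513,
                                                        intervention = 0.594),
                             dropout_rate = 0.12,
                             count_model = c("poisson_gamma", "poisson")) {
  count_model <- match.arg(count_model)
  stopifnot(all(c("control", "intervention") %in% names(n_per_arm)),
            all(n_per_arm >= 2),
            dropout_rate >= 0, dropout_rate < 1,
            inherits(targets, "trial_inputs"),
            all(c("control", "intervention") %in%
                  names(baseline_utility_means)))
  structure(list(n_per_arm = n_per_arm, seed = as.integer(seed),
                 targets = targets,
                 baseline_utility_means = baseline_utility_means,
                 dropout_rate = dropout_rate, count_model = count_model),
            class = "generator_config")
}

# Beta parameters matched to a mean/variance on the EQ-5D tariff range.
beta_moments <- function(mean, variance, lo = -0.594, hi = 1) {
  m <- (mean - lo) / (hi - lo)
  v <- variance / (hi - lo)^2
  if (v <= 0 || v >= m * (1 - m))
    stop("generator-config error: utility moments (", mean, ", ", variance,
         ") unreachable by a beta on [", lo, ", ", hi, "]", call. = FALSE)
  common <- m * (1 - m) / v - 1
  list(shape1 = m * common, shape2 = (1 - m) * common, lo = lo, hi = hi)
}

rbeta_scaled <- function(n, mean, variance) {
  b <- beta_moments(mean, variance)
  b$lo + (b$hi - b$lo) * stats::rbeta(n, b$shape1, b$shape2)
}

#' Generate a synthetic patient-level trial cohort
#'
#' Per patient: arm, baseline and 3-month EQ-5D utilities drawn from beta
#' distributions moment-matched to the target means and variances (then
#' clipped to the tariff range by construction), and one count per resource
#' category available to the arm, drawn from a Poisson-gamma (negative
#' binomial) matched to the target mean/variance. Drop-outs are flagged and
#' their follow-up utility and counts withheld.
#'
#' @param config a [generator_config()].
#' @return Data frame with columns `id`, `arm`, `dropout`, `u_baseline`,
#'   `u_3month` and one `count_<category>` column per category (NA where the
#'   category is unavailable to the arm or the patient dropped out), with
#'   the config attached as attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 42))
#' table(cohort$arm, cohort$dropout)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  targets <- config$targets
  all_cats <- targets$categories$category
  arms <- c("control", "intervention")

  per_arm <- lapply(arms, function(a) {
    n <- config$n_per_arm[[a]]
    arm <- targets$arms[[a]]
    d <- data.frame(arm = a,
                    dropout = stats::runif(n) < config$dropout_rate,
                    u_baseline = rbeta_scaled(
                      n, config$baseline_utility_means[[a]],
                      arm$utility_variance),
                    u_3month = rbeta_scaled(n, arm$utility_mean,
                                            arm$utility_variance),
                    stringsAsFactors = FALSE)
    fallback <- character(0)
    for (cat in all_cats) {
      row <- arm$usage[arm$usage$category == cat, ]
      col <- paste0("count_", cat)
      if (nrow(row) == 0) { d[[col]] <- NA_integer_; next }
      m <- row$mean; v <- row$variance
      d[[col]] <- if (config$count_model == "poisson_gamma" && v > m) {
        stats::rnbinom(n, mu = m, size = m^2 / (v - m))
      } else {
        if (config$count_model == "poisson_gamma" && v <= m)
          fallback <- c(fallback, cat)
        stats::rpois(n, m)
      }
    }
    if (length(fallback))
      message("generate_cohort (", a, "): variance <= mean, Poisson ",
              "fallback for ", paste(fallback, collapse = ", "))
    d
  })
  cohort <- do.call(rbind, per_arm)
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  count_cols <- grep("^count_", names(cohort), value = TRUE)
  cohort[cohort$dropout, c("u_3month", count_cols)] <- NA
  structure(cohort, config = config)
}

#' Recover arm-level summaries from a patient-level cohort
#'
#' Complete-case per-arm means and variances of the 3-month utility and of
#' every resource-category count, in the same shape as the reported summary
#' table, closing the loop between the patient-level and summary-level
#' pipelines.
#'
#' @param records a cohort from [generate_cohort()] (or any data frame in
#'   the same dialect).
#' @param bundled categories flagged as excluded from cost totals in the
#'   returned summaries.
#' @return List with elements `control` and `intervention`, each an
#'   [arm_summary()].
#' @export
roundtrip_summary <- function(records, bundled = dtu_bundled_categories()) {
  stopifnot(all(c("arm", "u_3month") %in% names(records)))
  count_cols <- grep("^count_", names(records), value = TRUE)
  out <- lapply(c(control = "control", intervention = "intervention"),
    function(a) {
      d <- records[records$arm == a & !is.na(records$u_3month), ]
      if (nrow(d) < 2)
        stop("insufficient data: fewer than 2 completers in ", a, " arm",
             call. = FALSE)
      cats <- count_cols[colSums(!is.na(d[count_cols])) > 0]
      usage <- data.frame(
        category = sub("^count_", "", cats),
        mean = vapply(d[cats], mean, numeric(1), na.rm = TRUE),
        variance = vapply(d[cats], stats::var, numeric(1), na.rm = TRUE),
        stringsAsFactors = FALSE)
      usage$in_total <- !(usage$category %in% bundled)
      rownames(usage) <- NULL
      arm_summary(a, mean(d$u_3month), stats::var(d$u_3month), usage)
    })
  out
}

#' Write a cohort with its generating manifest
#'
#' @param records a cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`cohort.csv`, `manifest.json`).
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  config <- attr(records, "config")
  manifest <- list(
    n_per_arm = as.list(config$n_per_arm),
    seed = config$seed,
    baseline_utility_means = as.list(config$baseline_utility_means),
    dropout_rate = config$dropout_rate,
    count_model = config$count_model,
    n_generated = nrow(records),
    n_completers = sum(!records$dropout))
  json <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(cohort = csv, manifest = json))
}
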