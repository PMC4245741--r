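#' Categories bundled into the day-therapy attendance fee
#'
#' The hospice-supplied cost per day-therapy-unit (DTU) attendance is a
#' per-attendance fee for the service as delivered, and the physiotherapy
#' and "other" hospice services recorded for the intervention arm are
#' delivered during those attendances. Pricing them separately on top of
#' the attendance fee double-counts them and is inconsistent with the
#' trial's reported deterministic total expected cost; they are therefore
#' excluded from arm totals by default. Pass `bundled = character(0)` to
#' [load_trial_inputs()] to price every recorded category.
#'
#' @return Character vector of category names.
#' @export
dtu_bundled_categories <- function() {
  c("hospice_physiotherapy", "other_hospice")
}

#' Per-arm summary of utilities and resource use
#'
#' @param arm `"control"` or `"intervention"`.
#' @param utility_mean,utility_variance 3-month EQ-5D utility moments; the
#'   mean must lie in the UK tariff range \[-0.594, 1\].
#' @param usage data frame with columns `category`, `mean`, `variance`
#'   (counts per 3 months) and logical `in_total`.
#' @return An object of class `arm_summary`.
#' @export
arm_summary <- function(arm = c("control", "intervention"),
                        utility_mean, utility_variance, usage) {
  arm <- match.arg(arm)
  stopifnot(utility_mean >= -0.594, utility_mean <= 1, utility_variance >= 0)
  stopifnot(is.data.frame(usage),
            all(c("category", "mean", "variance", "in_total") %in% names(usage)))
  if (anyDuplicated(usage$category))
    stop("duplicate resource category in arm summary", call. = FALSE)
  if (any(usage$mean < 0) || any(usage$variance < 0))
    stop("usage means and variances must be non-negative", call. = FALSE)
  structure(list(arm = arm, utility_mean = utility_mean,
                 utility_variance = utility_variance,
                 usage = usage[order(usage$category), , drop = FALSE]),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("<arm_summary: %s> utility %.3f (s2 %.4g), %d categories\n",
              x$arm, x$utility_mean, x$utility_variance, nrow(x$usage)))
  invisible(x)
}

check_headers <- function(df, expected, file) {
  if (!identical(names(df), expected))
    stop("fixture ", file, " has headers [", paste(names(df), collapse = ","),
         "]; expected [", paste(expected, collapse = ","), "]", call. = FALSE)
}

#' Load the trial's summary-statistic fixtures
#'
#' Reads the reported arm-level resource-use and utility summaries, national
#' and hospice unit costs, the per-arm QALY credible intervals used by the
#' interval-implied parameter mode, and the baseline-adjusted QALY-difference
#' rows, all shipped as plain CSV under `inst/extdata`. Headers are validated
#' exactly.
#'
#' @param path directory holding the fixture CSVs; defaults to the copies
#'   installed with the package.
#' @param bundled category names excluded from arm cost totals (see
#'   [dtu_bundled_categories()]).
#' @return A list of class `trial_inputs` with elements `arms` (list of two
#'   [arm_summary()]), `unit_costs` (named numeric, GBP per unit, 2010-2011
#'   prices), `categories` (registry data frame), `qaly_ci`, `adjusted_diff`
#'   and `fixture_files`.
#' @examples
#' inputs <- load_trial_inputs()
#' inputs$unit_costs[["dtu_attendance"]]
#' @export
load_trial_inputs <- function(path = system.file("extdata",
                                                 package = "hospicecua"),
                              bundled = dtu_bundled_categories()) {
  files <- c(usage = "table2_usage.csv",
             costs = "table3_unit_costs.csv",
             qaly_ci = "qaly_credible_intervals.csv",
             adj = "adjusted_qaly_differences.csv")
  paths <- file.path(path, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing fixture file(s): ", paste(files[missing], collapse = ", "),
         call. = FALSE)

  usage <- utils::read.csv(paths[["usage"]], stringsAsFactors = FALSE)
  check_headers(usage, c("category", "arm", "mean", "variance", "availability"),
                files[["usage"]])
  costs <- utils::read.csv(paths[["costs"]], stringsAsFactors = FALSE)
  check_headers(costs, c("category", "unit_cost_gbp", "unit_description",
                         "source"), files[["costs"]])
  qaly_ci <- utils::read.csv(paths[["qaly_ci"]], stringsAsFactors = FALSE)
  check_headers(qaly_ci, c("method", "horizon_months", "arm", "mean",
                           "ci_low", "ci_high"), files[["qaly_ci"]])
  adj <- utils::read.csv(paths[["adj"]], stringsAsFactors = FALSE)
  check_headers(adj, c("horizon_months", "mean_diff", "se_diff"),
                files[["adj"]])

  if (any(costs$unit_cost_gbp <= 0))
    stop("unit costs must be positive", call. = FALSE)
  if (anyDuplicated(costs$category))
    stop("duplicate category in unit-cost table", call. = FALSE)
  unit_costs <- stats::setNames(costs$unit_cost_gbp, costs$category)

  res <- usage[usage$category != "utility", , drop = FALSE]
  unpriced <- setdiff(res$category, names(unit_costs))
  if (length(unpriced))
    stop("missing cost: no unit cost for ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  registry <- unique(res[, c("category", "availability")])
  if (anyDuplicated(registry$category))
    stop("category listed with conflicting availability", call. = FALSE)
  registry$in_total <- !(registry$category %in% bundled)

  mk_arm <- function(a) {
    u <- usage[usage$category == "utility" & usage$arm == a, ]
    r <- res[res$arm == a, c("category", "mean", "variance")]
    r$in_total <- !(r$category %in% bundled)
    arm_summary(a, u$mean, u$variance, r)
  }
  structure(list(
    arms = list(control = mk_arm("control"),
                intervention = mk_arm("intervention")),
    unit_costs = unit_costs,
    categories = registry,
    qaly_ci = qaly_ci,
    adjusted_diff = adj,
    fixture_files = paths
  ), class = "trial_inputs")
}

#' Aggregate rarely used services into one costed category
#'
#' Services accessed too infrequently to model individually are pooled:
#' the combined unit cost is the frequency-weighted average of the member
#' unit costs, and the combined mean use is the total frequency normalised
#' per participant.
#'
#' @param frequency non-negative access counts, one per service (not all 0).
#' @param unit_cost GBP per unit for each service.
#' @param n_participants denominator for mean use (default 1 returns the
#'   total frequency).
#' @return List with `mean_use` and `unit_cost`.
#' @examples
#' aggregate_rare_services(c(3, 1), c(20, 60)) # unit_cost 30
#' @export
aggregate_rare_services <- function(frequency, unit_cost, n_participants = 1) {
  stopifnot(length(frequency) == length(unit_cost), length(frequency) >= 1,
            n_participants > 0)
  if (any(frequency < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (sum(frequency) == 0)
    stop("empty aggregate: all service frequencies are zero", call. = FALSE)
  list(mean_use = sum(frequency) / n_participants,
       unit_cost = sum(frequency * unit_cost) / sum(frequency))
}
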