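#' Endpoint (crude) QALYs over a short horizon
#'
#' The crude method credits the full 3-month utility level for the whole
#' horizon: `QALY = u_3month * horizon_years`. Three months is converted to
#' exactly 0.25 years.
#'
#' @param u_3month utility at 3 months (vectorised).
#' @param horizon_years horizon in years (> 0), default 0.25.
#' @return QALYs.
#' @examples
#' endpoint_qaly(0.447) # 0.11175
#' @export
endpoint_qaly <- function(u_3month, horizon_years = 0.25) {
  stopifnot(horizon_years > 0)
  u_3month * horizon_years
}

#' Area-under-the-curve QALYs between baseline and 3 months
#'
#' Trapezoid rule with two nodes, assuming utility changes linearly between
#' the baseline and 3-month measurements:
#' `QALY = (u_baseline + u_3month) / 2 * horizon_years`.
#'
#' @param u_baseline,u_3month utilities at the two measurement points
#'   (vectorised).
#' @param horizon_years horizon in years (> 0), default 0.25.
#' @return QALYs.
#' @examples
#' auc_qaly(0.513, 0.447) # 0.12
#' @export
auc_qaly <- function(u_baseline, u_3month, horizon_years = 0.25) {
  stopifnot(horizon_years > 0)
  (u_baseline + u_3month) / 2 * horizon_years
}

#' Extrapolate 3-month QALYs assuming benefit is maintained
#'
#' Beyond the trial window each arm is assumed to hold its 3-month utility
#' level, so the between-arm difference observed at 3 months is maintained:
#' `QALY = q_3month + u_3month * extra_months / 12`. Costs are never
#' extended (no between-arm cost difference is assumed after 3 months).
#'
#' @param q_3month QALYs accrued over the first 3 months (vectorised).
#' @param u_3month utility at 3 months (vectorised).
#' @param extra_months additional months of maintained benefit: 0, 3, 6 or 9.
#' @return QALYs over the extended horizon.
#' @examples
#' extrapolate_qaly(0.120, 0.447, 3) # 0.23175, six-month horizon
#' @export
extrapolate_qaly <- function(q_3month, u_3month, extra_months) {
  if (!(length(extra_months) == 1L && extra_months %in% c(0, 3, 6, 9)))
    stop("unsupported horizon: extra_months must be one of 0, 3, 6, 9",
         call. = FALSE)
  q_3month + u_3month * extra_months / 12
}

#' Baseline-adjusted between-arm QALY difference
#'
#' Ordinary least squares of individual QALYs on an intervention indicator
#' and baseline utility, the standard covariate adjustment for baseline
#' imbalance in trial-based economic evaluation. The arm coefficient is the
#' adjusted mean difference; its conventional standard error is reported.
#' The difference is assumed normal when sampled downstream.
#'
#' Drop-outs (missing baseline or follow-up utility, or missing `qaly`) are
#' excluded as complete-case with a logged count.
#'
#' @param records data frame with columns `arm` ("control"/"intervention"),
#'   `u_baseline`, `u_3month`, and optionally `qaly` (individual QALYs; if
#'   absent, computed by `qaly_method` from the two utilities).
#' @param qaly_method how to form individual QALYs when no `qaly` column is
#'   supplied: `"auc"` (default) or `"endpoint"`.
#' @return List of class `adjusted_diff` with `mean_diff`, `se_diff`
#'   (QALYs), `u_mean_diff`, `u_se_diff` (the same regression on 3-month
#'   utility, used to extrapolate), `n` and `horizon_months = 3`.
#' @export
baseline_adjusted_diff <- function(records, qaly_method = c("auc", "endpoint")) {
  qaly_method <- match.arg(qaly_method)
  stopifnot(all(c("arm", "u_baseline", "u_3month") %in% names(records)))
  if (!"qaly" %in% names(records))
    records$qaly <- switch(qaly_method,
      auc = auc_qaly(records$u_baseline, records$u_3month),
      endpoint = endpoint_qaly(records$u_3month))
  complete <- stats::complete.cases(
    records[, c("arm", "u_baseline", "u_3month", "qaly")])
  n_drop <- sum(!complete)
  if (n_drop > 0)
    message("baseline_adjusted_diff: excluding ", n_drop,
            " incomplete record(s) (complete-case analysis)")
  d <- records[complete, , drop = FALSE]
  if (any(table(factor(d$arm, levels = c("control", "intervention"))) < 3))
    stop("need at least 3 complete patients per arm", call. = FALSE)
  d$treat <- as.integer(d$arm == "intervention")
  fit_q <- stats::lm(qaly ~ treat + u_baseline, data = d)
  fit_u <- stats::lm(u_3month ~ treat + u_baseline, data = d)
  if (any(is.na(stats::coef(fit_q))))
    stop("degenerate design: baseline utilities collinear with arm",
         call. = FALSE)
  sq <- summary(fit_q)$coefficients
  su <- summary(fit_u)$coefficients
  structure(list(horizon_months = 3,
                 mean_diff = unname(sq["treat", "Estimate"]),
                 se_diff = unname(sq["treat", "Std. Error"]),
                 u_mean_diff = unname(su["treat", "Estimate"]),
                 u_se_diff = unname(su["treat", "Std. Error"]),
                 n = nrow(d)),
            class = "adjusted_diff")
}

#' @export
print.adjusted_diff <- function(x, ...) {
  cat(sprintf(
    "Baseline-adjusted QALY difference at %d months: %.4f (SE %.4f), n = %d\n",
    x$horizon_months, x$mean_diff, x$se_diff, x$n))
  invisible(x)
}

#' Baseline-adjusted differences across extrapolation horizons
#'
#' Extends the 3-month adjusted QALY difference to 6/9/12-month horizons by
#' adding quarters of the adjusted 3-month *utility* difference
#' (`diff_h = diff_3m + u_diff * extra/12`), with standard errors combined
#' on the same linear scale assuming the two regression coefficients are
#' estimated from the same fit (conservatively treated as perfectly
#' correlated, since both are driven by the same arm contrast).
#'
#' @param adj an `adjusted_diff` from [baseline_adjusted_diff()].
#' @param horizons months, subset of `c(3, 6, 9, 12)`.
#' @return Data frame with columns `horizon_months`, `mean_diff`, `se_diff`.
#' @export
adjusted_diff_table <- function(adj, horizons = c(3, 6, 9, 12)) {
  stopifnot(inherits(adj, "adjusted_diff"), all(horizons %in% c(3, 6, 9, 12)))
  extra <- horizons - 3
  data.frame(horizon_months = horizons,
             mean_diff = adj$mean_diff + adj$u_mean_diff * extra / 12,
             se_diff = adj$se_diff + adj$u_se_diff * extra / 12)
}

#' Load an EQ-5D-3L value-set coefficient table
#'
#' @param path CSV with columns `term`, `coefficient`; defaults to the UK
#'   time-trade-off social tariff shipped with the package.
#' @return Named numeric vector of coefficients.
#' @export
load_eq5d_value_set <- function(path = system.file(
    "extdata", "eq5d_uk_tto_value_set.csv", package = "hospicecua")) {
  vs <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(vs, c("term", "coefficient"), basename(path))
  dims <- c("mobility", "self_care", "usual_activities", "pain_discomfort",
            "anxiety_depression")
  needed <- c("constant", "n3", paste0(rep(dims, each = 2), "_", 2:3))
  missing <- setdiff(needed, vs$term)
  if (length(missing))
    stop("value set missing term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  stats::setNames(vs$coefficient, vs$term)
}

#' EQ-5D-3L utility from a five-dimension profile
#'
#' Additive tariff: utility = 1, minus a constant if any dimension departs
#' from level 1, minus each dimension's level-2 or level-3 decrement, minus
#' an extra "N3" decrement if any dimension is at level 3.
#'
#' @param profile integer vector of five levels in 1..3 (order: mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression), or a
#'   matrix with five columns for vectorised evaluation.
#' @param value_set named coefficients from [load_eq5d_value_set()].
#' @return Utility value(s) on the tariff scale (1 = full health).
#' @examples
#' eq5d_utility(c(1, 1, 1, 1, 1)) # 1
#' eq5d_utility(c(3, 3, 3, 3, 3)) # -0.594 (UK tariff floor)
#' @export
eq5d_utility <- function(profile, value_set = load_eq5d_value_set()) {
  m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1)
  if (ncol(m) != 5 || !all(m %in% 1:3))
    stop("malformed profile: need five dimension levels, each in 1..3",
         call. = FALSE)
  dims <- c("mobility", "self_care", "usual_activities", "pain_discomfort",
            "anxiety_depression")
  dec <- matrix(0, nrow(m), 5)
  for (j in 1:5) {
    dec[m[, j] == 2, j] <- value_set[[paste0(dims[j], "_2")]]
    dec[m[, j] == 3, j] <- value_set[[paste0(dims[j], "_3")]]
  }
  any_dys <- apply(m > 1, 1, any)
  any_l3 <- apply(m == 3, 1, any)
  u <- 1 - any_dys * value_set[["constant"]] - rowSums(dec) -
    any_l3 * value_set[["n3"]]
  if (!is.matrix(profile)) u <- u[[1]]
  u
}
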