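#' Deterministic 3-month expected cost of one arm
#'
#' Prices each resource category at its reported mean use times its unit
#' cost. Unrounded values are carried; rounding to whole pounds happens only
#' in the print method. Categories flagged as bundled into the day-therapy
#' attendance fee are reported as memo rows but excluded from the total
#' unless `include_bundled = TRUE`.
#'
#' @param summary an [arm_summary()].
#' @param costs named numeric unit-cost vector (GBP per unit).
#' @param include_bundled include bundled categories in the total?
#' @return A `cost_breakdown`: data frame with columns `category`,
#'   `mean_use`, `unit_cost`, `expected_cost`, `in_total`, with attributes
#'   `total` and `arm`.
#' @examples
#' inputs <- load_trial_inputs()
#' deterministic_cost(inputs$arms$control, inputs$unit_costs)
#' @export
deterministic_cost <- function(summary, costs, include_bundled = FALSE) {
  stopifnot(inherits(summary, "arm_summary"))
  u <- summary$usage
  unpriced <- setdiff(u$category, names(costs))
  if (length(unpriced))
    stop("missing cost: no unit cost for ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  bd <- data.frame(category = u$category,
                   mean_use = u$mean,
                   unit_cost = unname(costs[u$category]),
                   in_total = u$in_total | include_bundled,
                   stringsAsFactors = FALSE)
  bd$expected_cost <- bd$mean_use * bd$unit_cost
  structure(bd[, c("category", "mean_use", "unit_cost", "expected_cost",
                   "in_total")],
            total = sum(bd$expected_cost[bd$in_total]),
            arm = summary$arm,
            class = c("cost_breakdown", "data.frame"))
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Deterministic 3-month expected cost, %s arm (GBP)\n",
              attr(x, "arm")))
  shown <- x
  shown$expected_cost <- round(shown$expected_cost)
  print.data.frame(shown, row.names = FALSE)
  cat(sprintf("Total expected cost: £%s\n",
              format(round(attr(x, "total")), big.mark = ",")))
  invisible(x)
}

#' Total cost of sampled resource-use counts
#'
#' `total = mff * sum(count_i * unit_cost_i)` per simulation. The same
#' market-forces-factor draw must be applied to both arms within one
#' simulation; the caller passes the shared vector.
#'
#' @param counts numeric matrix, one row per simulation, one column per
#'   category (column names must match `costs` names).
#' @param costs named numeric unit-cost vector covering every column.
#' @param mff positive multiplier, length 1 or `nrow(counts)`.
#' @return Numeric vector of per-simulation totals (GBP).
#' @export
sampled_cost <- function(counts, costs, mff = 1) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("count matrix must have category column names", call. = FALSE)
  unpriced <- setdiff(colnames(counts), names(costs))
  if (length(unpriced))
    stop("missing cost: no unit cost for ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  if (any(counts < 0))
    stop("sampling-contract violation: negative sampled count", call. = FALSE)
  if (any(mff <= 0))
    stop("sampling-contract violation: non-positive mff multiplier",
         call. = FALSE)
  drop(mff * (counts %*% costs[colnames(counts)]))
}
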