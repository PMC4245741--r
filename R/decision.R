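#' Incremental cost-effectiveness ratio of mean increments
#'
#' Computed as the ratio of the Monte-Carlo mean incremental cost to the
#' mean incremental QALYs (never as a mean of per-draw ratios, which is
#' unstable). When the intervention is cheaper and more effective it is
#' reported as `"dominant"`; costlier and less effective as `"dominated"`.
#' A negative ratio is uninterpretable, so when the QALY difference is
#' negative the south-west quadrant label is reported instead of a number,
#' and a zero QALY difference yields an undefined-ratio flag without
#' division.
#'
#' @param delta_cost mean incremental cost (GBP).
#' @param delta_qaly mean incremental QALYs.
#' @return List of class `icer_result` with `icer` (GBP/QALY or `NA`),
#'   `label` (`"ratio"`, `"dominant"`, `"dominated"`, `"SW"` or
#'   `"undefined"`), `delta_cost` and `delta_qaly`.
#' @examples
#' icer(735, 0.05165) # ~£14,231 per QALY
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(length(delta_cost) == 1L, length(delta_qaly) == 1L)
  res <- if (delta_qaly == 0) {
    list(icer = NA_real_, label = "undefined")
  } else if (delta_qaly > 0) {
    if (delta_cost < 0) list(icer = NA_real_, label = "dominant")
    else list(icer = delta_cost / delta_qaly, label = "ratio")
  } else {
    if (delta_cost > 0) list(icer = NA_real_, label = "dominated")
    else list(icer = NA_real_, label = "SW")
  }
  structure(c(res, list(delta_cost = delta_cost, delta_qaly = delta_qaly)),
            class = "icer_result")
}

#' @export
format.icer_result <- function(x, ...) {
  if (x$label == "ratio")
    sprintf("£%s per QALY", format(round(x$icer), big.mark = ","))
  else x$label
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("ICER: %s (dC £%.0f, dQ %.4f)\n", format(x), x$delta_cost,
              x$delta_qaly))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_qaly - delta_cost` at willingness-to-pay `wtp`
#' (GBP/QALY). Vectorised over all arguments.
#'
#' @param wtp willingness to pay per QALY (>= 0).
#' @param delta_qaly incremental QALYs.
#' @param delta_cost incremental cost (GBP).
#' @return Net monetary benefit in GBP.
#' @export
nmb <- function(wtp, delta_qaly, delta_cost) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability the intervention is
#' cost-effective is the fraction of simulations with strictly positive net
#' monetary benefit (a draw with NMB exactly zero counts as not
#' cost-effective).
#'
#' @param draws a `psa_draws` from [run_psa()].
#' @param wtp_grid willingness-to-pay values; defaults to the grid in the
#'   draws' configuration.
#' @return Data frame of class `ceac_curve` with columns `wtp` and
#'   `probability`.
#' @export
ceac <- function(draws, wtp_grid = NULL) {
  stopifnot(inherits(draws, "psa_draws"), nrow(draws) > 0)
  if (is.null(wtp_grid)) wtp_grid <- attr(draws, "config")$wtp_grid
  inc <- incremental(draws)
  prob <- vapply(wtp_grid,
                 function(w) mean(nmb(w, inc$dq, inc$dc) > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Cost-effectiveness plane quadrant shares
#'
#' Fraction of simulations falling in each quadrant of the incremental
#' cost-effectiveness plane. Boundary draws (a zero increment) are assigned
#' to the more-costly / more-effective side, consistent with the strict
#' inequality used by [ceac()].
#'
#' @param draws a `psa_draws` from [run_psa()].
#' @return Named numeric vector summing to 1: `NE` (costlier, more
#'   effective), `SE` (cheaper, more effective — dominant), `SW` (cheaper,
#'   less effective), `NW` (costlier, less effective — dominated).
#' @export
ce_plane <- function(draws) {
  stopifnot(inherits(draws, "psa_draws"), nrow(draws) > 0)
  inc <- incremental(draws)
  up <- inc$dc >= 0
  eff <- inc$dq > 0
  c(NE = mean(up & eff), SE = mean(!up & eff),
    SW = mean(!up & !eff), NW = mean(up & !eff))
}

#' Per-person expected value of perfect information
#'
#' EVPI at a willingness-to-pay threshold: the expected net-benefit gain
#' from always choosing the better option per draw, over committing to the
#' better option on average. With the comparator as reference (NMB 0),
#' `EVPI = E[max(NMB, 0)] - max(E[NMB], 0)`; non-negative by construction
#' and zero when every draw agrees in sign.
#'
#' @param draws a `psa_draws` from [run_psa()].
#' @param wtp willingness to pay per QALY.
#' @return EVPI in GBP per person.
#' @export
evpi <- function(draws, wtp) {
  stopifnot(inherits(draws, "psa_draws"), nrow(draws) > 0,
            length(wtp) == 1L, wtp >= 0)
  inc <- incremental(draws)
  b <- nmb(wtp, inc$dq, inc$dc)
  mean(pmax(b, 0)) - max(mean(b), 0)
}
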