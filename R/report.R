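#' Scenario grid: every QALY method by every horizon
#'
#' Runs one PSA per (method, horizon) combination and tabulates incremental
#' cost and QALYs, the ICER of the mean increments, and the probability of
#' cost-effectiveness at £20,000 and £30,000 per QALY.
#'
#' @param inputs a `trial_inputs` from [load_trial_inputs()].
#' @param base_config a [scenario_config()] supplying everything but the
#'   method and horizon.
#' @param methods,horizons the grid to run.
#' @return Data frame with one row per scenario, full precision (round for
#'   display).
#' @export
scenario_table <- function(inputs,
                           base_config = scenario_config(),
                           methods = c("endpoint", "auc", "baseline_adjusted"),
                           horizons = c(3, 6, 9, 12)) {
  grid <- expand.grid(qaly_method = methods, horizon_months = horizons,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$qaly_method <- grid$qaly_method[i]
    cfg$horizon_months <- as.integer(grid$horizon_months[i])
    draws <- run_psa(cfg, inputs)
    inc <- incremental(draws)
    ic <- icer(mean(inc$dc), mean(inc$dq))
    cc <- ceac(draws, c(20000, 30000))
    data.frame(qaly_method = cfg$qaly_method,
               horizon_months = cfg$horizon_months,
               incremental_cost = mean(inc$dc),
               incremental_qaly = mean(inc$dq),
               icer = ic$icer,
               icer_label = ic$label,
               prob_ce_20k = cc$probability[1],
               prob_ce_30k = cc$probability[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(match(out$qaly_method, methods), out$horizon_months), ]
}

#' Persist PSA draws with a provenance manifest
#'
#' Writes the draws as one-row-per-simulation CSV plus a JSON sidecar
#' echoing the scenario configuration, the package version and MD5
#' checksums of the input fixtures, so any reported number can be
#' re-derived from the persisted draws.
#'
#' @param draws a `psa_draws` from [run_psa()].
#' @param inputs the `trial_inputs` the draws were generated from.
#' @param dir output directory (created if needed).
#' @param stem file stem, default `"psa"`.
#' @return Invisibly, the paths written.
#' @export
write_psa_bundle <- function(draws, inputs, dir, stem = "psa") {
  stopifnot(inherits(draws, "psa_draws"), inherits(inputs, "trial_inputs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_draws.csv"))
  utils::write.csv(as.data.frame(draws), csv, row.names = FALSE)
  cfg <- attr(draws, "config")
  manifest <- list(
    config = list(qaly_method = cfg$qaly_method,
                  horizon_months = cfg$horizon_months,
                  n_sims = cfg$n_sims,
                  seed = cfg$seed,
                  wtp_grid = cfg$wtp_grid,
                  mff = c(cfg$mff$p1, cfg$mff$p2),
                  parameter_mode = cfg$parameter_mode,
                  baseline_utilities = as.list(cfg$baseline_utilities)),
    fixture_md5 = as.list(tools::md5sum(unname(inputs$fixture_files))),
    package_version = as.character(utils::packageVersion("hospicecua")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  json <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(draws = csv, manifest = json))
}
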