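#!/usr/bin/env Rscript
# Step 1: turn the trial's reported summary statistics into sampling
# distributions for the PSA, and record both parameterisation modes.
#
# Finding worth noting: the gamma (alpha, beta) pairs printed alongside the
# reported mean/s^2 columns are internally inconsistent with those columns
# (e.g. the control utility pair implies a mean of 0.589, not the reported
# 0.447), so every downstream analysis fits by method of moments from the
# mean/s^2 columns instead.

suppressPackageStartupMessages(library(hospicecua))

inputs <- load_trial_inputs()
dir.create("results", showWarnings = FALSE)

rows <- do.call(rbind, lapply(c("control", "intervention"), function(a) {
  arm <- inputs$arms[[a]]
  usage <- rbind(
    data.frame(category = "utility", mean = arm$utility_mean,
               variance = arm$utility_variance, in_total = NA),
    arm$usage)
  fits <- lapply(seq_len(nrow(usage)), function(i)
    fit_gamma_moments(usage$mean[i], usage$variance[i]))
  data.frame(arm = a, category = usage$category, mean = usage$mean,
             variance = usage$variance,
             shape = vapply(fits, `[[`, 1, "p1"),
             scale = vapply(fits, `[[`, 1, "p2"),
             in_cost_total = usage$in_total)
}))
write.csv(rows, "results/fitted_parameters.csv", row.names = FALSE)

ci_fits <- inputs$qaly_ci
ci_fits$implied_sd <- (ci_fits$ci_high - ci_fits$ci_low) / 3.92
write.csv(ci_fits, "results/qaly_interval_fits.csv", row.names = FALSE)

message("Fitted ", nrow(rows), " moment-matched gammas and ",
        nrow(ci_fits), " interval-implied QALY distributions.")
message("Control utility fit: shape ",
        round(rows$shape[rows$category == "utility" &
                           rows$arm == "control"], 2),
        " (the printed pair 29.45 does not reproduce the reported mean).")
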