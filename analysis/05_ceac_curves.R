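#!/usr/bin/env Rscript
# Step 5: cost-effectiveness acceptability curves for the AUC and
# baseline-adjusted scenarios across horizons. CSVs under results/,
# figures (if ggplot2 is available) under scratch/figures/.

suppressPackageStartupMessages(library(hospicecua))

inputs <- load_trial_inputs()
grid <- expand.grid(method = c("auc", "baseline_adjusted"),
                    horizon = c(3, 6, 9, 12), stringsAsFactors = FALSE)
curves <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  cfg <- scenario_config(grid$method[i], horizon_months = grid$horizon[i],
                         n_sims = 10000, seed = 20140558)
  cc <- ceac(run_psa(cfg, inputs))
  cbind(method = grid$method[i], horizon_months = grid$horizon[i], cc)
}))
dir.create("results", showWarnings = FALSE)
write.csv(curves, "results/ceac_curves.csv", row.names = FALSE)

at20 <- curves[curves$wtp == 20000, ]
message("Probability cost-effective at £20,000/QALY:")
for (i in seq_len(nrow(at20)))
  message(sprintf("  %-18s %2d months: %4.1f%%", at20$method[i],
                  at20$horizon_months[i], 100 * at20$probability[i]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
  curves$horizon <- factor(curves$horizon_months)
  p <- ggplot(curves, aes(wtp, probability, colour = horizon)) +
    geom_line() +
    facet_wrap(~method) +
    labs(x = "Willingness to pay (GBP per QALY)",
         y = "Probability cost-effective",
         colour = "Horizon (months)") +
    theme_minimal()
  ggsave("scratch/figures/ceac.png", p, width = 9, height = 4, dpi = 150)
}
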