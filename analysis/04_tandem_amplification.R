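#!/usr/bin/env Rscript
# Tandem-tag signal amplification: the shared-pool equilibrium model for
# 5x FP_11 arrays, and the microscopy quantification of a simulated
# 1x-vs-5x experiment (four replicate fields per condition).
#
# Finding: the model caps the 5x amplification strictly below 5-fold for
# any finite FP_1-10 pool; the image pipeline (rolling-ball background
# subtraction, bandpass segmentation, 80-2000 um^2 / 0.1-1.0 circularity
# particle filters, per-cell medians) recovers a simulated 2.3-fold
# median-signal increase and calls it significant with the one-sided
# Welch test. Writes results/tandem_model.csv, tandem_imaging.json and a
# replicate-averaged histogram figure.

library(splitFPquant)

dir.create("results", showWarnings = FALSE)

# model: amplification fold vs pool size and binding strength
grid <- expand.grid(a_total = 10^seq(-1, 3, by = 0.25),
                    kd = c(0.1, 1, 10))
grid$fold <- mapply(function(a, k) amplification_fold(5, a, 1, k),
                    grid$a_total, grid$kd)
write.csv(grid, "results/tandem_model.csv", row.names = FALSE)
stopifnot(all(grid$fold < 5))
cat(sprintf("max model fold on the grid: %.6f (always < 5 for finite pools)\n",
            max(grid$fold)))

# imaging experiment: 1x vs 5x at a true 2.3-fold median difference
cfg <- imaging_sim_config(seed = 404L)
fields <- simulate_imaging_experiment(cfg, c("1x" = 1, "5x" = 2.3))
report <- run_image_analysis(fields, pixel_size_um = cfg$pixel_size_um)
print(report)

amp <- report$amplification
jsonlite::write_json(
  list(fold_change = amp$fold_change, t = amp$t_statistic,
       df = amp$degrees_of_freedom, p_one_sided = amp$p_value,
       alternative = amp$alternative,
       field_medians = lapply(report$summaries, `[[`, "field_medians")),
  "results/tandem_imaging.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

p <- plot_condition_histograms(report$summaries)
ggplot2::ggsave("results/tandem_histograms.png", p, width = 6, height = 4,
                dpi = 150)
cat("wrote results/tandem_model.csv, tandem_imaging.json, tandem_histograms.png\n")
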