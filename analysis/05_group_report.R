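#!/usr/bin/env Rscript
# Hierarchical group report: pools the per-cell motility metrics across
# scenes the way nested designs are summarised (cell -> scene -> genotype),
# so scenes with many cells do not dominate, and contrasts the genotypes.

library(musctrack)
library(dplyr)

metrics <- read.csv("results/motility_metrics.csv")

report <- bind_rows(lapply(
  c(mobile = "avg_speed_um_h", straight = "straightness",
    turn = "mean_turn_deg"),
  function(col) {
    df <- metrics[metrics$mobility_class == "mobile" &
                    !is.na(metrics[[col]]), ]
    out <- summarize_groups(df, value = col, unit = "scene",
                            group = "genotype")
    out$metric <- col
    out
  }))
print(as.data.frame(report), digits = 3)

frac <- metrics |>
  mutate(mobile = mobility_class == "mobile") |>
  summarize_groups(value = "mobile", unit = "scene", group = "genotype")
frac$metric <- "mobile_fraction"
report <- bind_rows(report, frac)

write.csv(report, "results/group_report.csv", row.names = FALSE)
cat("\nwrote results/group_report.csv\n")
cat("mobile fraction by genotype (scene-level means):\n")
print(as.data.frame(frac), digits = 3)
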