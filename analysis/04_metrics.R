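#!/usr/bin/env Rscript
# Circadian summaries and dose arithmetic.
#
# Collapse the per-animal hourly stage minutes (from 01_simulate.R) into
# 12-h light/dark totals, and tabulate the drinking-water morphine dose:
# mice drinking ~5 mL/day of 0.5 mg/mL morphine at 25 g body weight ingest
# ~100 mg/kg/day.

suppressPackageStartupMessages(library(hypnoscore))

hourly <- read.csv("results/hourly_stage_minutes.csv")

ld <- do.call(rbind, lapply(split(hourly, hourly$animal_id), function(d) {
  out <- aggregate_light_dark(d)
  cbind(animal_id = d$animal_id[1], condition = d$condition[1], out)
}))
rownames(ld) <- NULL
write.csv(ld, "results/light_dark_minutes.csv", row.names = FALSE)

wake <- ld[ld$stage == "WAKE", ]
agg <- aggregate(minutes ~ condition + phase, wake, mean)
cat("Mean wake minutes per 12-h phase:\n")
print(agg, row.names = FALSE)

dose <- data.frame(
  scenario = c("study dose", "escalation start", "light drinker"),
  volume_ml_per_day = c(5, 4, 3),
  concentration_mg_per_ml = c(0.5, 0.3, 0.5),
  body_weight_g = c(25, 24, 25))
dose$mg_per_kg_per_day <- with(dose, dose_from_intake(
  volume_ml_per_day, concentration_mg_per_ml, body_weight_g))
write.csv(dose, "results/dose_table.csv", row.names = FALSE)
cat("\nDrinking-water dose table (mg/kg/day):\n")
print(dose, row.names = FALSE)
cat("Wrote results/light_dark_minutes.csv, results/dose_table.csv\n")
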