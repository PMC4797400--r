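#!/usr/bin/env Rscript
# Stage 7 -- therapy efficacy.
#
# Caliper volumes (V = w^2 l / 2), percent volume change per group,
# endpoint evaluation (strict 15 mm / 20 % weight-loss rules) and
# Kaplan-Meier survival with group medians over the 120 d follow-up.

library(mousedose)

meas <- read.csv("results/cohort_measurements.csv")
rec <- read.csv("results/cohort_survival.csv")

pv <- percent_volume_change(meas)
write.csv(pv$per_group, "results/volume_change_by_group.csv", row.names = FALSE)

km <- kaplan_meier(rec)
jsonlite::write_json(list(median_survival_days = as.list(km$median_days)),
                     "results/km_summary.json", auto_unbox = TRUE, digits = NA)
write.csv(km$curves, "results/km_curves.csv", row.names = FALSE)

cat("median survival (days) by group:\n")
print(km$median_days)
cat("groups without a defined median (too few endpoint events within 120 d):",
    paste(names(km$median_days)[is.na(km$median_days)], collapse = ", "), "\n")
d60 <- pv$per_group[pv$per_group$day == 60, ]
cat("mean tumour volume at day 60, % of baseline:\n")
print(d60[order(d60$mean_pct), c("group", "mean_pct", "n_alive")], row.names = FALSE)
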