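#!/usr/bin/env Rscript
# Stage 2: cold exposure of every eligible calf.
#
# Reads the study written by 01_simulate.R, applies the eligibility
# filters, and computes for each calf the proportion of hours its
# effective temperature fell below its age-related LCT in each housing
# phase, with the quartile categorisation used by the models.

library(calfclim)

study <- read_study("results/study")

b2g <- assemble_b2g(study)
g2e <- assemble_g2e(study)

exposure <- rbind(
  data.frame(phase = "B2G", b2g$data[, c("calf_id", "hours_below",
                                         "total_hours", "proportion",
                                         "category")]),
  data.frame(phase = "G2E", g2e$data[, c("calf_id", "proportion",
                                         "category")],
             hours_below = NA, total_hours = NA)[,
    c("phase", "calf_id", "hours_below", "total_hours", "proportion",
      "category")]
)
write.csv(exposure, "results/exposure.csv", row.names = FALSE)
write.csv(rbind(b2g$exclusions, g2e$exclusions),
          "results/exclusions.csv", row.names = FALSE)
write.csv(report_descriptives(b2g$data, g2e$data)$calves,
          "results/calf_descriptives.csv", row.names = FALSE)

cat("B2G eligible:", nrow(b2g$data), "| mean proportion below LCT:",
    round(mean(b2g$data$proportion), 2), "\n")
print(table(b2g$data$category))
cat("G2E eligible:", nrow(g2e$data), "| mean proportion below LCT:",
    round(mean(g2e$data$proportion), 2), "\n")
print(table(g2e$data$category))
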