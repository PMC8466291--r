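#!/usr/bin/env Rscript
# Stage 3: the screening -> backward-elimination -> post-hoc model chain.
#
# B2G: univariable linear screens at p < 0.20, a maximal multivariable
# model, backward elimination at p < 0.05, Tukey contrasts for retained
# factors. G2E: the same chain with linear mixed models carrying random
# intercepts for rearing group, igloo pen and milk-feeder system.

library(calfclim)

study <- read_study("results/study")

cat("== Birth to group pen (B2G) ==\n")
b2g <- run_b2g(study)
print(b2g$result)
write_run(b2g, "results", "b2g")

cat("\n== Group pen to end of study (G2E) ==\n")
g2e <- run_g2e(study)
print(g2e$result)
write_run(g2e, "results", "g2e")

cat("\nB2G screening p-values:\n")
print(b2g$screening, digits = 3)
cat("\nG2E screening p-values:\n")
print(g2e$screening, digits = 3)
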