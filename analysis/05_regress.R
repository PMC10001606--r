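#!/usr/bin/env Rscript
# Stage 5: size of the intervention effect. OLS of mortality on the
# GRA-selected factors over the 40 stacked (year, sex) rows, in three
# specifications: (1) smoking + physician density, (2) adding the
# female-after-ban dummy, (3) dropping smoking. Case-resampling bootstrap
# SEs (1000 reps) and a Ramsey RESET diagnostic accompany each fit.

library(greyrel)

seed <- 1L
panel <- read.csv("results/synthetic_panel.csv")

bundle <- run_pipeline(panel, pipeline_config(bootstrap_reps = 1000,
                                              seed = seed))
for (nm in names(bundle$regressions)) {
  cat("\n== specification:", nm, "==\n")
  print(bundle$regressions[[nm]])
}
write_bundle(bundle, "results/bundle")

full <- bundle$regressions$full
cat("\nThe full specification estimates an extra post-ban change of ",
    round(full$coefficients["after_ban"], 2),
    " deaths per 100k women per year (truth: -5), R-squared ",
    round(full$r_squared, 3),
    ".\nAll pipeline tables (CSV + text report + run log) -> results/bundle/\n",
    sep = "")
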