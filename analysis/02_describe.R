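#!/usr/bin/env Rscript
# Stage 2: descriptive statistics (mean, SE, t-based 95% CI) per variable
# and group, mirroring the layout of a study's first descriptive table.

library(greyrel)

panel <- read.csv("results/synthetic_panel.csv")
vars <- intersect(c("mortality", "income", "physician", "smoking",
                    "alcohol", "overweight"), names(panel))

desc <- do.call(rbind, lapply(unique(panel$group), function(g) {
  d <- describe_panel(panel[panel$group == g, vars])
  cbind(group = g, d)
}))
num <- vapply(desc, is.numeric, logical(1))
desc[num] <- lapply(desc[num], round, 2)
write.csv(desc, "results/describe.csv", row.names = FALSE)

cat("Descriptive statistics -> results/describe.csv\n")
print(desc, row.names = FALSE)
cat("\nNote the stratified structure the generator emulates: male smoking",
    "an order of magnitude above female, physician density ~2.4 per 1k.\n")
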