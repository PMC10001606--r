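#!/usr/bin/env Rscript
# Stage 3: degree-of-grey-incidence tables. For each group, rank the three
# baseline factors (income, physician density, smoking rate) against
# mortality under all five models, contemporaneously (lag 0) and with
# factors lagged one year (outcome at t vs factor at t-1).

library(greyrel)

panel <- read.csv("results/synthetic_panel.csv")
factors <- c("income", "physician", "smoking")

for (g in unique(panel$group)) {
  seqs <- panel_sequences(panel, g, "mortality", factors)
  for (lag in c(0L, 1L)) {
    tab <- gra_table(seqs$reference, seqs$comparisons, lag = lag)
    out <- data.frame(factor = tab$factor,
                      round(tab[c("deng", "sdgra", "ssgra", "absolute",
                                  "relative")], 3),
                      deng_rank = tab$deng_rank_label,
                      sdgra_rank = tab$sdgra_rank_label,
                      ssgra_rank = tab$ssgra_rank_label)
    write.csv(out, sprintf("results/rank_%s_lag%d.csv", g, lag),
              row.names = FALSE)
    cat("\n== ", g, ", lag ", lag, " ==\n", sep = "")
    print(tab)
  }
}

cat("\nIn this synthetic world mortality is driven by physician density",
    "(plus the female post-ban shift), so physician density should top",
    "Deng's ranking in most draws; the lag-1 tables probe the same",
    "ordering under a one-year delayed response.\n")
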