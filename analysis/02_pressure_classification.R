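#!/usr/bin/env Rscript
# Score total human pressure, classify sites against reference
# conditions (all ten criteria <= 2, at most one 3) and bin the
# pressure gradient into the five quality classes.

library(fishinvade)

sites <- read_site_table("results/sites.csv")
cl <- classify_sites(sites)
write.csv(cl, "results/classification.csv", row.names = FALSE)

cat(sprintf("%d sites: %d reference, %d disturbed\n",
            nrow(cl), sum(cl$reference), sum(!cl$reference)))
cat("quality class distribution:\n")
print(table(cl$quality_class))
cat(sprintf("total pressure range: %d..%d\n",
            min(cl$total_pressure), max(cl$total_pressure)))
cat("wrote results/classification.csv\n")
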