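#!/usr/bin/env Rscript
# Decompose every network into connected components and compute the raw
# topological metric battery per component.

suppressPackageStartupMessages(library(mitotopo))

cohort <- read_cohort("results/cohort")
tb <- metrics_table(cohort)
write.table(tb, "results/component_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

labs <- cohort_labels(cohort)
tb$group <- labs[tb$subject_id]
cat(sprintf("Computed metrics for %d components (sizes %d..%d)\n",
            nrow(tb), min(tb$size), max(tb$size)))
for (g in unique(tb$group)) {
  sub <- tb[tb$group == g & tb$size >= 2, ]
  cat(sprintf("  %-8s mean size %.2f, mean efficiency %.3f, mean ASPL %.3f, mean transitivity %.3f\n",
              g, mean(sub$size), mean(sub$efficiency, na.rm = TRUE),
              mean(sub$aspl, na.rm = TRUE),
              mean(sub$transitivity, na.rm = TRUE)))
}
cat("Written: results/component_metrics.tsv\n")
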