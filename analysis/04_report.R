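#!/usr/bin/env Rscript
# Render the aggregate accuracy matrix (mean +- SD percent per band, the
# shape of the study's main table), per-subject maxima, and a figure of
# accuracy by band.

library(eegscape)

rep_ <- render_report("results/grid")
print(rep_$table)

write.table(rep_$table, "results/accuracy_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
cat("per-subject best cells (by classifier):\n")
print(head(rep_$best_by_classifier, 8))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  g <- plot_grid_accuracy(read_grid("results/grid"), family = "DE")
  ggplot2::ggsave("results/accuracy_by_band.pdf", g, width = 6, height = 4)
  cat("figure written to results/accuracy_by_band.pdf\n")
}
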