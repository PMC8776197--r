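#!/usr/bin/env Rscript
# Per-subject 7-class decoding over the full (family x band x classifier)
# grid: BP network, KNN (k=5), random forest (500 trees) and linear SVM
# under stratified 10-fold cross-validation, aggregated across subjects.

library(eegscape)

IN <- "results/features"
OUT <- "results"

cfg <- load_config()
grid <- run_classification(IN, cfg, out_dir = OUT)

s <- summarize_grid(grid)
cat(paste(s$text, collapse = "\n"), "\n")
cat("expected pattern: gamma and beta bands dominate; frequency-domain\n")
cat("families (MAS/PSD/DE) outperform the asymmetry/caudality families.\n")
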