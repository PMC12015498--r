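#!/usr/bin/env Rscript
# Stage 4: feature-fusion ablation. For each task (species, origin), each
# of the seven fusion sets (S, C, T, S+T, S+C, C+T, S+C+T) and each of the
# four classifiers (BP, RF, SVM, ELM), train on a stratified 7:3 split and
# record training and test accuracy.

library(tuberscope)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

features <- read.csv("results/features.csv")
res <- run_study(features = features, seed = seed)

write.csv(format_ablation(res$ablation), "results/ablation.csv",
          row.names = FALSE)
writeLines(ablation_markdown(res$ablation), "results/ablation.md")

cat("Feature-fusion ablation (test accuracy %, by task):\n")
for (task in unique(res$ablation$task)) {
  sub <- res$ablation[res$ablation$task == task, ]
  best <- sub[which.max(sub$test_accuracy), ]
  cat(sprintf("  %s: best %s with %s (%d features): %.2f%%\n", task,
              best$model, best$fusion, best$n_features,
              100 * best$test_accuracy))
}
cat("Full table -> results/ablation.csv, results/ablation.md\n")
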