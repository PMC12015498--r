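#!/usr/bin/env Rscript
# Stage 5: evaluation of the shape+texture models — 10-fold
# cross-validation, per-class precision/recall/F1 from test-set confusion
# matrices, and a one-way ANOVA over the four models' cross-validated
# accuracies with 95% confidence intervals.

library(tuberscope)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

features <- read.csv("results/features.csv")
models <- c("BP", "RF", "SVM", "ELM")

cat("10-fold CV, shape+texture fusion, origin task:\n")
cv <- lapply(setNames(models, models), function(kind)
  kfold_cv(features, kind = kind, task = "origin", groups = c("S", "T"),
           k = 10, seed = seed))
for (kind in models)
  cat(sprintf("  %-3s mean %.4f (sd %.4f)\n", kind, cv[[kind]]$mean,
              cv[[kind]]$sd))

aov_res <- anova_models(lapply(cv, `[[`, "fold_accuracy"))
cat(sprintf("ANOVA across models: F = %.3f, p = %.3f\n", aov_res$F, aov_res$p))
print(aov_res$ci, digits = 4)

# test-set confusion matrices for the random forest on both tasks
for (task in c("species", "origin")) {
  sp <- stratified_split(features, task = task, seed = seed)
  m <- train_model(sp$train, "RF", task = task, groups = c("S", "T"),
                   seed = seed)
  rep <- evaluate_model(m, sp$test)
  cat(sprintf("\nRF S+T, %s task: test accuracy %.2f%%\n", task,
              100 * rep$accuracy))
  print(rep$confusion)
  print(rep$per_class, digits = 3)
}
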