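# Evaluation: confusion matrices, one-vs-rest accuracy/precision/recall/F1
# with macro averaging, stratified 10-fold cross-validation, and one-way
# ANOVA across models with 95% confidence intervals per model.

#' Confusion matrix with fixed class order
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param truth,pred label vectors of equal length.
#' @param levels class order; defaults to the sorted union of labels.
#' @return k x k integer matrix.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  stopifnot(length(truth) == length(pred))
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(pred), levels = levels)
  if (anyNA(t_f) || anyNA(p_f))
    stop("labels outside the supplied class order", call. = FALSE)
  unclass(table(truth = t_f, predicted = p_f))
}

#' Classification metrics from a confusion matrix
#'
#' Per class c (one-vs-rest): TP = cm[c,c], FP = column sum - TP,
#' FN = row sum - TP, TN = the rest; precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2PR/(P+R), with 0 substituted whenever a
#' denominator is 0. Global accuracy is trace/total; macro values are
#' unweighted class means.
#'
#' @param cm confusion matrix (true x predicted).
#' @return list with `accuracy`, `per_class` (data.frame of precision,
#'   recall, f1) and `macro` (named numeric).
#' @export
classification_metrics <- function(cm) {
  n <- sum(cm)
  stopifnot(n > 0)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  list(accuracy = sum(tp) / n,
       per_class = data.frame(class = rownames(cm), precision = precision,
                              recall = recall, f1 = f1, row.names = NULL),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

#' Full evaluation report for a model on a test table
#'
#' @param model a `tuber_model`.
#' @param test labelled feature data.frame.
#' @return list with `confusion` and the output of
#'   [classification_metrics()].
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  cm <- confusion_matrix(test[[model$task]], pred, levels = model$levels)
  c(list(confusion = cm), classification_metrics(cm))
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of one model/fusion/task
#'
#' @param table labelled feature data.frame.
#' @param kind model kind, see [train_model()].
#' @param task label column.
#' @param groups fusion groups.
#' @param k number of folds (every class must have at least k members).
#' @param seed integer seed (fold assignment and model fits).
#' @param hyper hyperparameter overrides passed to [train_model()].
#' @return list with `k`, `fold_accuracy`, `mean`, `sd`, `folds`.
#' @export
kfold_cv <- function(table, kind = "RF", task = "origin",
                     groups = c("S", "C", "T"), k = 10L, seed = 1L,
                     hyper = list()) {
  y <- as.character(table[[task]])
  if (any(table(y) < k))
    stop("every class needs at least k members for stratified k-fold",
         call. = FALSE)
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    m <- train_model(train, kind = kind, task = task, groups = groups,
                     seed = seed + f, hyper = hyper)
    model_accuracy(m, test)
  }, numeric(1))
  list(k = k, fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       folds = fold)
}

#' One-way ANOVA over per-model accuracy samples
#'
#' Fixed-effects one-way ANOVA of accuracy against model identity, plus a
#' per-model 95% confidence interval mean +/- t(0.975, n-1) * se. With zero
#' within-group variance the F statistic is undefined and `p` is NaN with
#' `degenerate = TRUE`.
#'
#' @param accuracy_lists named list of numeric vectors, one per model, each
#'   of length >= 2.
#' @return list with `F`, `p`, `df`, `degenerate` and a data.frame `ci`
#'   (model, mean, lower, upper).
#' @export
anova_models <- function(accuracy_lists) {
  stopifnot(length(accuracy_lists) >= 2,
            all(vapply(accuracy_lists, length, 0L) >= 2))
  values <- unlist(accuracy_lists, use.names = FALSE)
  group <- factor(rep(names(accuracy_lists),
                      vapply(accuracy_lists, length, 0L)))
  n <- length(values); g <- nlevels(group)
  grand <- mean(values)
  means <- tapply(values, group, mean)
  ss_between <- sum(tapply(values, group, length) * (means - grand)^2)
  ss_within <- sum((values - means[group])^2)
  df1 <- g - 1L; df2 <- n - g
  if (ss_within <= 0) {
    f_stat <- NaN; p <- NaN; degenerate <- TRUE
  } else {
    f_stat <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
    degenerate <- FALSE
  }
  ci <- do.call(rbind, lapply(names(accuracy_lists), function(nm) {
    x <- accuracy_lists[[nm]]
    se <- stats::sd(x) / sqrt(length(x))
    tq <- stats::qt(0.975, length(x) - 1)
    data.frame(model = nm, mean = mean(x),
               lower = mean(x) - tq * se, upper = mean(x) + tq * se)
  }))
  list(F = f_stat, p = p, df = c(df1, df2), degenerate = degenerate, ci = ci)
}
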