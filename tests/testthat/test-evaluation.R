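test_that("confusion matrices count true/predicted pairs in fixed order", {
  cm <- confusion_matrix(c("a", "a", "a", "b", "b"),
                         c("a", "a", "b", "b", "b"), levels = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(2L, 0L, 1L, 2L), 2, 2,
               dimnames = list(truth = c("a", "b"), predicted = c("a", "b"))))
  expect_equal(sum(cm), 5L)

  perfect <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion_matrix("a", "z", levels = c("a", "b")), "class order")
})

test_that("metrics implement one-vs-rest precision/recall/F1 and accuracy", {
  cm <- matrix(c(2L, 0L, 1L, 2L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$per_class$precision[1], 1.0)
  expect_equal(m$per_class$recall[1], 2 / 3)
  expect_equal(m$per_class$f1[1], 0.8)

  diag3 <- diag(3L); dimnames(diag3) <- list(letters[1:3], letters[1:3])
  md <- classification_metrics(diag3)
  expect_equal(md$accuracy, 1)
  expect_true(all(md$per_class$f1 == 1))

  # class never predicted: precision 0 by convention, no division error
  cm0 <- matrix(c(3L, 2L, 0L, 0L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m0 <- classification_metrics(cm0)
  expect_equal(m0$per_class$precision[2], 0)
  expect_equal(m0$per_class$f1[2], 0)
})

test_that("metrics agree with a brute-force per-element counter", {
  set.seed(14)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(10:60, 1)
    levels <- letters[1:k]
    truth <- sample(levels, n, TRUE)
    pred <- sample(levels, n, TRUE)
    cm <- confusion_matrix(truth, pred, levels)
    m <- classification_metrics(cm)
    expect_equal(m$accuracy, sum(truth == pred) / n)
    for (ci in seq_along(levels)) {
      cl <- levels[ci]
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      p_ref <- if (tp + fp > 0) tp / (tp + fp) else 0
      r_ref <- if (tp + fn > 0) tp / (tp + fn) else 0
      expect_equal(m$per_class$precision[ci], p_ref)
      expect_equal(m$per_class$recall[ci], r_ref)
      expect_equal(m$per_class$f1[ci],
                   if (p_ref + r_ref > 0) 2 * p_ref * r_ref / (p_ref + r_ref) else 0)
    }
    # micro-averaged precision = micro recall = accuracy
    tp_all <- sum(diag(cm))
    expect_equal(tp_all / sum(cm), m$accuracy)
    if (k == 2) {
      # macro recall equals balanced accuracy for two classes
      sens <- m$per_class$recall
      expect_equal(unname(m$macro["recall"]), mean(sens))
    }
  }
})

test_that("cross-validation folds are stratified, seeded and exhaustive", {
  ft <- small_feature_table()               # 12 samples, 3 per origin
  cv1 <- kfold_cv(ft, kind = "RF", task = "origin", groups = c("S", "T"),
                  k = 3, seed = 6)
  cv2 <- kfold_cv(ft, kind = "RF", task = "origin", groups = c("S", "T"),
                  k = 3, seed = 6)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(sort(unique(cv1$folds)), 1:3)
  for (f in 1:3) expect_equal(as.vector(table(ft$origin[cv1$folds == f])), rep(1L, 4))
  expect_length(cv1$fold_accuracy, 3L)
  expect_equal(cv1$mean, mean(cv1$fold_accuracy))
  expect_error(kfold_cv(ft, k = 10), "at least k")

  # separable clouds: RF cross-validates perfectly
  toy <- toy_clouds(n = 40, seed = 3)
  cv <- kfold_cv(toy, kind = "RF", task = "species", groups = "S", k = 10,
                 seed = 2)
  expect_equal(cv$mean, 1.0)
})

test_that("one-way ANOVA matches aov and handles degenerate groups", {
  groups <- list(a = c(0.9, 0.92, 0.88, 0.91), b = c(0.85, 0.87, 0.86, 0.9),
                 c = c(0.8, 0.84, 0.82, 0.81))
  res <- anova_models(groups)
  df <- data.frame(y = unlist(groups), g = rep(names(groups), each = 4))
  ref <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(res$F, ref[["F value"]][1])
  expect_equal(res$p, ref[["Pr(>F)"]][1])
  expect_true(all(res$ci$lower <= res$ci$mean & res$ci$mean <= res$ci$upper))

  # zero within-group variance with distinct means: p below any threshold
  sep <- anova_models(list(hi = c(0.9, 0.9, 0.9) + c(0, 1e-9, -1e-9),
                           lo = c(0.5, 0.5, 0.5)))
  expect_lt(sep$p, 0.001)

  # identical constants: degenerate, flagged, p = NaN
  deg <- anova_models(list(a = c(0.7, 0.7), b = c(0.7, 0.7)))
  expect_true(deg$degenerate)
  expect_true(is.nan(deg$p))
})
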