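# Fusion feature sets, stratified splitting, per-feature standardization,
# and the four classifiers: random forest and RBF-SVM via their standard
# implementations, a single-hidden-layer backpropagation network via nnet,
# and an extreme learning machine implemented here (random fixed input
# weights, least-squares output weights via pseudoinverse -- no iteration).

.fusion_groups <- list(S = c("C", "R", "L"),
                       C = c("mean_h", "mean_s"),
                       T = as.vector(outer(
                         c("ASM", "CON", "COR", "ENT"), c("d1", "d2", "d4"),
                         function(a, b) paste(a, b, sep = "_"))))

#' The seven fusion specifications of the ablation
#'
#' Shape (S, 3 features), colour (C, 2) and texture (T, 12) groups and all
#' their combinations, labelled S, C, T, S+T, S+C, C+T, S+C+T.
#'
#' @return named list of character vectors of group codes.
#' @export
fusion_specs <- function() {
  list("S" = "S", "C" = "C", "T" = "T",
       "S+T" = c("S", "T"), "S+C" = c("S", "C"), "C+T" = c("C", "T"),
       "S+C+T" = c("S", "C", "T"))
}

#' Feature columns of a fusion specification
#'
#' @param groups nonempty subset of c("S", "C", "T").
#' @return character vector of feature column names in canonical order.
#' @export
fusion_columns <- function(groups) {
  stopifnot(length(groups) >= 1, all(groups %in% names(.fusion_groups)))
  unlist(.fusion_groups[intersect(names(.fusion_groups), groups)],
         use.names = FALSE)
}

#' Restrict a feature table to one fusion's columns
#'
#' @param table feature data.frame (as from [feature_table()]).
#' @param groups nonempty subset of c("S", "C", "T").
#' @return the table with label columns plus the selected feature columns.
#' @export
select_fusion <- function(table, groups) {
  cols <- fusion_columns(groups)
  label_cols <- intersect(c("sample_id", "origin", "species"), names(table))
  table[, c(label_cols, cols), drop = FALSE]
}

#' Stratified train/test split
#'
#' Per-class partition at `train_fraction`, using largest-remainder
#' rounding of the per-class train counts; disjoint and exhaustive.
#'
#' @param table feature data.frame.
#' @param task "species" or "origin" (the label column to stratify on).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed for the within-class shuffles.
#' @return list with data.frames `train` and `test`.
#' @export
stratified_split <- function(table, task = "origin", train_fraction = 0.7,
                             seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- table[[task]]
  counts <- table(y)
  if (any(counts < 2))
    stop("every class needs at least 2 samples to stratify", call. = FALSE)
  set.seed(seed)
  # largest-remainder apportionment of round(train_fraction * n) overall
  exact <- counts * train_fraction
  base <- floor(exact)
  total <- round(sum(exact))
  rem <- exact - base
  extra <- order(rem, decreasing = TRUE)[seq_len(total - sum(base))]
  n_train <- base
  n_train[extra] <- n_train[extra] + 1L
  train_idx <- unlist(lapply(names(counts), function(cl) {
    idx <- which(y == cl)
    sample(idx, n_train[[cl]])
  }), use.names = FALSE)
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Fit a per-feature z-score scaler on training data
#'
#' @param x numeric matrix or data.frame of features.
#' @return list with `mean` and `sd` vectors; zero-sd features are marked
#'   to pass through unscaled.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  list(mean = mu, sd = sd)
}

#' Apply a fitted scaler
#'
#' @param x numeric matrix or data.frame.
#' @param scaler output of [fit_scaler()].
#' @return scaled matrix; constant (sd = 0) columns are left unchanged.
#' @export
apply_scaler <- function(x, scaler) {
  x <- as.matrix(x)
  sd <- ifelse(scaler$sd > 0, scaler$sd, 1)
  mu <- ifelse(scaler$sd > 0, scaler$mean, 0)
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit an extreme learning machine
#'
#' Single hidden layer with input weights and biases drawn i.i.d.
#' uniform(-1, 1) from the seed and never updated; output weights solve the
#' least-squares problem H beta = one-hot(y) through the Moore-Penrose
#' pseudoinverse. Training requires no iteration.
#'
#' @param X numeric matrix, n x p.
#' @param y factor or character labels, length n.
#' @param n_hidden number of hidden nodes.
#' @param activation "sigmoid" (default) or "tanh".
#' @param seed integer seed for the random projection.
#' @return an `elm` model object.
#' @export
elm_fit <- function(X, y, n_hidden = 100L, activation = "sigmoid", seed = 1L) {
  stopifnot(n_hidden >= 1)
  X <- as.matrix(X)
  y <- factor(y)
  set.seed(seed)
  p <- ncol(X)
  W <- matrix(stats::runif(p * n_hidden, -1, 1), p, n_hidden)
  b <- stats::runif(n_hidden, -1, 1)
  act <- switch(activation, sigmoid = sigmoid, tanh = tanh,
                stop("unknown activation", call. = FALSE))
  H <- act(sweep(X %*% W, 2, b, "+"))
  target <- stats::model.matrix(~ y - 1)           # one-hot, n x k
  beta <- MASS::ginv(H) %*% target
  structure(list(W = W, b = b, beta = beta, activation = act,
                 levels = levels(y)),
            class = "elm")
}

#' Predict method for extreme learning machines
#'
#' @param object an `elm` model.
#' @param newdata numeric matrix of features.
#' @param ... unused.
#' @return factor of predicted labels (argmax of the output layer).
#' @export
predict.elm <- function(object, newdata, ...) {
  H <- object$activation(sweep(as.matrix(newdata) %*% object$W, 2,
                               object$b, "+"))
  scores <- H %*% object$beta
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Train one classifier on a feature table
#'
#' `kind` selects the model: "RF" (random forest, 500 trees), "SVM" (RBF
#' kernel, C = 1, gamma = 1/p), "BP" (single hidden layer of 32 units,
#' up to 500 epochs) or "ELM" (100 sigmoid hidden nodes). Features are
#' z-scored with training statistics for the scale-sensitive SVM, BP and
#' ELM; the random forest sees raw features.
#'
#' @param train feature data.frame including the label column.
#' @param kind one of "RF", "SVM", "BP", "ELM".
#' @param task label column, "species" or "origin".
#' @param groups fusion groups, subset of c("S","C","T").
#' @param seed integer seed.
#' @param hyper optional named list overriding default hyperparameters.
#' @return a `tuber_model` object.
#' @export
train_model <- function(train, kind = c("RF", "SVM", "BP", "ELM"),
                        task = "origin", groups = c("S", "C", "T"),
                        seed = 1L, hyper = list()) {
  kind <- match.arg(kind)
  cols <- fusion_columns(groups)
  y <- factor(train[[task]])
  if (nlevels(y) < 2) stop("training labels are degenerate", call. = FALSE)
  X <- as.matrix(train[, cols, drop = FALSE])
  scaler <- NULL
  if (kind %in% c("SVM", "BP", "ELM")) {
    scaler <- fit_scaler(X)
    X <- apply_scaler(X, scaler)
  }
  hp <- utils::modifyList(switch(kind,
    RF = list(n_trees = 500L),
    SVM = list(cost = 1, gamma = 1 / ncol(X)),
    BP = list(size = 32L, maxit = 500L, decay = 1e-4),
    ELM = list(n_hidden = 100L, activation = "sigmoid")), hyper)
  set.seed(seed)
  fit <- switch(kind,
    RF = randomForest::randomForest(x = X, y = y, ntree = hp$n_trees),
    SVM = e1071::svm(x = X, y = y, kernel = "radial", cost = hp$cost,
                     gamma = hp$gamma, scale = FALSE),
    BP = nnet::nnet(x = X, y = stats::model.matrix(~ y - 1), size = hp$size,
                    maxit = hp$maxit, decay = hp$decay, softmax = TRUE,
                    MaxNWts = 10000L, trace = FALSE),
    ELM = elm_fit(X, y, n_hidden = hp$n_hidden, activation = hp$activation,
                  seed = seed))
  structure(list(kind = kind, task = task, groups = groups,
                 feature_names = cols, scaler = scaler, fit = fit,
                 levels = levels(y)),
            class = "tuber_model")
}

#' Predict labels with a trained model
#'
#' Columns are bound by name, so column order in `newdata` is irrelevant.
#'
#' @param object a `tuber_model`.
#' @param newdata feature data.frame containing the model's feature columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.tuber_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) stop("no rows to predict", call. = FALSE)
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (!is.null(object$scaler)) X <- apply_scaler(X, object$scaler)
  pred <- switch(object$kind,
    RF = predict(object$fit, X),
    SVM = predict(object$fit, X),
    BP = {
      scores <- predict(object$fit, X)
      factor(colnames(scores)[max.col(scores, ties.method = "first")])
    },
    ELM = predict(object$fit, X))
  if (object$kind == "BP") {
    # nnet one-hot columns are named "y<level>"
    lv <- sub("^y", "", as.character(pred))
    pred <- factor(lv, levels = object$levels)
  }
  factor(as.character(pred), levels = object$levels)
}

#' Accuracy of a model on a labelled table
#'
#' @param model a `tuber_model`.
#' @param table labelled feature data.frame.
#' @return fraction of correct predictions.
#' @export
model_accuracy <- function(model, table) {
  mean(as.character(predict(model, table)) == as.character(table[[model$task]]))
}
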