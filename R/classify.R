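#' Configuration of the three base classifiers
#'
#' Bundles the settings of the ensemble's base learners: an RBF-kernel
#' support vector machine whose cost `C` and kernel width `gamma` are tuned
#' by an inner cross-validated grid search on the training folds only; a
#' multilayer perceptron with two hidden layers of three neurons trained by
#' online backpropagation at learning rate 0.3; and a pruned univariate
#' decision tree with entropy splits whose pruning strength derives from a
#' C4.5-style confidence factor (default 0.25).
#'
#' @param C_grid,gamma_grid Positive grids searched for the SVM.
#' @param inner_cv_folds Folds of the inner tuning loop (default 3).
#' @param mlp_hidden Hidden layer sizes (default `c(3, 3)`).
#' @param mlp_learning_rate,mlp_momentum,mlp_max_epochs Backpropagation
#'   settings (defaults 0.3, 0.2, 500).
#' @param tree_confidence Confidence factor controlling tree pruning; lower
#'   values prune harder. Mapped to an rpart complexity penalty
#'   `cp = 0.01 * 0.25 / tree_confidence`.
#' @param standardize Standardize features with training-fold statistics
#'   before fitting (default `TRUE`; RBF kernels on raw pixel-count scales
#'   are degenerate).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(C_grid = c(0.1, 1, 10, 100),
                              gamma_grid = c(0.001, 0.01, 0.1, 1),
                              inner_cv_folds = 3L,
                              mlp_hidden = c(3L, 3L),
                              mlp_learning_rate = 0.3,
                              mlp_momentum = 0.2,
                              mlp_max_epochs = 500L,
                              tree_confidence = 0.25,
                              standardize = TRUE) {
  if (length(C_grid) == 0L || length(gamma_grid) == 0L ||
      any(C_grid <= 0) || any(gamma_grid <= 0)) {
    stop("classifier_config: SVM grids must be non-empty and positive")
  }
  if (mlp_learning_rate <= 0) {
    stop("classifier_config: learning rate must be positive")
  }
  if (tree_confidence <= 0) {
    stop("classifier_config: tree_confidence must be positive")
  }
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_learning_rate = mlp_learning_rate,
                 mlp_momentum = mlp_momentum,
                 mlp_max_epochs = as.integer(mlp_max_epochs),
                 tree_confidence = tree_confidence,
                 standardize = isTRUE(standardize)),
            class = "classifier_config")
}

#' Feature subset selectors
#'
#' The eight feature configurations evaluated by the pipeline: each single
#' feature, the three tissue volumes together, both hippocampal areas
#' together, and all five features.
#'
#' @return Named list mapping subset names to feature column vectors.
#' @export
feature_subsets <- function() {
  list(gm = "vol_gm", wm = "vol_wm", csf = "vol_csf",
       `gm+wm+csf` = c("vol_gm", "vol_wm", "vol_csf"),
       left = "left_area", right = "right_area",
       `left+right` = c("left_area", "right_area"),
       all = c("vol_gm", "vol_wm", "vol_csf", "left_area", "right_area"))
}

resolve_features <- function(table, subset) {
  subs <- feature_subsets()
  cols <- if (is.character(subset) && length(subset) == 1L &&
              subset %in% names(subs)) subs[[subset]] else as.character(subset)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("feature columns not found in table: ",
         paste(missing_cols, collapse = ", "))
  }
  cols
}

#' Majority vote over class votes
#'
#' Returns +1 (disease) exactly when the number of +1 votes strictly exceeds
#' half the number of voters, and -1 (control) otherwise. With an even
#' number of voters a tie therefore resolves to -1.
#'
#' @param votes Non-empty vector with elements in `{+1, -1}`.
#' @return `+1L` or `-1L`.
#' @export
majority_vote <- function(votes) {
  if (length(votes) == 0L) stop("majority_vote: empty vote vector")
  if (!all(votes %in% c(-1L, 1L))) {
    stop("majority_vote: votes must be +1 or -1")
  }
  if (sum(votes == 1L) > length(votes) / 2) 1L else -1L
}

derive_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) * 48271 + i * 7919) %% 2147483546) + 1)
}

standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

svm_grid_search <- function(X, y, config, seed) {
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  counts <- table(y)
  k <- min(config$inner_cv_folds, min(counts))
  if (k < 2L) {
    # too few cases to tune; fall back to the grid midpoint
    mid <- ceiling(nrow(grid) / 2)
    return(list(C = grid$C[mid], gamma = grid$gamma[mid]))
  }
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE],
                        factor(y[tr], levels = c(-1L, 1L)),
                        kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      hits <- hits + sum(as.integer(as.character(pred)) == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  best <- which.max(acc) # first maximum: deterministic
  list(C = grid$C[best], gamma = grid$gamma[best])
}

#' Train the three base classifiers
#'
#' Fits the RBF SVM (with inner cross-validated grid search for `C` and
#' `gamma` on the training data only), the 2x3 multilayer perceptron and the
#' pruned entropy decision tree on a labelled feature table. When
#' `config$standardize` is set the features are z-scored with statistics
#' computed from this training set, and the same statistics are reapplied at
#' prediction time (no leakage).
#'
#' @param train Data frame with the feature columns and a `label` column in
#'   `{+1, -1}` containing both classes.
#' @param config A [classifier_config()].
#' @param seed Integer seed (MLP initialization, inner fold assignment).
#' @param subset Feature subset name from [feature_subsets()] or a character
#'   vector of feature columns (default `"all"`).
#' @return An object of class `classifier_triple`.
#' @export
train_base_classifiers <- function(train, config = classifier_config(),
                                   seed = 1L, subset = "all") {
  cols <- resolve_features(train, subset)
  y <- as.integer(train$label)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  if (length(unique(y)) < 2L) {
    stop("train_base_classifiers: training set contains a single class")
  }
  X <- as.matrix(train[cols])
  std <- if (config$standardize) standardizer(X) else
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- apply_standardizer(X, std)

  tuned <- svm_grid_search(Xs, y, config, derive_seed(seed, 1L))
  svm_fit <- e1071::svm(Xs, factor(y, levels = c(-1L, 1L)),
                        kernel = "radial", cost = tuned$C,
                        gamma = tuned$gamma, scale = FALSE)

  mlp_model <- mlp_fit(Xs, (y + 1L) / 2L, hidden = config$mlp_hidden,
                       learning_rate = config$mlp_learning_rate,
                       momentum = config$mlp_momentum,
                       max_epochs = config$mlp_max_epochs,
                       seed = derive_seed(seed, 2L))

  cp <- 0.01 * 0.25 / config$tree_confidence
  tree_data <- data.frame(Xs, label = factor(y, levels = c(-1L, 1L)))
  tree_fit <- rpart::rpart(label ~ ., data = tree_data, method = "class",
                           parms = list(split = "information"),
                           control = rpart::rpart.control(
                             cp = cp, minsplit = 4L, minbucket = 2L,
                             xval = 0L, maxsurrogate = 0L, usesurrogate = 0L))

  structure(list(svm = svm_fit, mlp = mlp_model, tree = tree_fit,
                 std = std, features = cols, svm_params = tuned,
                 config = config, seed = seed),
            class = "classifier_triple")
}

#' Per-classifier predictions
#'
#' @param models A [train_base_classifiers()] fit.
#' @param rows Data frame holding the same feature columns the models were
#'   trained on.
#' @return Integer matrix with one row per input row and columns `svm`,
#'   `mlp`, `tree`, entries in `{+1, -1}`.
#' @export
predict_base <- function(models, rows) {
  stopifnot(inherits(models, "classifier_triple"))
  missing_cols <- setdiff(models$features, names(rows))
  if (length(missing_cols)) {
    stop("predict_base: rows lack feature columns: ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(rows[models$features])
  Xs <- apply_standardizer(X, models$std)
  svm_pred <- as.integer(as.character(predict(models$svm, Xs)))
  mlp_pred <- mlp_predict(models$mlp, Xs)
  tree_pred <- as.integer(as.character(
    predict(models$tree, data.frame(Xs), type = "class")))
  cbind(svm = svm_pred, mlp = mlp_pred, tree = tree_pred)
}

#' Majority-voting ensemble predictions
#'
#' Collects the three base-classifier votes per row and applies
#' [majority_vote()].
#'
#' @inheritParams predict_base
#' @return Integer vector of `{+1, -1}` predictions.
#' @export
predict_ensemble <- function(models, rows) {
  base <- predict_base(models, rows)
  as.integer(apply(base, 1L, majority_vote))
}

confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1L & pred == 1L),
       fn = sum(truth == 1L & pred == -1L),
       tn = sum(truth == -1L & pred == -1L),
       fp = sum(truth == -1L & pred == 1L))
}

#' Accuracy, specificity and sensitivity from confusion counts
#'
#' Positive class is AD (+1). Accuracy is the fraction of correct calls,
#' sensitivity the detection rate among AD cases, specificity the
#' true-negative rate among controls; all as percentages. Sensitivity or
#' specificity is `NA` when its denominator is zero.
#'
#' @param counts List or named vector with elements `tp`, `fn`, `tn`, `fp`.
#' @return One-row tibble with columns `accuracy`, `specificity`,
#'   `sensitivity` (percent).
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(counts))) {
    stop("compute_metrics: counts must contain tp, fn, tn, fp")
  }
  v <- vapply(counts[need], as.numeric, numeric(1))
  if (any(v < 0)) stop("compute_metrics: counts must be non-negative")
  total <- sum(v)
  if (total == 0) stop("compute_metrics: all counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    accuracy = 100 * (v[["tp"]] + v[["tn"]]) / total,
    specificity = ratio(v[["tn"]], v[["tn"]] + v[["fp"]]),
    sensitivity = ratio(v[["tp"]], v[["tp"]] + v[["fn"]]))
}

#' Stratified k-fold cross-validation of the base classifiers and ensemble
#'
#' Splits the subjects into k stratified folds, trains the three base
#' classifiers on the training folds (with inner SVM tuning and
#' standardization statistics confined to the training folds), predicts the
#' held-out fold with each base model and the majority-voting ensemble, and
#' pools the test predictions over folds into one confusion matrix per
#' classifier (micro-averaged reporting).
#'
#' @param table Feature table (e.g. from [extract_features()] or
#'   [generate_feature_table()]) with a `label` column in `{+1, -1}`.
#' @param k Number of folds (default 10); reduced with a warning when a
#'   class has fewer than `k` members.
#' @param config A [classifier_config()].
#' @param seed Integer seed driving fold assignment and per-fold training.
#' @param subset Feature subset, see [feature_subsets()].
#' @return An object of class `evaluation_report`; see [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] methods.
#' @export
crossvalidate <- function(table, k = 10L, config = classifier_config(),
                          seed = 1L, subset = "all") {
  cols <- resolve_features(table, subset)
  if (nrow(table) == 0L) stop("crossvalidate: empty feature table")
  y <- as.integer(table$label)
  if (length(unique(y)) < 2L) {
    stop("crossvalidate: need both classes present")
  }
  k <- as.integer(k)
  if (k < 2L) stop("crossvalidate: k must be >= 2")
  min_class <- min(table(y))
  if (min_class < 2L) stop("crossvalidate: each class needs >= 2 subjects")
  if (min_class < k) {
    warning(sprintf("crossvalidate: reducing k from %d to %d (smallest class)",
                    k, min_class))
    k <- min_class
  }
  fold <- stratified_folds(y, k, seed)

  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    models <- train_base_classifiers(table[tr, , drop = FALSE], config,
                                     seed = derive_seed(seed, 100L + f),
                                     subset = cols)
    base <- predict_base(models, table[!tr, , drop = FALSE])
    ens <- as.integer(apply(base, 1L, majority_vote))
    preds[[f]] <- tibble::tibble(
      row = which(!tr), fold = f, truth = y[!tr],
      svm = base[, "svm"], mlp = base[, "mlp"], tree = base[, "tree"],
      ensemble = ens)
  }
  predictions <- dplyr::bind_rows(preds) |> dplyr::arrange(.data$row)
  if ("subject_id" %in% names(table)) {
    predictions <- dplyr::mutate(predictions,
                                 subject_id = table$subject_id[.data$row],
                                 .after = "row")
  }

  metrics <- purrr::map_dfr(c("svm", "mlp", "tree", "ensemble"), function(cl) {
    cc <- confusion_counts(predictions$truth, predictions[[cl]])
    dplyr::bind_cols(tibble::tibble(classifier = cl,
                                    tp = cc$tp, fn = cc$fn,
                                    tn = cc$tn, fp = cc$fp),
                     compute_metrics(cc))
  })

  structure(list(metrics = metrics, predictions = predictions,
                 fold = fold, k = k, seed = as.integer(seed),
                 subset = if (is.character(subset) && length(subset) == 1L)
                   subset else paste(cols, collapse = "+"),
                 features = cols, config = config),
            class = "evaluation_report")
}

#' Evaluate all feature subsets
#'
#' Runs [crossvalidate()] for each requested feature subset and stacks the
#' per-classifier metrics into one long table (subsets x classifiers x
#' metrics).
#'
#' @inheritParams crossvalidate
#' @param subsets Character vector of subset names (default all eight).
#' @return A tibble with columns `subset`, `classifier`, the confusion
#'   counts and the three metrics.
#' @export
evaluate_subsets <- function(table, subsets = names(feature_subsets()),
                             k = 10L, config = classifier_config(),
                             seed = 1L) {
  purrr::map_dfr(subsets, function(s) {
    rep <- crossvalidate(table, k = k, config = config, seed = seed,
                         subset = s)
    dplyr::mutate(rep$metrics, subset = s, .before = 1L)
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV, n = %d, features: %s\n",
              x$k, nrow(x$predictions), x$subset))
  print(x$metrics)
  invisible(x)
}

#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  ens <- dplyr::filter(x$metrics, .data$classifier == "ensemble")
  tibble::tibble(accuracy = ens$accuracy, specificity = ens$specificity,
                 sensitivity = ens$sensitivity,
                 n = nrow(x$predictions), k = x$k, seed = x$seed,
                 subset = x$subset)
}

#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              cols = c("accuracy", "specificity",
                                       "sensitivity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("%d-fold cross-validation (%s features)",
                                  object$k, object$subset)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
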