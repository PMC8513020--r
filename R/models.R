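#' Classifier specification
#'
#' One of the six compared classifiers with its fixed hyperparameters:
#' random forest (100 trees), multilayer perceptron (three tanh hidden
#' layers of 100 units, Adam, L2 1e-4, constant learning rate, max 1000
#' iterations), RBF support vector machine (cost 64, class-balanced
#' weights), decision tree (entropy split, max depth 12, min split 11, min
#' leaf 4), 3-nearest-neighbours (Euclidean), and multinomial logistic
#' regression (effectively unregularized, inverse regularization strength
#' 1e6).
#'
#' @param algorithm One of `"RF"`, `"ANN"`, `"SVM"`, `"DT"`, `"KNN"`, `"LR"`.
#' @param ... Hyperparameter overrides (e.g. `n_estimators = 60` for RF).
#' @return A `model_spec` list with `algorithm` and `hyperparameters`.
#' @export
model_spec <- function(algorithm = c("RF", "ANN", "SVM", "DT", "KNN", "LR"),
                       ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    RF = list(n_estimators = 100),
    ANN = list(hidden_layer_sizes = c(100, 100, 100), activation = "tanh",
               solver = "adam", alpha = 1e-4, learning_rate = "constant",
               learning_rate_init = 1e-3, max_iter = 1000),
    SVM = list(kernel = "radial", cost = 64, class_weight = "balanced"),
    DT = list(criterion = "entropy", max_depth = 12, min_samples_split = 11,
              min_samples_leaf = 4),
    KNN = list(n_neighbors = 3, metric = "euclidean"),
    LR = list(solver = "newton-cg", C = 1e6, max_iter = 500)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(algorithm = algorithm, hyperparameters = defaults),
            class = "model_spec")
}

#' The six default classifier specifications
#'
#' @return Named list of [model_spec()] objects (RF, ANN, SVM, DT, KNN, LR).
#' @export
default_model_specs <- function() {
  algos <- c("RF", "ANN", "SVM", "DT", "KNN", "LR")
  setNames(lapply(algos, model_spec), algos)
}

#' Data partitioning specification
#'
#' Either a stratified 80/20 holdout split or stratified 10-fold
#' cross-validation. Stratification keeps the class proportions of the full
#' dataset in every partition (within one row per class); it can be turned
#' off for a purely random split. `group_by_participant = TRUE` instead
#' assigns whole participants to train/test, avoiding within-subject leakage
#' at the cost of matching the row-wise description less closely.
#'
#' @param mode `"holdout"` or `"kfold"`.
#' @param test_fraction Holdout test fraction (default 0.20).
#' @param k Number of folds for `"kfold"` (default 10).
#' @param stratified Stratify by class (default TRUE).
#' @param group_by_participant Split by participant rather than row.
#' @param seed Integer seed for the partition.
#' @return A `partition_spec` list.
#' @export
partition_spec <- function(mode = c("holdout", "kfold"), test_fraction = 0.20,
                           k = 10, stratified = TRUE,
                           group_by_participant = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  structure(list(mode = mode, test_fraction = test_fraction, k = as.integer(k),
                 stratified = stratified,
                 group_by_participant = group_by_participant,
                 seed = as.integer(seed)),
            class = "partition_spec")
}

#' Build a 4x4 confusion matrix from labels
#'
#' Rows are the true class, columns the predicted class, both in the fixed
#' [fatigue_classes()] order (or the supplied levels).
#'
#' @param truth,pred Factors or characters of true and predicted classes.
#' @param levels Class levels defining the matrix order.
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, levels = fatigue_classes()) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  t_ <- factor(as.character(truth), levels = levels)
  p_ <- factor(as.character(pred), levels = levels)
  m <- table(truth = t_, predicted = p_)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(truth = levels, predicted = levels))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision, recall and F1 (`2PR/(P+R)`), multiclass
#' accuracy (`trace/total`), and both averaging conventions: macro (mean of
#' per-class values, the headline convention here) and pooled/micro (metrics
#' of the summed one-vs-rest counts; for single-label multiclass
#' predictions, pooled precision = pooled recall = accuracy identically).
#' Classes with a zero denominator get metric 0 with a warning.
#'
#' @param cm A square count matrix, rows = truth, columns = predicted.
#' @param averaging Headline convention, `"macro"` (default) or `"pooled"`.
#' @return A `fatigue_metrics` object: list with `per_class` tibble,
#'   `accuracy`, `macro`, `pooled`, `n`, and the `averaging` tag.
#' @examples
#' cm <- confusion_matrix(rep(fatigue_classes(), 3), rep(fatigue_classes(), 3))
#' metrics_from_confusion(cm)$accuracy
#' @export
metrics_from_confusion <- function(cm, averaging = c("macro", "pooled")) {
  averaging <- match.arg(averaging)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is all zero", call. = FALSE)
  if (any(cm < 0)) stop("negative counts", call. = FALSE)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_div <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
    if (any(den == 0)) {
      warning("zero denominator for ", what, " in class(es) ",
              paste(rownames(cm)[den == 0], collapse = ", "),
              "; metric set to 0", call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  pooled_p <- sum(tp) / (sum(tp) + sum(fp))
  pooled_r <- sum(tp) / (sum(tp) + sum(fn))
  pooled_f1 <- if (pooled_p + pooled_r == 0) 0 else {
    2 * pooled_p * pooled_r / (pooled_p + pooled_r)
  }
  structure(list(
    per_class = tibble::tibble(
      class = rownames(cm) %||% paste0("class", seq_len(nrow(cm))),
      tp = unname(tp), fp = unname(fp), fn = unname(fn), tn = unname(tn),
      precision = unname(precision), recall = unname(recall), f1 = unname(f1)
    ),
    accuracy = sum(tp) / total,
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    pooled = list(precision = pooled_p, recall = pooled_r, f1 = pooled_f1),
    n = total,
    averaging = averaging
  ), class = "fatigue_metrics")
}

#' @export
print.fatigue_metrics <- function(x, ...) {
  h <- x[[x$averaging]]
  cat(sprintf(
    "<fatigue_metrics> n = %d | accuracy %.3f | %s precision %.3f recall %.3f F1 %.3f\n",
    x$n, x$accuracy, x$averaging, h$precision, h$recall, h$f1))
  invisible(x)
}

#' @export
tidy.fatigue_metrics <- function(x, ...) x$per_class

#' @export
glance.fatigue_metrics <- function(x, ...) {
  h <- x[[x$averaging]]
  tibble::tibble(accuracy = x$accuracy, precision = h$precision,
                 recall = h$recall, f1 = h$f1, averaging = x$averaging,
                 n = x$n)
}

feature_columns <- function(data) {
  fn <- feature_names()
  missing <- setdiff(fn, names(data))
  if (length(missing) > 0) {
    stop("data is missing feature column(s): ",
         paste(head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  }
  fn
}

stratified_test_idx <- function(y, fraction, stratified, seed) {
  with_seed(seed, {
    if (!stratified) {
      sample(seq_along(y), max(1L, round(fraction * length(y))))
    } else {
      unlist(lapply(split(seq_along(y), y), function(idx) {
        if (length(idx) == 0) return(integer(0))
        sample(idx, max(1L, round(fraction * length(idx))))
      }), use.names = FALSE)
    }
  })
}

stratified_folds <- function(y, k, stratified, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    if (!stratified) {
      fold <- sample(rep_len(seq_len(k), length(y)))
    } else {
      for (idx in split(seq_along(y), y)) {
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    fold
  })
}

fit_classifier <- function(spec, x, y, seed) {
  hp <- spec$hyperparameters
  switch(spec$algorithm,
    RF = with_seed(seed, randomForest::randomForest(
      x = x, y = y, ntree = hp$n_estimators, importance = FALSE)),
    ANN = mlp_fit(x, y, hidden = hp$hidden_layer_sizes, alpha = hp$alpha,
                  learning_rate = hp$learning_rate_init,
                  max_iter = hp$max_iter, seed = seed),
    SVM = {
      tab <- table(y)
      w <- if (identical(hp$class_weight, "balanced")) {
        as.list(length(y) / (length(tab) * pmax(tab, 1)))
      } else NULL
      with_seed(seed, e1071::svm(x = x, y = y, kernel = hp$kernel,
                                 cost = hp$cost, class.weights = w))
    },
    DT = {
      d <- data.frame(.class = y, x, check.names = FALSE)
      with_seed(seed, rpart::rpart(
        .class ~ ., data = d, method = "class",
        parms = list(split = "information"),
        control = rpart::rpart.control(maxdepth = hp$max_depth,
                                       minsplit = hp$min_samples_split,
                                       minbucket = hp$min_samples_leaf,
                                       cp = 0, xval = 0)))
    },
    KNN = structure(list(x = x, y = y, k = hp$n_neighbors), class = "gf_knn"),
    LR = {
      d <- data.frame(.class = y, x, check.names = FALSE)
      # C = 1e6 in the reference parameterization is effectively no penalty
      with_seed(seed, nnet::multinom(.class ~ ., data = d, trace = FALSE,
                                     maxit = hp$max_iter, decay = 1 / hp$C,
                                     MaxNWts = 100000))
    }
  )
}

predict_classifier <- function(model, x, levels) {
  pred <- if (inherits(model, "gf_knn")) {
    class::knn(model$x, x, model$y, k = model$k)
  } else if (inherits(model, "rpart")) {
    predict(model, data.frame(x, check.names = FALSE), type = "class")
  } else if (inherits(model, "multinom")) {
    predict(model, data.frame(x, check.names = FALSE))
  } else {
    predict(model, x)
  }
  factor(as.character(pred), levels = levels)
}

#' Train one classifier and evaluate it
#'
#' Fits the specified classifier on a stratified train partition and
#' evaluates it on the held-out rows. In `"kfold"` mode, metrics are the
#' mean across the k fold-wise evaluations and the confusion matrix is the
#' sum over folds (every row is predicted exactly once).
#'
#' @param data Labeled feature tibble from [assemble_dataset()] (a `class`
#'   column plus the 43 feature columns).
#' @param spec A [model_spec()].
#' @param partition A [partition_spec()].
#' @return A `fatigue_fit`: list with `spec`, `partition`, `metrics`
#'   ([metrics_from_confusion()] result), `confusion`, the fitted `model`
#'   (holdout mode), and row counts.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_participants = 3, bout_duration = 30))
#' data <- cohort |> segment_cohort() |>
#'   (\(w) extract_features(cohort, w))() |>
#'   normalize_features() |> assemble_dataset(cohort$labels)
#' fit <- train_eval(data, model_spec("RF"), partition_spec(seed = 1))
#' glance(fit)
#' }
#' @export
train_eval <- function(data, spec, partition = partition_spec()) {
  stopifnot(inherits(spec, "model_spec"), inherits(partition, "partition_spec"))
  fn <- feature_columns(data)
  y <- droplevels(fatigue_factor(data$class))
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  x <- as.matrix(data[, fn])
  levels_ <- levels(y)
  fit_seed <- fan_seed(partition$seed, 31L)

  if (partition$mode == "holdout") {
    test_idx <- if (partition$group_by_participant) {
      parts <- unique(data$participant)
      test_p <- with_seed(partition$seed,
                          sample(parts, max(1L, round(partition$test_fraction *
                                                        length(parts)))))
      which(data$participant %in% test_p)
    } else {
      stratified_test_idx(y, partition$test_fraction, partition$stratified,
                          partition$seed)
    }
    if (nlevels(droplevels(y[-test_idx])) < 2) {
      stop("training partition contains a single class", call. = FALSE)
    }
    model <- fit_classifier(spec, x[-test_idx, , drop = FALSE], y[-test_idx],
                            fit_seed)
    pred <- predict_classifier(model, x[test_idx, , drop = FALSE], levels_)
    cm <- confusion_matrix(y[test_idx], pred, levels_)
    metrics <- metrics_from_confusion(cm)
    out <- list(spec = spec, partition = partition, metrics = metrics,
                confusion = cm, model = model,
                n_train = length(y) - length(test_idx),
                n_test = length(test_idx))
  } else {
    if (any(table(y) < partition$k)) {
      stop("a class has fewer rows than folds", call. = FALSE)
    }
    fold <- stratified_folds(y, partition$k, partition$stratified,
                             partition$seed)
    cms <- list(); fold_metrics <- list()
    for (f in seq_len(partition$k)) {
      te <- which(fold == f)
      model <- fit_classifier(spec, x[-te, , drop = FALSE], y[-te],
                              fan_seed(fit_seed, f))
      pred <- predict_classifier(model, x[te, , drop = FALSE], levels_)
      cms[[f]] <- confusion_matrix(y[te], pred, levels_)
      fold_metrics[[f]] <- glance(metrics_from_confusion(cms[[f]]))
    }
    cm <- Reduce(`+`, cms)
    per_fold <- dplyr::bind_rows(fold_metrics, .id = "fold")
    metrics <- metrics_from_confusion(cm)
    # headline numbers: mean across folds
    metrics$macro$precision <- mean(per_fold$precision)
    metrics$macro$recall <- mean(per_fold$recall)
    metrics$macro$f1 <- mean(per_fold$f1)
    metrics$accuracy <- mean(per_fold$accuracy)
    out <- list(spec = spec, partition = partition, metrics = metrics,
                confusion = cm, model = NULL, per_fold = per_fold,
                n_train = length(y), n_test = length(y))
  }
  structure(out, class = "fatigue_fit")
}

#' @export
print.fatigue_fit <- function(x, ...) {
  cat("<fatigue_fit> ", x$spec$algorithm, " (", x$partition$mode, ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.fatigue_fit <- function(x, ...) {
  dplyr::mutate(x$metrics$per_class, algorithm = x$spec$algorithm, .before = 1)
}

#' @export
glance.fatigue_fit <- function(x, ...) {
  dplyr::mutate(glance(x$metrics), algorithm = x$spec$algorithm, .before = 1,
                n_train = x$n_train, n_test = x$n_test)
}

#' Compare the six classifiers on one dataset
#'
#' Trains and evaluates every supplied specification under the same
#' partition seed and ranks them by macro F1 (the headline metric under
#' class imbalance), breaking ties by accuracy.
#'
#' @param data Labeled feature tibble.
#' @param specs List of [model_spec()]s (default all six).
#' @param partition A [partition_spec()].
#' @return Tibble with one row per model (`algorithm`, `accuracy`,
#'   `precision`, `recall`, `f1`, `rank`, `hyperparameters` string) and the
#'   fitted `fatigue_fit`s in a `fit` list-column, sorted by rank.
#' @export
compare_models <- function(data, specs = default_model_specs(),
                           partition = partition_spec()) {
  fits <- lapply(specs, function(s) train_eval(data, s, partition))
  res <- dplyr::bind_rows(lapply(fits, glance))
  res$hyperparameters <- vapply(specs, function(s) {
    paste(names(s$hyperparameters),
          vapply(s$hyperparameters, function(v) paste(format(v), collapse = ","),
                 character(1)),
          sep = "=", collapse = "; ")
  }, character(1))
  res$fit <- unname(fits)
  res <- res[order(-res$f1, -res$accuracy), ]
  res$rank <- seq_len(nrow(res))
  tibble::as_tibble(res)
}
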