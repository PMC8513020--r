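#' Rank features by random-forest importance
#'
#' Extracts impurity-based (mean decrease in Gini) importances from a fitted
#' random forest, normalizes them to sum to one, sorts descending and
#' computes the cumulative importance curve.
#'
#' @param fit A `fatigue_fit` whose model is a random forest (holdout mode),
#'   or a `randomForest` object.
#' @return An `importance_ranking` tibble: `rank`, `feature`, `index`
#'   (0-based feature index), `importance`, `cumulative`.
#' @export
rank_features <- function(fit) {
  model <- if (inherits(fit, "fatigue_fit")) fit$model else fit
  if (!inherits(model, "randomForest")) {
    stop("feature ranking requires a fitted tree-ensemble (random forest) model",
         call. = FALSE)
  }
  imp <- randomForest::importance(model, type = 2)[, 1]
  w <- imp / sum(imp)
  fn <- feature_names()
  ord <- order(w, decreasing = TRUE)
  out <- tibble::tibble(
    rank = seq_along(ord),
    feature = names(w)[ord],
    index = match(names(w)[ord], fn) - 1L,
    importance = unname(w[ord]),
    cumulative = cumsum(unname(w[ord]))
  )
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Retrain after keeping only the top-k ranked features
#'
#' For each `k`, keeps the `k` highest-importance features (in their
#' original column order, so `k = 43` reproduces the full design matrix
#' exactly) and retrains/evaluates a random forest under the same partition.
#' Optional per-row tree counts allow a reduction grid with its own
#' estimator settings.
#'
#' @param data Labeled feature tibble.
#' @param ranking An [rank_features()] result.
#' @param k_list Numbers of features to keep (default 25, 16, 13, 11, 8).
#' @param partition A [partition_spec()].
#' @param estimators Optional integer vector (recycled) of trees per grid
#'   row; default 100 for every row.
#' @return Tibble with `k`, `n_estimators`, `accuracy`, `precision`,
#'   `recall`, `f1` and the `fatigue_fit`s in a `fit` list-column.
#' @export
reduce_and_eval <- function(data, ranking, k_list = c(25, 16, 13, 11, 8),
                            partition = partition_spec(), estimators = NULL) {
  fn <- feature_names()
  if (any(k_list > length(fn)) || any(k_list < 1)) {
    stop("k must be between 1 and ", length(fn), call. = FALSE)
  }
  est <- rep_len(estimators %||% 100, length(k_list))
  meta <- setdiff(names(data), fn)
  rows <- lapply(seq_along(k_list), function(i) {
    k <- k_list[i]
    keep <- sort(ranking$index[seq_len(k)]) + 1L # original column order
    sub <- data[, c(meta, fn[keep])]
    # absent features are treated as constant (zero) so the design stays 43-wide
    for (f in fn[-keep]) sub[[f]] <- NULL
    fit <- train_eval_subset(sub, fn[keep],
                             model_spec("RF", n_estimators = est[i]), partition)
    dplyr::mutate(glance(fit), k = k, n_estimators = est[i], fit = list(fit),
                  .before = 1)
  })
  dplyr::bind_rows(rows)[, c("k", "n_estimators", "accuracy", "precision",
                             "recall", "f1", "fit")]
}

# train_eval on a feature subset: temporarily narrows the feature-name
# contract to the retained columns
train_eval_subset <- function(data, features, spec, partition) {
  y <- droplevels(fatigue_factor(data$class))
  if (nlevels(y) < 2) stop("labels contain a single class", call. = FALSE)
  x <- as.matrix(data[, features, drop = FALSE])
  levels_ <- levels(y)
  fit_seed <- fan_seed(partition$seed, 31L)
  test_idx <- stratified_test_idx(y, partition$test_fraction,
                                  partition$stratified, partition$seed)
  model <- fit_classifier(spec, x[-test_idx, , drop = FALSE], y[-test_idx],
                          fit_seed)
  pred <- predict_classifier(model, x[test_idx, , drop = FALSE], levels_)
  cm <- confusion_matrix(y[test_idx], pred, levels_)
  structure(list(spec = spec, partition = partition,
                 metrics = metrics_from_confusion(cm), confusion = cm,
                 model = model, n_train = length(y) - length(test_idx),
                 n_test = length(test_idx)),
            class = "fatigue_fit")
}

sensor_subset_indices <- function(subset) {
  map <- sensor_feature_map()
  idx <- switch(subset,
    "all" = c(map$foot, map$l5s1, map$emg),
    "l5s1+foot" = c(map$foot, map$l5s1),
    "l5s1" = map$l5s1,
    "foot" = map$foot,
    stop("unknown sensor subset: ", subset, call. = FALSE)
  )
  sort(idx)
}

#' Retrain after restricting features to sensor subsets
#'
#' Evaluates the cost of removing hardware: for each subset, only features
#' originating from the allowed sensors are kept (foot IMU: indices 0-18;
#' L5-S1 IMU: 19-38; EMG: 39-42) and a random forest is retrained. EMG
#' features are only present in the `"all"` subset, reflecting that surface
#' EMG is too invasive for routine use.
#'
#' @param data Labeled feature tibble.
#' @param subsets Character vector from `"all"`, `"l5s1+foot"`, `"l5s1"`,
#'   `"foot"`.
#' @param partition A [partition_spec()].
#' @param spec Classifier to retrain (default RF with 100 trees).
#' @return Tibble with `subset`, `n_features`, the four headline metrics and
#'   a `fit` list-column.
#' @export
sensor_ablation <- function(data,
                            subsets = c("all", "l5s1+foot", "l5s1", "foot"),
                            partition = partition_spec(),
                            spec = model_spec("RF")) {
  fn <- feature_names()
  rows <- lapply(subsets, function(s) {
    idx <- sensor_subset_indices(s)
    if (length(idx) == 0) stop("empty feature set for subset ", s, call. = FALSE)
    fit <- train_eval_subset(data, fn[idx + 1L], spec, partition)
    dplyr::mutate(glance(fit), subset = s, n_features = length(idx),
                  fit = list(fit), .before = 1)
  })
  dplyr::bind_rows(rows)[, c("subset", "n_features", "accuracy", "precision",
                             "recall", "f1", "fit")]
}
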