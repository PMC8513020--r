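test_that("a perfect prediction gives unit metrics", {
  truth <- rep(fatigue_classes(), times = c(9, 6, 4, 3))
  cm <- confusion_matrix(truth, truth)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$precision, rep(1, 4))
  expect_equal(m$per_class$recall, rep(1, 4))
  expect_equal(m$macro$f1, 1)
  expect_equal(m$pooled$f1, 1)
})

test_that("a class never predicted has zero recall, flagged with a warning", {
  truth <- c("Low", "Low", "Moderate", "High", "VeryHigh")
  pred <- c("Low", "Low", "Moderate", "High", "High")
  m <- suppressWarnings(metrics_from_confusion(confusion_matrix(truth, pred)))
  expect_equal(m$per_class$recall[m$per_class$class == "VeryHigh"], 0)
  expect_warning(metrics_from_confusion(confusion_matrix(truth, pred)),
                 "zero denominator")
  expect_error(metrics_from_confusion(matrix(0, 4, 4)), "all zero")
})

test_that("metrics match a brute-force recount on random prediction sets", {
  set.seed(99)
  classes <- fatigue_classes()
  for (i in 1:200) {
    n <- sample(20:120, 1)
    truth <- sample(classes, n, replace = TRUE, prob = c(4, 3, 2, 1))
    pred <- sample(classes, n, replace = TRUE)
    if (length(unique(truth)) < 4) next
    m <- suppressWarnings(metrics_from_confusion(confusion_matrix(truth, pred)))
    o <- oracle_metrics(truth, pred, classes)
    expect_equal(m$accuracy, o$accuracy, tolerance = 1e-12)
    expect_equal(m$macro$precision, o$macro_precision, tolerance = 1e-12)
    expect_equal(m$macro$recall, o$macro_recall, tolerance = 1e-12)
    expect_equal(m$macro$f1, o$macro_f1, tolerance = 1e-12)
    # pooled precision = pooled recall = accuracy, identically
    expect_identical(m$pooled$precision, m$pooled$recall)
    expect_identical(m$pooled$precision, m$accuracy)
  }
})

test_that("model specifications carry the fixed hyperparameters", {
  specs <- default_model_specs()
  expect_named(specs, c("RF", "ANN", "SVM", "DT", "KNN", "LR"))
  expect_equal(specs$RF$hyperparameters$n_estimators, 100)
  expect_equal(specs$ANN$hyperparameters$hidden_layer_sizes, c(100, 100, 100))
  expect_equal(specs$ANN$hyperparameters$activation, "tanh")
  expect_equal(specs$SVM$hyperparameters$cost, 64)
  expect_equal(specs$DT$hyperparameters$max_depth, 12)
  expect_equal(specs$KNN$hyperparameters$n_neighbors, 3)
  expect_equal(specs$LR$hyperparameters$C, 1e6)
  expect_error(model_spec("RF", trees = 5), "unknown hyperparameter")
  # hyperparameters survive a JSON round trip
  rt <- jsonlite::fromJSON(jsonlite::toJSON(specs$DT$hyperparameters,
                                            auto_unbox = TRUE, digits = NA))
  expect_equal(rt, specs$DT$hyperparameters)
})

test_that("stratified holdout preserves class proportions within one row", {
  data <- tiny_dataset()
  y <- factor(data$class)
  idx <- gaitfatigue:::stratified_test_idx(y, 0.2, TRUE, seed = 77L)
  for (cl in levels(y)) {
    expect_lte(abs(sum(y[idx] == cl) - 0.2 * sum(y == cl)), 1)
  }
})

test_that("train_eval is deterministic and separates a strong effect ladder", {
  data <- tiny_dataset()
  part <- partition_spec(seed = 42L)
  fit1 <- train_eval(data, model_spec("RF"), part)
  fit2 <- train_eval(data, model_spec("RF"), part)
  expect_identical(fit1$confusion, fit2$confusion)
  expect_gte(fit1$metrics$macro$f1, 0.90)
  expect_equal(fit1$n_test + fit1$n_train, nrow(data))
})

test_that("permuted labels score near the majority-class baseline", {
  data <- tiny_dataset()
  perm <- data
  set.seed(1234)
  perm$class <- sample(data$class)
  fit <- train_eval(perm, model_spec("RF"), partition_spec(seed = 7L))
  p0 <- max(table(data$class)) / nrow(data)
  n <- fit$n_test
  half <- 1.96 * sqrt(p0 * (1 - p0) / n)
  expect_lte(fit$metrics$accuracy, p0 + half)
})

test_that("degenerate label sets are rejected", {
  data <- tiny_dataset()
  solo <- data[data$class == "Low", ]
  expect_error(train_eval(solo, model_spec("RF")), "single class")
  few <- data[c(which(data$class == "Low"),
                which(data$class == "VeryHigh")[1:5]), ]
  expect_error(train_eval(few, model_spec("RF"),
                          partition_spec(mode = "kfold", k = 10)),
               "fewer rows than folds")
})

test_that("ten-fold cross-validation predicts every row exactly once", {
  data <- tiny_dataset()
  fit <- train_eval(data, model_spec("DT"),
                    partition_spec(mode = "kfold", k = 10, seed = 3L))
  expect_equal(sum(fit$confusion), nrow(data))
  expect_equal(nrow(fit$per_fold), 10)
  expect_gte(fit$metrics$macro$f1, 0.8)
})

test_that("the MLP engine learns a separable three-class problem", {
  set.seed(61)
  n <- 120
  x <- rbind(matrix(rnorm(n, 0, 0.4), ncol = 2),
             matrix(rnorm(n, 3, 0.4), ncol = 2),
             cbind(rnorm(n / 2, 0, 0.4), rnorm(n / 2, 3, 0.4)))
  y <- factor(rep(c("a", "b", "c"), each = n / 2))
  fit <- gaitfatigue:::mlp_fit(x, y, hidden = c(16, 16), max_iter = 300,
                               seed = 5L)
  expect_gte(mean(predict(fit, x) == y), 0.95)
  p <- predict(fit, x, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(x)), tolerance = 1e-9)
})

test_that("compare_models ranks all six classifiers by macro F1", {
  cmp <- cached("tiny_comparison", function() {
    compare_models(tiny_dataset(), partition = partition_spec(seed = 11L))
  })
  expect_equal(nrow(cmp), 6)
  expect_setequal(cmp$algorithm, c("RF", "ANN", "SVM", "DT", "KNN", "LR"))
  expect_equal(cmp$rank, 1:6)
  expect_true(all(diff(cmp$f1) <= 1e-12))
  # the RF row echoes its 100-tree configuration
  expect_match(cmp$hyperparameters[cmp$algorithm == "RF"], "n_estimators=100")
  # tidy/glance expose per-class and headline views
  fit <- cmp$fit[[1]]
  expect_equal(nrow(tidy(fit)), 4)
  expect_named(glance(fit),
               c("algorithm", "accuracy", "precision", "recall", "f1",
                 "averaging", "n", "n_train", "n_test"),
               ignore.order = TRUE)
})
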