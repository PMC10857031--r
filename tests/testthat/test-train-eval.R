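test_that("an untrained model starts near the uniform cross-entropy", {
  ds <- tiny_dataset(n_subjects = 2, windows = 3, n_classes = 4)
  cfg <- tiny_config()
  mdl <- init_model(cfg, seed = 1)
  probs <- rmfsn_forward(ds, mdl$params, cfg, mdl$state)
  loss <- rmfsn:::ce_loss(t(probs), ds$labels)
  expect_equal(loss, log(4), tolerance = 0.05)
})

test_that("training overfits a single mini-batch", {
  ds <- tiny_dataset(n_subjects = 1, windows = 3, n_classes = 4)
  cfg <- tiny_config(filters = 16L)
  fit <- train_model(ds, cfg, train_config(epochs = 200, batch_size = 12,
                                           learning_rate = 3e-3, seed = 2))
  expect_lt(utils::tail(fit$loss_history, 1), 0.01)
})

test_that("training is seed-deterministic and mostly monotone in loss", {
  ds <- tiny_dataset(n_subjects = 2, windows = 4, n_classes = 4)
  tc <- train_config(epochs = 4, batch_size = 16, learning_rate = 2e-3, seed = 7)
  f1 <- train_model(ds, tiny_config(), tc)
  f2 <- train_model(ds, tiny_config(), tc)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_error(train_model(dataset_subset(ds, ds$labels == 1),
                           tiny_config(), tc), "two classes")
})

test_that("loss decreases across most epoch transitions on separable data", {
  ds <- tiny_dataset(n_subjects = 2, windows = 5, n_classes = 4, noise_sd = 0.1)
  fit <- train_model(ds, tiny_config(filters = 8L),
                     train_config(epochs = 10, batch_size = 20,
                                  learning_rate = 2e-3, seed = 3))
  drops <- diff(fit$loss_history) < 0
  expect_gte(mean(drops), 0.8)
})

test_that("leave-one-subject-out folds partition windows without leakage", {
  ds <- tiny_dataset(n_subjects = 5, windows = 2)
  folds <- loso_folds(ds)
  expect_length(folds, 5L)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, seq_along(ds$labels))
  expect_equal(anyDuplicated(all_test), 0L)
  for (fo in folds) {
    expect_length(unique(ds$subjects[fo$test]), 1L)
    expect_false(any(ds$subjects[fo$train] %in% ds$subjects[fo$test]))
  }
  one <- dataset_subset(ds, ds$subjects == "synth1")
  expect_error(loso_folds(one), "2 subjects")
})

test_that("ratio splits and k-folds are stratified partitions", {
  ds <- tiny_dataset(n_subjects = 5, windows = 5)  # 100 windows, 4 classes
  sp <- ratio_split(ds, c(0.7, 0.1, 0.2), seed = 3)
  expect_equal(length(sp$train$labels), 70L)
  expect_equal(length(sp$val$labels), 10L)
  expect_equal(length(sp$test$labels), 20L)
  expect_true(all(table(sp$test$labels) == 5L))  # class-stratified

  folds <- kfold_folds(ds, 5, seed = 4)
  expect_length(folds, 5L)
  sizes <- vapply(folds, function(f) length(f$test), 0L)
  expect_true(all(sizes == 20L))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), 1:100)
  expect_error(kfold_folds(ds, 101), "k must lie")
})

test_that("metrics match hand-computed values on a binary confusion matrix", {
  # TP = 50, FN = 10, FP = 5, TN = 35 for the positive class
  m <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE,
              dimnames = list(true = c("pos", "neg"), pred = c("pos", "neg")))
  rep1 <- compute_metrics(m)
  expect_equal(rep1$per_class$precision[1], 0.9091, tolerance = 1e-4)
  expect_equal(rep1$per_class$recall[1], 0.8333, tolerance = 1e-4)
  expect_equal(rep1$per_class$f1[1], 0.8696, tolerance = 1e-4)
  expect_equal(rep1$accuracy, 0.85)
})

test_that("a diagonal confusion matrix scores 1 everywhere", {
  m <- diag(c(5L, 9L, 3L))
  rep1 <- compute_metrics(m)
  expect_equal(rep1$accuracy, 1)
  expect_true(all(rep1$per_class$f1 == 1))
  expect_equal(rep1$macro_f1, 1)
})

test_that("zero-denominator classes yield 0 with a flag", {
  m <- matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE)  # class 2 never occurs
  rep1 <- compute_metrics(m)
  expect_true(rep1$zero_denominator)
  expect_equal(rep1$per_class$recall[2], 0)
  expect_error(compute_metrics(matrix(0L, 2, 2)), "empty")
})

test_that("micro recall equals accuracy and metrics are permutation-invariant", {
  set.seed(10)
  for (rep in 1:10) {
    m <- random_confusion(sample(3:6, 1))
    r <- compute_metrics(m)
    micro_recall <- sum(diag(m)) / sum(m)  # identity: micro recall == accuracy
    expect_equal(r$accuracy, micro_recall)
    p <- sample(nrow(m))
    rp <- compute_metrics(m[p, p])
    expect_equal(sort(rp$per_class$f1), sort(r$per_class$f1))
    expect_equal(rp$macro_f1, r$macro_f1)
    expect_equal(rp$accuracy, r$accuracy)
  }
})

test_that("metrics agree with the caret reference implementation", {
  skip_if_not_installed("caret")
  set.seed(11)
  for (rep in 1:5) {
    m <- random_confusion(4)
    r <- compute_metrics(m)
    # caret expects prediction-by-reference tables
    cm <- caret::confusionMatrix(as.table(t(m)))
    by_class <- cm$byClass
    expect_lt(max(abs(by_class[, "Precision"] - r$per_class$precision)), 1e-9)
    expect_lt(max(abs(by_class[, "Recall"] - r$per_class$recall)), 1e-9)
    expect_lt(max(abs(by_class[, "F1"] - r$per_class$f1)), 1e-9)
    expect_lt(abs(as.numeric(cm$overall["Accuracy"]) - r$accuracy), 1e-9)
  }
})

test_that("run_protocol aggregates fold statistics and persists confusions", {
  ds <- tiny_dataset(n_subjects = 3, windows = 3, window_length = 30)
  cfg <- tiny_config(filters = 6L)
  tc <- train_config(epochs = 2, batch_size = 16, learning_rate = 2e-3, seed = 5)
  rep1 <- run_protocol(ds, cfg, tc, "loso")
  expect_length(rep1$fold_accuracy, 3L)
  expect_equal(rep1$fold_mean$accuracy, mean(rep1$fold_accuracy))
  expect_equal(rep1$fold_sd$accuracy, stats::sd(rep1$fold_accuracy))
  expect_length(rep1$fold_confusions, 3L)
  expect_equal(sum(Reduce(`+`, rep1$fold_confusions)), length(ds$labels))

  rr <- run_protocol(ds, cfg, tc, "ratio", ratios = c(0.6, 0.1, 0.3))
  expect_equal(sum(rr$confusion), 11L)  # round(0.9 * 36) .. 36, stratified
})

test_that("the ablation suite covers the six canonical configurations", {
  ds <- tiny_dataset(n_subjects = 2, windows = 3, window_length = 20)
  cfg <- tiny_config(window_length = 20L, filters = 4L, fc_width = 6L)
  tc <- train_config(epochs = 1, batch_size = 24, learning_rate = 1e-3, seed = 6)
  tab <- ablation_suite(ds, cfg, tc, protocol = "ratio")
  expect_equal(nrow(tab), 6L)
  expect_setequal(tab$model, c("Without C", "Without T", "Without M",
                               "Without T and M", "Without C, T, and M", "RMFSN"))
  full <- tab$parameters[tab$model == "RMFSN"]
  bare <- tab$parameters[tab$model == "Without C, T, and M"]
  expect_lt(bare, full)
  expect_true(all(tab$parameters <= full))
  expect_error(ablation_suite(ds, tiny_config(enable_casb = FALSE), tc),
               "all blocks enabled")
})

test_that("selection heatmaps expose the shrinkage survival structure", {
  cfg <- tiny_config(window_length = 20L)
  mdl <- init_model(cfg, seed = 8)
  fit <- structure(list(params = mdl$params, state = mdl$state, config = cfg),
                   class = "rmfsn_fit")
  set.seed(3)
  w <- array(rnorm(2 * 3 * 20), c(2, 3, 20))
  maps <- selection_heatmap(fit, w, mode = "magnitude")
  expect_length(maps, 2L)
  expect_equal(dim(maps[[1]]), c(cfg$filters, cfg$window_length))
  masks <- selection_heatmap(fit, w, mode = "mask")
  expect_true(all(masks[[1]] %in% c(0, 1)))
  # survival mask agrees with the magnitude map's support
  expect_equal(masks[[1]] > 0, maps[[1]] > 0)

  # forcing alpha (hence tau) to zero keeps every activation alive
  fit0 <- fit
  fit0$params$casb$b2 <- rep(-1e3, cfg$filters)
  expect_true(all(selection_heatmap(fit0, w, mode = "mask")[[1]] == 1))

  # identical windows give identical maps at inference
  w2 <- w; w2[2, , ] <- w[1, , ]
  maps2 <- selection_heatmap(fit, w2)
  expect_identical(maps2[[1]], maps2[[2]])

  cfg_off <- tiny_config(enable_casb = FALSE)
  fit_off <- structure(list(params = init_model(cfg_off, 1)$params,
                            state = init_model(cfg_off, 1)$state,
                            config = cfg_off), class = "rmfsn_fit")
  expect_error(selection_heatmap(fit_off, w), "enabled")
})

test_that("checkpoints round-trip through disk", {
  ds <- tiny_dataset(n_subjects = 2, windows = 2, window_length = 20)
  cfg <- tiny_config(window_length = 20L, filters = 4L)
  fit <- train_model(ds, cfg, train_config(epochs = 1, batch_size = 16, seed = 4))
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, fit$params)
  expect_equal(predict(back, ds), predict(fit, ds))
})
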