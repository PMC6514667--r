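# MLP construction, training mechanics, and evaluation metrics.

make_split <- function(X, labels, frac = c(0.6, 0.2, 0.2), seed = 1L) {
  ds <- st_dataset(X, data.frame(source_region = 1L, target_region = 2L,
                                 source_voxel = 0L, target_voxel = 1L,
                                 label = labels))
  split_dataset(ds, frac, seed = seed)
}

test_that("parameter count matches the closed-form sum over dense layers", {
  cfg <- mlp_config(input_dim = 6636L, mode = "binary", seed = 1L)
  model <- build_mlp(cfg)
  expect_equal(mlp_n_params(model),
               (6636 * 64 + 64) + (64 * 32 + 32) + (32 * 32 + 32) +
                 (32 * 1 + 1))

  cfg2 <- mlp_config(input_dim = 4L, mode = "multiclass",
                     hidden_widths = 2L, hidden_activations = "sigmoid",
                     dropout_rates = 0, seed = 1L)
  expect_equal(mlp_n_params(build_mlp(cfg2)), (4 * 2 + 2) + (2 * 3 + 3))
})

test_that("config invariants are enforced", {
  expect_error(mlp_config(10, hidden_widths = c(4, 4),
                          hidden_activations = "relu",
                          dropout_rates = c(0, 0)), "equal length")
  expect_error(mlp_config(10, dropout_rates = c(1, 0.2, 0.2)), "dropout")
  expect_error(mlp_config(10, hidden_activations = c("tanh", "relu", "relu")),
               "sigmoid")
})

test_that("zero dropout forward pass equals the dropout-free network", {
  cfg <- mlp_config(input_dim = 5L, mode = "binary",
                    dropout_rates = c(0, 0, 0), seed = 2L)
  model <- build_mlp(cfg)
  X <- matrix(runif(40), nrow = 8)
  p_eval <- predict_mlp(model, X)
  # training-mode forward with all rates 0 draws no masks
  p_train <- voxconn:::.mlp_forward(model, X, training = TRUE)$out
  expect_identical(p_eval, p_train)
})

test_that("epochs = 0 leaves the model untouched with an empty history", {
  cfg <- mlp_config(input_dim = 4L, mode = "binary", epochs = 0L,
                    seed = 3L)
  model <- build_mlp(cfg)
  split <- make_split(matrix(runif(80), ncol = 4),
                      rep(c(0L, 1L), 10))
  fit <- train_mlp(model, split)
  expect_identical(fit$model$W, model$W)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is deterministic given the seed and runs exactly `epochs` epochs", {
  X <- matrix(runif(400), ncol = 4)
  labels <- as.integer(X[, 1] + X[, 2] > 1)
  cfg <- mlp_config(input_dim = 4L, mode = "binary",
                    hidden_widths = c(8L, 4L, 4L), epochs = 15L,
                    batch_size = 16L, seed = 4L)
  split <- make_split(X, labels)
  f1 <- train_mlp(build_mlp(cfg), split)
  f2 <- train_mlp(build_mlp(cfg), split)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 15L)
  expect_named(f1$history, c("epoch", "loss", "accuracy", "val_loss",
                             "val_accuracy"))
})

test_that("training learns a separable rule and dimension mismatches error", {
  set.seed(5)
  X <- matrix(runif(1200), ncol = 4)
  labels <- as.integer(X[, 1] > X[, 3])
  cfg <- mlp_config(input_dim = 4L, mode = "binary",
                    hidden_widths = c(8L, 4L, 4L),
                    dropout_rates = c(0, 0, 0), epochs = 150L,
                    batch_size = 32L, seed = 5L)
  split <- make_split(X, labels)
  fit <- train_mlp(build_mlp(cfg), split)
  expect_gt(tail(fit$history$accuracy, 1), 0.9)

  bad <- make_split(matrix(runif(60), ncol = 3), rep(0:1, 10))
  expect_error(train_mlp(build_mlp(cfg), bad), "configuration error")
})

test_that("confusion matrix and per-class metrics match hand computations", {
  truth <- c(0L, 0L, 1L, 1L, 2L, 2L, 2L)
  pred <-  c(0L, 1L, 1L, 1L, 2L, 0L, 2L)
  cm <- confusion_matrix(truth, pred, classes = 0:2)
  expect_equal(unname(cm),
               matrix(c(1L, 0L, 1L,  1L, 2L, 0L,  0L, 0L, 2L), nrow = 3))
  expect_equal(sum(cm), 7L)
  pct <- confusion_percent(cm)
  expect_equal(unname(rowSums(pct)), rep(100, 3))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$per_class$precision, c(1 / 2, 2 / 3, 1))
  expect_equal(m$per_class$recall, c(1 / 2, 1, 2 / 3))
  expect_equal(m$per_class$f1,
               c(0.5, 2 * (2 / 3) / (2 / 3 + 1), 2 * (2 / 3) / (2 / 3 + 1)))
})

test_that("perfect 3-class predictions yield the identity confusion matrix and all-1 metrics", {
  truth <- rep(0:2, each = 3)
  cm <- confusion_matrix(truth, truth, classes = 0:2)
  expect_equal(unname(cm), diag(3L) * 3L)
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$per_class$f1, rep(1, 3))
})

test_that("a class absent from the test set gets NA metrics, not zero", {
  cm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), classes = 0:2)
  m <- classification_metrics(cm)
  expect_true(is.na(m$per_class$recall[3]))
  expect_true(is.na(m$per_class$precision[3]))
})

test_that("AUC matches pair-counting on toy cases and is monotone-invariant", {
  expect_equal(roc_auc(c(1L, 1L, 0L, 0L), c(0.9, 0.8, 0.3, 0.1)), 1.0)
  # 4 positive-negative pairs: 3 concordant, 1 discordant
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), c(0.9, 0.8, 0.3, 0.1)), 0.75)
  # 4 positive-negative pairs: 2 concordant, 2 discordant
  expect_equal(roc_auc(c(1L, 0L, 1L, 0L), c(0.9, 0.8, 0.3, 0.4)), 0.5)

  set.seed(6)
  truth <- rbinom(50, 1, 0.5)
  scores <- runif(50)
  a1 <- roc_auc(truth, scores)
  expect_equal(roc_auc(truth, exp(5 * scores)), a1)
  expect_equal(roc_auc(truth, rank(scores)), a1)

  rc <- roc_curve(truth, scores)
  expect_equal(rc$fpr[1], 0)
  expect_equal(tail(rc$tpr, 1), 1)
  expect_error(roc_curve(rep(1L, 4), runif(4)), "both classes")
})

test_that("our trapezoidal AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    truth <- rbinom(40, 1, 0.5)
    scores <- round(runif(40), 2)  # ties included
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(truth, scores), ref, tolerance = 1e-12)
  }
})

test_that("evaluate_mlp assembles a coherent report", {
  X <- matrix(runif(600), ncol = 4)
  labels <- as.integer(X[, 1] > X[, 3])
  cfg <- mlp_config(input_dim = 4L, mode = "binary",
                    hidden_widths = c(8L, 4L, 4L),
                    dropout_rates = c(0, 0, 0), epochs = 40L,
                    batch_size = 32L, seed = 8L)
  split <- make_split(X, labels)
  fit <- train_mlp(build_mlp(cfg), split)
  rep <- evaluate_mlp(fit$model, split$test, history = fit$history)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$confusion), nrow(split$test$features))
  # accuracy from the matrix equals direct fraction correct
  pred <- predict_mlp(fit$model, split$test$features, type = "class")
  expect_equal(rep$accuracy, mean(pred == split$test$meta$label))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_equal(unname(rowSums(rep$confusion_percent)),
               rep(100, 2))
})

test_that("models round-trip through their JSON serialization", {
  cfg <- mlp_config(input_dim = 6L, mode = "multiclass",
                    hidden_widths = c(5L, 3L, 3L), seed = 9L)
  model <- build_mlp(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(model, path)
  back <- load_mlp(path)
  expect_equal(back$W, model$W)
  expect_equal(back$b, model$b)
  expect_equal(back$config$hidden_widths, cfg$hidden_widths)
  X <- matrix(runif(60), ncol = 6)
  expect_equal(predict_mlp(back, X), predict_mlp(model, X))
})

test_that("multiclass training separates three well-separated strata", {
  # The three-stratum task is designed for separation: 12 regions, pairs
  # within a factor-~2 of either threshold dropped (so strata have a margin
  # in connectivity and hence in expression space), classes balanced by the
  # per-class caps, and no dropout — at a few hundred training vectors the
  # regularisation rates suited to tens of thousands of vectors prevent
  # convergence.
  atlas <- generate_atlas(synthetic_config(n_regions = 12L, noise_sd = 0.3,
                                           seed = 1L))
  pairs <- pair_connectivity_table(atlas$experiments,
                                   atlas$annotation$fine,
                                   scheme = label_scheme("multiclass"))
  pairs <- pairs[pairs$value == 0 |
                   (pairs$value >= 0.012 & pairs$value < 0.05) |
                   pairs$value >= 0.2, ]
  expect_true(all(table(pairs$label) >= 8))
  built <- build_st_dataset(pairs, atlas$annotation$coarse,
                            atlas$expression,
                            build_config(M = 25L,
                                         per_class_cap = c("0" = 350,
                                                           "1" = Inf,
                                                           "2" = 350),
                                         seed = 1L))
  cfg <- mlp_config(input_dim = ncol(built$split$train$features),
                    mode = "multiclass", dropout_rates = c(0, 0, 0),
                    epochs = 100L, batch_size = 6L, seed = 1L)
  fit <- train_mlp(build_mlp(cfg), built$split)
  rep <- evaluate_mlp(fit$model, built$split$test)
  f1 <- rep$per_class$f1
  f1[is.na(f1)] <- 0  # a collapsed class counts as failure, not missing
  expect_gt(mean(f1), 0.8)
  # train accuracy >= validation accuracy at the final epoch, up to the
  # sampling noise of a ~100-vector validation partition
  expect_gte(tail(fit$history$accuracy, 1) + 0.05,
             tail(fit$history$val_accuracy, 1))
})
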