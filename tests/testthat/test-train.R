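make_checkpoint <- function(epoch, val_correlation, val_accuracy = NA_real_) {
  structure(list(model_state = NULL, center = NULL, scale = NULL,
                 epoch = epoch, hyperparams = NULL,
                 val_correlation = val_correlation,
                 val_accuracy = val_accuracy),
            class = "luma_checkpoint")
}

test_that("model selection returns the calibration argmax", {
  one <- make_checkpoint(1, 0.4)
  expect_identical(select_model(list(one)), one)
  cks <- list(make_checkpoint(1, 0.2), make_checkpoint(2, 0.8),
              make_checkpoint(3, 0.5))
  expect_identical(select_model(cks)$epoch, 2)
  expect_error(select_model(list()), "no checkpoints")
})

test_that("selection ties resolve to the earliest epoch, order-independent", {
  cks <- list(make_checkpoint(3, 0.8), make_checkpoint(1, 0.8),
              make_checkpoint(2, 0.5))
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    expect_identical(select_model(cks[perm])$epoch, 1)
  }
})

test_that("selection falls back to accuracy when no correlation exists", {
  cks <- list(make_checkpoint(1, NA_real_, 0.6),
              make_checkpoint(2, NA_real_, 0.9))
  expect_identical(select_model(cks)$epoch, 2)
})

test_that("a calibrated checkpoint beats one with shuffled predictions", {
  # plant: iLumA% equal to true admixture vs the same values shuffled
  set.seed(13)
  pl <- runif(12)
  shuffled <- sample(pl)
  good <- make_checkpoint(1, stats::cor(pl * 100, pl))
  bad <- make_checkpoint(2, stats::cor(shuffled * 100, pl))
  expect_identical(select_model(list(bad, good))$epoch, 1)
})

test_that("training rejects single-class data and learns separable textures", {
  fx <- patch_training_data()
  expect_error(train_classifier(fx$train$features,
                                rep("LumA", nrow(fx$train$features)),
                                NULL, train_config(epochs = 1)),
               "both classes")

  cfg <- train_config(epochs = 5, seed = 2)
  tr <- suppressWarnings(train_classifier(fx$train$features, fx$train$labels,
                                          fx$val_pure, cfg))
  accs <- vapply(tr$checkpoints, `[[`, numeric(1), "val_accuracy")
  expect_gt(max(accs), 0.95)   # zero-label-noise, separable by construction
  expect_length(tr$checkpoints, 5)
  # training loss decreases overall
  expect_lt(utils::tail(tr$loss_trace, 1), tr$loss_trace[1])
})

test_that("checkpoints track the iLumA%-pLumA calibration on mixed slides", {
  fx <- patch_training_data()
  val <- mapply(function(a, b) {
    if (is.matrix(a)) rbind(a, b) else c(a, b)
  }, fx$val_pure, fx$val_mixed, SIMPLIFY = FALSE)
  tr <- train_classifier(fx$train$features, fx$train$labels, val,
                         train_config(epochs = 5, seed = 2))
  best <- select_model(tr)
  expect_gte(best$val_correlation, 0.8)
  expect_true(all(vapply(tr$checkpoints, `[[`, numeric(1),
                         "val_correlation") >= -1, na.rm = TRUE))
})

test_that("training is reproducible for a fixed seed", {
  fx <- patch_training_data()
  cfg <- train_config(epochs = 2, seed = 7)
  t1 <- suppressWarnings(train_classifier(fx$train$features, fx$train$labels,
                                          fx$val_pure, cfg))
  t2 <- suppressWarnings(train_classifier(fx$train$features, fx$train$labels,
                                          fx$val_pure, cfg))
  expect_identical(t1$checkpoints[[2]]$model_state,
                   t2$checkpoints[[2]]$model_state)
  expect_identical(t1$loss_trace, t2$loss_trace)
})

test_that("GCE with pruning is no worse than plain CE under 30% label noise", {
  fx <- patch_training_data()
  res <- vapply(1:5, function(s) {
    noisy <- lumahet:::flip_labels(fx$train$labels, 0.3, seed = 100 + s)
    gce <- suppressWarnings(train_classifier(
      fx$train$features, noisy, fx$val_pure,
      train_config(epochs = 15, seed = s)))        # default GCE + pruning
    ce <- suppressWarnings(train_classifier(
      fx$train$features, noisy, fx$val_pure,
      train_config(epochs = 15, seed = s, q_exponent = 1e-3,
                   prune_fraction = 0)))           # cross-entropy limit
    c(gce = max(vapply(gce$checkpoints, `[[`, numeric(1), "val_accuracy")),
      ce = max(vapply(ce$checkpoints, `[[`, numeric(1), "val_accuracy")))
  }, numeric(2))
  expect_gte(stats::median(res["gce", ]), stats::median(res["ce", ]))
})
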