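#' Training configuration for the patch classifier
#'
#' Full-scale defaults follow the study design (Adam at learning rate 1e-4,
#' batch size 80, weight decay 0.2); the desk-scale preset keeps the same
#' optimizer and loss machinery but uses batch size 32 and a larger learning
#' rate suited to the compact feature network trained from scratch for a few
#' epochs.
#'
#' @param scale `"desk"` (default) or `"full"`.
#' @param ... Named overrides of any field: `learning_rate`, `batch_size`,
#'   `weight_decay`, `epochs`, `q_exponent` (GCE exponent in (0,1\]),
#'   `prune_fraction` (fraction of lowest-confidence samples zero-weighted
#'   per round), `warmup_epochs`, `augment_ops`, `seed`, `architecture`
#'   (currently `"feature_mlp"`), `hidden` (hidden layer widths).
#' @return Named list of class `train_config`.
#' @export
train_config <- function(scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    learning_rate = if (scale == "desk") 2e-3 else 1e-4,
    batch_size = if (scale == "desk") 32L else 80L,
    weight_decay = 0.2,
    epochs = if (scale == "desk") 30L else 20L,
    q_exponent = 0.7,
    prune_fraction = 0.1,
    warmup_epochs = 2L,
    augment_ops = list(flip = FALSE, rotate = FALSE, jitter = FALSE,
                       elastic = FALSE),
    seed = 1L,
    architecture = "feature_mlp",
    hidden = c(24L, 8L)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(cfg, over)
  }
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (cfg$q_exponent <= 0 || cfg$q_exponent > 1) stop("q_exponent must be in (0,1]", call. = FALSE)
  if (cfg$prune_fraction < 0 || cfg$prune_fraction >= 1) stop("prune_fraction must be in [0,1)", call. = FALSE)
  class(cfg) <- c("train_config", "list")
  cfg
}

# ---- compact fully-connected network, trained with hand-rolled Adam ----

mlp_init <- function(d_in, hidden) {
  sizes <- c(d_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(rnorm(sizes[i] * sizes[i + 1L],
                          sd = sqrt(2 / sizes[i])), sizes[i], sizes[i + 1L]),
         b = numeric(sizes[i + 1L]))
  })
}

mlp_forward <- function(params, X, cache = FALSE) {
  A <- X
  acts <- if (cache) list(A) else NULL
  L <- length(params)
  for (i in seq_len(L)) {
    Z <- A %*% params[[i]]$W
    Z <- sweep(Z, 2L, params[[i]]$b, "+")
    A <- if (i < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
    if (cache) acts[[i + 1L]] <- A
  }
  if (cache) list(prob = as.numeric(A), acts = acts) else as.numeric(A)
}

# Gradient of the weighted GCE loss; y in {0,1}, w per-sample weights.
mlp_grad <- function(params, X, y, w, q) {
  fw <- mlp_forward(params, X, cache = TRUE)
  p <- fw$prob
  p_true <- pmax(ifelse(y == 1, p, 1 - p), 1e-7)
  n_eff <- max(sum(w), 1)
  loss <- sum(w * (1 - p_true^q) / q) / n_eff
  # dL/dz at the output logit
  delta <- matrix(-(p_true^(q - 1)) * (2 * y - 1) * p * (1 - p) * w / n_eff,
                  ncol = 1L)
  L <- length(params)
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    A_prev <- fw$acts[[i]]
    grads[[i]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(params[[i]]$W)) * (fw$acts[[i]] > 0)
    }
  }
  list(grads = grads, loss = loss)
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW <- s$mW / (1 - beta1^t); vW <- s$vW / (1 - beta2^t)
    mb <- s$mb / (1 - beta1^t); vb <- s$vb / (1 - beta2^t)
    params[[i]]$W <- params[[i]]$W - lr * (mW / (sqrt(vW) + eps) +
                                             weight_decay * params[[i]]$W)
    params[[i]]$b <- params[[i]]$b - lr * mb / (sqrt(vb) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

#' Train the LumA vs non-LumA patch classifier
#'
#' Minimizes the sample-weighted generalized cross-entropy over patch
#' feature vectors with Adam. Each epoch first refreshes the pruning
#' weights from the current model's per-sample true-class probabilities
#' ([sample_weight_update()]) — warm-up epochs train on everything, later
#' epochs drop the lowest-confidence (putatively mislabeled) fraction —
#' then sweeps shuffled minibatches. After every epoch a checkpoint records
#' validation patch accuracy and, when at least 3 validation slides with
#' distinct pLumA are supplied, the Pearson correlation between slide-level
#' iLumA% and pLumA, the model-selection currency.
#'
#' @param features Numeric matrix, one row per training patch
#'   ([featurize_patches()]).
#' @param labels Patch labels: `"LumA"`/`"nonLumA"` or 1/0. Both classes
#'   must be present.
#' @param validation List with `features` (matrix), `labels`, `slide_id`
#'   (per-patch slide identifier) and `pLumA` (named per-slide genomic
#'   admixture proportions), or `NULL` for no validation tracking.
#' @param config A [train_config()].
#' @return Object of class `luma_training`: list of per-epoch `checkpoint`
#'   objects plus the training-loss trace.
#' @export
train_classifier <- function(features, labels, validation = NULL,
                             config = train_config()) {
  y <- to_binary_label(labels)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  stopifnot(nrow(features) == length(y))
  center <- colMeans(features)
  spread <- apply(features, 2L, stats::sd)
  spread[spread == 0 | !is.finite(spread)] <- 1
  X <- sweep(sweep(features, 2L, center, "-"), 2L, spread, "/")
  n <- nrow(X)

  val <- NULL
  if (!is.null(validation)) {
    val <- validation
    val$X <- sweep(sweep(val$features, 2L, center, "-"), 2L, spread, "/")
    val$y <- to_binary_label(val$labels)
  }

  with_seed(config$seed, {
    params <- mlp_init(ncol(X), config$hidden)
    state <- adam_init(params)
    t_step <- 0L
    loss_trace <- numeric(config$epochs)
    checkpoints <- vector("list", config$epochs)
    corr_warned <- FALSE
    for (epoch in seq_len(config$epochs)) {
      p_all <- mlp_forward(params, X)
      p_true <- ifelse(y == 1, p_all, 1 - p_all)
      w <- sample_weight_update(p_true, config$prune_fraction, epoch,
                                config$warmup_epochs)
      ord <- sample.int(n)
      epoch_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        g <- mlp_grad(params, X[idx, , drop = FALSE], y[idx], w[idx],
                      config$q_exponent)
        t_step <- t_step + 1L
        upd <- adam_step(params, g$grads, state, t_step,
                         config$learning_rate, config$weight_decay)
        params <- upd$params; state <- upd$state
        epoch_loss <- epoch_loss + g$loss; n_batches <- n_batches + 1L
      }
      loss_trace[epoch] <- epoch_loss / n_batches

      val_acc <- NA_real_; val_cor <- NA_real_
      if (!is.null(val)) {
        vp <- mlp_forward(params, val$X)
        val_acc <- mean((vp > 0.5) == (val$y == 1))
        by_slide <- split(vp, val$slide_id)
        iluma <- vapply(by_slide, function(p) 100 * mean(p > 0.5), numeric(1))
        pl <- val$pLumA[names(by_slide)]
        if (length(iluma) < 3 || length(unique(pl)) < 3) {
          if (!corr_warned) {
            warning("fewer than 3 validation slides with distinct pLumA; ",
                    "falling back to validation accuracy for model selection")
            corr_warned <- TRUE
          }
        } else if (stats::sd(iluma) > 0) {
          # constant iLumA% leaves the correlation undefined (NA) this epoch
          val_cor <- stats::cor(iluma, pl)
        }
      }
      checkpoints[[epoch]] <- structure(
        list(model_state = params, center = center, scale = spread,
             epoch = epoch, hyperparams = config,
             val_correlation = val_cor, val_accuracy = val_acc),
        class = "luma_checkpoint")
    }
    structure(list(checkpoints = checkpoints, loss_trace = loss_trace,
                   config = config),
              class = "luma_training")
  })
}

to_binary_label <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("LumA", "nonLumA"))
    if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    as.integer(labels == "LumA")
  } else {
    as.integer(labels)
  }
}

#' Select the calibration-best checkpoint
#'
#' Returns the checkpoint maximizing the validation iLumA%-vs-pLumA Pearson
#' correlation; ties resolve to the earliest epoch, independent of list
#' order. If no checkpoint has a correlation (too few distinct validation
#' slides), validation accuracy is used instead.
#'
#' @param checkpoints A `luma_training` object or list of
#'   `luma_checkpoint`s.
#' @return The selected `luma_checkpoint`.
#' @export
select_model <- function(checkpoints) {
  if (inherits(checkpoints, "luma_training")) checkpoints <- checkpoints$checkpoints
  if (!length(checkpoints)) stop("no checkpoints supplied", call. = FALSE)
  epochs <- vapply(checkpoints, `[[`, numeric(1), "epoch")
  checkpoints <- checkpoints[order(epochs)]
  metric <- vapply(checkpoints, `[[`, numeric(1), "val_correlation")
  if (all(is.na(metric))) {
    metric <- vapply(checkpoints, `[[`, numeric(1), "val_accuracy")
  }
  if (all(is.na(metric))) return(checkpoints[[length(checkpoints)]])
  checkpoints[[which.max(metric)]]  # which.max takes the first (earliest) max
}

#' @export
print.luma_checkpoint <- function(x, ...) {
  cat(sprintf("Patch-classifier checkpoint (epoch %d)\n", x$epoch))
  cat(sprintf("  val iLumA%%-pLumA correlation: %s, val accuracy: %s\n",
              format(x$val_correlation, digits = 3),
              format(x$val_accuracy, digits = 3)))
  invisible(x)
}

#' @export
print.luma_training <- function(x, ...) {
  cat(sprintf("Training run: %d epochs, final loss %.4f\n",
              length(x$checkpoints), utils::tail(x$loss_trace, 1)))
  best <- select_model(x)
  cat(sprintf("  best checkpoint: epoch %d\n", best$epoch))
  invisible(x)
}
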