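#' Training configuration
#'
#' Optimizer and loop settings. Adam with learning rate 5e-4 and voxel-wise
#' categorical cross-entropy are the defaults; training monitors the overall
#' validation Dice (computed on plain argmax predictions, no post-processing)
#' and checkpoints every improvement, stopping after `patience` epochs
#' without one.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param max_epochs maximum number of epochs (>= 1).
#' @param patience epochs without validation-Dice improvement before stop.
#' @param batch_size volumes per optimizer step (gradients averaged).
#' @param seed integer seed controlling epoch shuffling.
#' @param checkpoint_dir directory for improvement checkpoints (`NULL` keeps
#'   the best model in memory only).
#' @param stop_at_train_loss optional early exit once the mean training loss
#'   drops below this value (used by overfitting capacity checks).
#' @param verbose print a line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, max_epochs = 200L,
                         patience = 15L, batch_size = 1L, seed = 1L,
                         checkpoint_dir = NULL, stop_at_train_loss = NULL,
                         verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 stop_at_train_loss = stop_at_train_loss,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Voxel-wise categorical cross-entropy
#'
#' `mean over voxels of -sum_i y_i log(p_i)` over the class channels, with
#' probabilities clipped at `eps` before the log. Zero (up to the clip) when
#' the prediction equals the one-hot target; a uniform three-class
#' prediction scores `log(3)` per voxel.
#'
#' @param prediction probability array `(rows, cols, slices, classes)`,
#'   per-voxel channel sums ~1.
#' @param target one-hot array of the same shape.
#' @param eps clipping floor for the probabilities (default 1e-7).
#' @return Non-negative scalar.
#' @export
categorical_cross_entropy <- function(prediction, target, eps = 1e-7) {
  if (!identical(dim(prediction), dim(target)))
    stop(sprintf("prediction shape %s does not match target shape %s",
                 paste(dim(prediction), collapse = "x"),
                 paste(dim(target), collapse = "x")))
  d <- dim(prediction)
  n_vox <- prod(d[-length(d)])
  -sum(target * log(pmax(prediction, eps))) / n_vox
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(params)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    params[[key]] <- params[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = params, state = state)
}

val_metrics <- function(model, val_set) {
  losses <- numeric(length(val_set))
  d_bg <- d_wall <- d_tum <- numeric(length(val_set))
  for (i in seq_along(val_set)) {
    s <- val_set[[i]]
    oh <- s$onehot %||% to_onehot(s$labels)
    probs <- unet_forward(model, s$image, keep_cache = FALSE)$probs
    losses[i] <- categorical_cross_entropy(probs, oh)
    pred <- from_onehot(probs)
    d_bg[i] <- dice(pred == 0, s$labels == 0)
    d_wall[i] <- dice(pred == 255, s$labels == 255)
    d_tum[i] <- dice(pred == 125, s$labels == 125)
  }
  c(loss = mean(losses), background = mean(d_bg), wall = mean(d_wall),
    tumor = mean(d_tum), overall = mean((d_bg + d_wall + d_tum) / 3))
}

#' Train a 3D U-Net
#'
#' Fits `model` with Adam on voxel-wise categorical cross-entropy, iterating
#' seeded shuffled epochs over the training set. After each epoch the
#' validation loss and per-class validation Dice (argmax predictions) are
#' computed; whenever the overall validation Dice improves on the running
#' best, the model is checkpointed (and retained as the best). Training
#' stops at `max_epochs`, after `patience` epochs without improvement, or
#' once the optional training-loss target is reached. A non-finite loss
#' aborts with the offending epoch.
#'
#' @param model a [build_model()] network.
#' @param train_set,val_set lists of samples, each `list(image, labels)`
#'   (optionally a precomputed `onehot`), with `image` matching the model's
#'   input shape.
#' @param config a [train_config()].
#' @return An object of class `unet_train`: `model` (best checkpoint),
#'   `history` (per-epoch data frame), `best_epoch`, `best_val_dice`, and
#'   `checkpoints` (paths, when a checkpoint directory was given).
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "unet3d"), inherits(config, "train_config"))
  if (!length(train_set) || !length(val_set))
    stop("train_set and val_set must be non-empty")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  params <- get_params(model)
  state <- adam_init(params)
  n_vox <- prod(model$spec$input_shape)
  onehots <- lapply(train_set, function(s) s$onehot %||% to_onehot(s$labels))

  best_dice <- -Inf
  best_model <- model
  best_epoch <- 0L
  since_improved <- 0L
  checkpoints <- character(0)
  hist <- list()
  if (!is.null(config$checkpoint_dir))
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample.int(length(train_set))
    epoch_losses <- numeric(0)
    acc <- NULL
    acc_n <- 0L
    for (pos in seq_along(order_idx)) {
      s <- train_set[[order_idx[pos]]]
      oh <- onehots[[order_idx[pos]]]
      fw <- unet_forward(model, s$image, keep_cache = TRUE)
      loss <- categorical_cross_entropy(fw$probs, oh)
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      epoch_losses <- c(epoch_losses, loss)
      dz <- (fw$probs - oh) / n_vox
      g <- unet_backward(model, fw$cache, dz)
      if (is.null(acc)) acc <- g
      else for (key in names(acc)) acc[[key]] <- acc[[key]] + g[[key]]
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || pos == length(order_idx)) {
        if (acc_n > 1L)
          for (key in names(acc)) acc[[key]] <- acc[[key]] / acc_n
        st <- adam_step(params, acc, state, config$learning_rate)
        params <- st$params
        state <- st$state
        model <- set_params(model, params)
        acc <- NULL
        acc_n <- 0L
      }
    }
    vm <- val_metrics(model, val_set)
    improved <- vm[["overall"]] > best_dice
    if (improved) {
      best_dice <- vm[["overall"]]
      best_model <- model
      best_epoch <- epoch
      since_improved <- 0L
      if (!is.null(config$checkpoint_dir)) {
        path <- file.path(config$checkpoint_dir,
                          sprintf("checkpoint_epoch%03d.rds", epoch))
        saveRDS(model, path)
        checkpoints <- c(checkpoints, path)
      }
    } else since_improved <- since_improved + 1L
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(epoch_losses),
      val_loss = vm[["loss"]], val_dice_background = vm[["background"]],
      val_dice_wall = vm[["wall"]], val_dice_tumor = vm[["tumor"]],
      val_dice_overall = vm[["overall"]], improved = improved)
    if (config$verbose)
      message(sprintf("epoch %3d  train loss %.5f  val loss %.5f  val dice %.4f%s",
                      epoch, mean(epoch_losses), vm[["loss"]], vm[["overall"]],
                      if (improved) " *" else ""))
    if (!is.null(config$stop_at_train_loss) &&
        mean(epoch_losses) < config$stop_at_train_loss) break
    if (since_improved >= config$patience) break
  }
  structure(list(model = best_model, last_model = model,
                 history = do.call(rbind, hist), best_epoch = best_epoch,
                 best_val_dice = best_dice, checkpoints = checkpoints),
            class = "unet_train")
}

#' @export
print.unet_train <- function(x, ...) {
  cat(sprintf(paste0("<unet_train> %d epochs; best overall validation Dice ",
                     "%.4f at epoch %d; final train loss %.5f\n"),
              nrow(x$history), x$best_val_dice, x$best_epoch,
              x$history$train_loss[nrow(x$history)]))
  invisible(x)
}
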