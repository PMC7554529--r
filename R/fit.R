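#' Training configuration
#'
#' Defaults mirror the within-subject training recipe: SGDM with learning
#' rate 6.7929e-4 and momentum 0.9799, batch size 40, 55 epochs, L2
#' 0.0014, a piecewise learning-rate schedule that multiplies the rate by
#' `lr_drop_factor` every `lr_drop_period` epochs, and 500 randomly drawn
#' segment images held out for monitoring. For Adam the conventional
#' moment decays 0.9/0.999 and epsilon 1e-8 are used.
#'
#' @param optimizer `"sgdm"` or `"adam"`.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param learning_rate Initial learning rate; default 6.7929e-4 for SGDM
#'   and 0.01 for Adam.
#' @param momentum SGDM momentum coefficient.
#' @param lr_drop_factor,lr_drop_period Learning-rate schedule: multiply
#'   by `lr_drop_factor` after every `lr_drop_period` epochs.
#' @param l2 Weight-decay coefficient for conv/FC kernels.
#' @param validation_size Number of segment images sampled (without
#'   replacement) from the training set and held out purely to monitor
#'   validation loss/error; capped at a quarter of the data. `0` disables
#'   monitoring. There is no early stopping.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param seed Root seed governing weight initialization, shuffling and
#'   validation sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(optimizer = c("sgdm", "adam"), epochs = 55,
                         batch_size = 40, learning_rate = NULL,
                         momentum = 0.9799, lr_drop_factor = 0.1,
                         lr_drop_period = 20, l2 = 0.0014,
                         validation_size = 500, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1) stopf("midecoder_error_config", "epochs must be >= 1")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1)
    stopf("midecoder_error_config", "lr_drop_factor must be in (0, 1]")
  learning_rate <- learning_rate %??%
    if (optimizer == "sgdm") 6.7929e-4 else 0.01
  structure(list(optimizer = optimizer, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period), l2 = l2,
                 validation_size = as.integer(validation_size),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "train_config")
}

label_index <- function(label) {
  as.integer(factor(as.character(label), levels = c("left", "right")))
}

one_hot <- function(idx, k = 2) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Fit a spectrogram-image CNN
#'
#' Trains an architecture from [build_architecture()] on a segment-image
#' table from [trials_to_images()] with seeded shuffled mini-batches,
#' weight decay on conv/FC kernels, and the piecewise learning-rate
#' schedule of the configuration. Every epoch records the mean training
#' loss (cross-entropy plus the L2 penalty), the learning rate in force,
#' and — when a monitoring split is configured — validation loss and
#' misclassification rate in inference mode.
#'
#' @param images A segment-image tibble with `image` and `label` columns.
#' @param architecture An `mi_architecture`; the `l2` of `config`
#'   overrides the architecture's block-level coefficient.
#' @param config A [train_config()].
#' @return An `mi_cnn_fit` object: `model`, `history` tibble, `config`.
#' @export
fit_cnn <- function(images, architecture = build_architecture("arch1"),
                    config = train_config()) {
  if (!nrow(images)) stopf("midecoder_error_config", "no training images")
  arch <- architecture
  for (i in seq_along(arch$stages))
    if (inherits(arch$stages[[i]], "mega_block"))
      arch$stages[[i]]$block$l2 <- config$l2
  model <- init_cnn(arch, seed = config$seed)
  for (i in seq_along(model$plan))
    if (model$plan[[i]]$type %in% c("conv", "fc"))
      model$plan[[i]]$l2 <- config$l2
  y_all <- label_index(images$label)
  if (anyNA(y_all))
    stopf("midecoder_error_label", "labels must be left/right")
  n <- nrow(images)
  val_idx <- integer(0)
  if (config$validation_size > 0) {
    n_val <- min(config$validation_size, n %/% 4)
    if (n_val > 0)
      val_idx <- with_local_seed(substream_seed(config$seed, "validation"),
                                 sample.int(n, n_val))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  X_val <- if (length(val_idx)) stack_images(images$image[val_idx])
  y_val <- y_all[val_idx]
  opt_state <- NULL
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_period)
    order <- with_local_seed(
      substream_seed(config$seed, paste0("shuffle", epoch)),
      sample(train_idx))
    batch_losses <- c()
    for (start in seq(1, length(order), by = config$batch_size)) {
      idx <- order[start:min(start + config$batch_size - 1, length(order))]
      Xb <- stack_images(images$image[idx])
      yb <- y_all[idx]
      fwd <- cnn_forward(model, Xb, training = TRUE)
      model$running <- fwd$running
      loss <- cross_entropy_loss(fwd$probs, yb) + l2_penalty(model)
      if (!is.finite(loss))
        stopf("midecoder_error_training",
              "non-finite loss at epoch %d; try a smaller learning rate",
              epoch)
      batch_losses <- c(batch_losses, loss)
      dlogits <- (fwd$probs - one_hot(yb)) / length(idx)
      grads <- cnn_backward(model, fwd$caches, dlogits)
      step <- if (config$optimizer == "sgdm") {
        sgdm_step(model$params, grads, opt_state, learning_rate = lr,
                  momentum = config$momentum)
      } else {
        adam_step(model$params, grads, opt_state, learning_rate = lr,
                  beta1 = config$beta1, beta2 = config$beta2,
                  epsilon = config$epsilon)
      }
      model$params <- step$params
      opt_state <- step$state
    }
    val_loss <- val_error <- NA_real_
    if (length(val_idx)) {
      pv <- cnn_forward(model, X_val, training = FALSE)$probs
      val_loss <- cross_entropy_loss(pv, y_val) + l2_penalty(model)
      val_error <- mean(max.col(pv) != y_val)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, learning_rate = lr,
      train_loss = mean(batch_losses), val_loss = val_loss,
      val_error = val_error)
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = config, n_train = length(train_idx),
                 n_val = length(val_idx)),
            class = "mi_cnn_fit")
}

#' @export
print.mi_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<mi_cnn_fit> %s/%s, %d epochs on %d images (%d monitored)\n",
    x$model$arch$variant, x$config$optimizer, x$config$epochs, x$n_train,
    x$n_val))
  cat(sprintf("  final train loss %.4f%s\n", last$train_loss,
              if (is.finite(last$val_error))
                sprintf(", validation error %.1f%%", 100 * last$val_error)
              else ""))
  invisible(x)
}

#' Predict class probabilities or labels for segment images
#'
#' @param object An `mi_cnn_fit`.
#' @param new_images A segment-image tibble (or list of image arrays).
#' @param type `"prob"` or `"class"`.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return For tibble input, the input with `p_left`, `p_right` and
#'   `pred` columns appended; otherwise a probability matrix or a factor.
#' @export
predict.mi_cnn_fit <- function(object, new_images, type = c("prob", "class"),
                               batch_size = 256, ...) {
  type <- match.arg(type)
  imgs <- if (is.data.frame(new_images)) new_images$image else new_images
  chunks <- split(seq_along(imgs), (seq_along(imgs) - 1) %/% batch_size)
  probs <- do.call(rbind, lapply(chunks, function(ix)
    forward_classify(object$model, imgs[ix])))
  pred <- factor(c("left", "right")[max.col(probs)],
                 levels = c("left", "right"))
  if (is.data.frame(new_images)) {
    out <- new_images
    out$p_left <- probs[, 1]
    out$p_right <- probs[, 2]
    out$pred <- pred
    return(out)
  }
  if (type == "prob") probs else pred
}

#' Decode every segment of a trial set with a fitted network
#'
#' Produces the per-trial 11-slot prediction grid used by the
#' continuous-decoding metrics.
#'
#' @param fit An `mi_cnn_fit`.
#' @param images Segment-image tibble for the test trials.
#' @return A segment-prediction tibble: trial identifiers, `segment`,
#'   `time`, `truth`, `pred`, `p_left`, `p_right`.
#' @export
decode_trials <- function(fit, images) {
  out <- predict(fit, images)
  out$truth <- out$label
  dplyr::select(out, "subject", "session", "trial", "segment", "time",
                "truth", "pred", "p_left", "p_right")
}

#' @export
tidy.mi_cnn_fit <- function(x, ...) x$history

#' @export
glance.mi_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    variant = x$model$arch$variant, optimizer = x$config$optimizer,
    epochs = x$config$epochs, n_parameters = count_parameters(x$model$arch),
    n_train = x$n_train, n_val = x$n_val,
    final_train_loss = last$train_loss, final_val_loss = last$val_loss,
    final_val_error = last$val_error)
}

#' @export
autoplot.mi_cnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  h <- h[is.finite(h$loss), ]
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (cross-entropy + L2)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
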