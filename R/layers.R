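# Internal CNN engine. Batched activations are R arrays with dims
# (H, W, B, C); convolution is im2col (C++) + one BLAS GEMM per layer;
# batch norm and ReLU are vectorized over a (H*W*B) x C matrix view.

# Flatten architecture stages into a per-layer plan with resolved
# input/output geometry.
layer_plan <- function(arch) {
  h <- arch$input_shape[1]; w <- arch$input_shape[2]; c <- arch$input_shape[3]
  plan <- list()
  si <- 0
  for (stage in arch$stages) {
    si <- si + 1
    if (inherits(stage, "mega_block")) {
      for (r in seq_len(stage$repeats)) {
        nm <- sprintf("conv%d_%d", si, r)
        plan[[length(plan) + 1]] <- list(
          type = "conv", name = nm, kh = stage$block$kernel[1],
          kw = stage$block$kernel[2], cin = c, cout = stage$block$n_filters,
          l2 = stage$block$l2, h = h, w = w)
        plan[[length(plan) + 1]] <- list(
          type = "bn", name = sprintf("bn%d_%d", si, r),
          channels = stage$block$n_filters, eps = stage$block$bn_eps)
        plan[[length(plan) + 1]] <- list(type = "relu",
                                         name = sprintf("relu%d_%d", si, r))
        c <- stage$block$n_filters
      }
    } else {
      nm <- sprintf("%s%d", stage$type, si)
      plan[[length(plan) + 1]] <- list(type = stage$type, name = nm,
                                       k = stage$k, s = stage$s,
                                       h = h, w = w, channels = c)
      h <- pool_out_size(h, stage$k, stage$s)
      w <- pool_out_size(w, stage$k, stage$s)
    }
  }
  plan[[length(plan) + 1]] <- list(type = "fc", name = "fc",
                                   in_dim = h * w * c, h = h, w = w,
                                   channels = c, out_dim = arch$n_classes,
                                   l2 = if (length(arch$stages))
                                     arch$stages[[1]]$block$l2 else 0)
  plan
}

# Uniform fan-in initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in)).
init_tensor <- function(n, fan_in) {
  runif(n, -sqrt(6 / fan_in), sqrt(6 / fan_in))
}

init_cnn <- function(arch, seed = 1L) {
  plan <- layer_plan(arch)
  params <- list()
  running <- list()
  with_local_seed(substream_seed(seed, "init"), {
    for (ly in plan) {
      if (ly$type == "conv") {
        fan_in <- ly$kh * ly$kw * ly$cin
        params[[ly$name]] <- list(
          W = matrix(init_tensor(fan_in * ly$cout, fan_in), fan_in, ly$cout),
          b = numeric(ly$cout))
      } else if (ly$type == "bn") {
        params[[ly$name]] <- list(gamma = rep(1, ly$channels),
                                  beta = numeric(ly$channels))
        running[[ly$name]] <- list(mean = numeric(ly$channels),
                                   var = rep(1, ly$channels))
      } else if (ly$type == "fc") {
        params[[ly$name]] <- list(
          W = matrix(init_tensor(ly$in_dim * ly$out_dim, ly$in_dim),
                     ly$in_dim, ly$out_dim),
          b = numeric(ly$out_dim))
      }
    }
  })
  structure(list(arch = arch, plan = plan, params = params,
                 running = running), class = "mi_cnn")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

bn_cols <- function(x, channels) matrix(x, ncol = channels)

# Forward pass. Returns probs, logits, and (when keep_cache) everything
# the backward pass needs. Training mode uses batch statistics and
# updates running moments with momentum 0.9.
cnn_forward <- function(model, X, training = FALSE, keep_cache = training) {
  B <- dim(X)[3]
  caches <- if (keep_cache) vector("list", length(model$plan))
  for (li in seq_along(model$plan)) {
    ly <- model$plan[[li]]
    p <- model$params[[ly$name]]
    if (ly$type == "conv") {
      cols <- im2col_same(X, ly$h, ly$w, B, ly$cin, ly$kh, ly$kw)
      out <- cols %*% p$W
      add_bias_inplace(out, p$b)
      dim(out) <- c(ly$h, ly$w, B, ly$cout)
      X <- out
      if (keep_cache) caches[[li]] <- list(cols = cols)
    } else if (ly$type == "bn") {
      d <- dim(X); C <- d[4]
      run <- model$running[[ly$name]]
      bn <- bn_fwd(X, C, p$gamma, p$beta, run$mean, run$var, ly$eps,
                   training)
      if (training) {
        model$running[[ly$name]]$mean <- 0.9 * run$mean + 0.1 * bn$mu
        model$running[[ly$name]]$var <- 0.9 * run$var + 0.1 * bn$var
      }
      if (keep_cache)
        caches[[li]] <- list(xhat = bn$xhat, istd = bn$istd)
      X <- bn$out
      dim(X) <- d
    } else if (ly$type == "relu") {
      d <- dim(X)
      X <- relu_fwd(X)
      dim(X) <- d
      if (keep_cache) caches[[li]] <- list(out = X)
    } else if (ly$type == "maxpool") {
      mp <- maxpool_fwd(X, ly$h, ly$w, B, ly$channels, ly$k, ly$s)
      if (keep_cache)
        caches[[li]] <- list(argmax = mp$argmax, n_in = length(X))
      X <- mp$out
    } else if (ly$type == "avgpool") {
      if (keep_cache) caches[[li]] <- list(dims = dim(X))
      X <- avgpool_fwd(X, ly$h, ly$w, B, ly$channels, ly$k, ly$s)
    } else if (ly$type == "fc") {
      Xf <- t(matrix(aperm(X, c(1, 2, 4, 3)), ncol = B))
      logits <- sweep(Xf %*% p$W, 2, p$b, "+")
      if (keep_cache) caches[[li]] <- list(Xf = Xf, in_dims = dim(X))
    }
  }
  list(probs = softmax_rows(logits), logits = logits, caches = caches,
       running = model$running)
}

# Backward pass from dlogits (B x K). Returns gradients with the same
# nested structure as model$params; L2 (weight decay) is added to conv
# and FC kernel gradients only.
cnn_backward <- function(model, caches, dlogits) {
  grads <- list()
  dX <- NULL
  for (li in rev(seq_along(model$plan))) {
    ly <- model$plan[[li]]
    p <- model$params[[ly$name]]
    cache <- caches[[li]]
    if (ly$type == "fc") {
      grads[[ly$name]] <- list(W = crossprod(cache$Xf, dlogits) + ly$l2 * p$W,
                               b = colSums(dlogits))
      dXf <- dlogits %*% t(p$W)  # B x D
      d <- cache$in_dims
      dX <- aperm(array(t(dXf), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else if (ly$type == "avgpool") {
      d <- cache$dims
      dX <- avgpool_bwd(dX, d[1], d[2], d[3], d[4], ly$k, ly$s)
      dim(dX) <- d
    } else if (ly$type == "maxpool") {
      d <- c(ly$h, ly$w, dim(dX)[3], ly$channels)
      dX <- maxpool_bwd(dX, cache$argmax, cache$n_in)
      dim(dX) <- d
    } else if (ly$type == "relu") {
      dX <- dX * (cache$out > 0)
    } else if (ly$type == "bn") {
      d <- dim(dX); C <- d[4]
      bn <- bn_bwd(dX, cache$xhat, cache$istd, p$gamma, C)
      grads[[ly$name]] <- list(gamma = bn$dgamma, beta = bn$dbeta)
      dX <- bn$dx
      dim(dX) <- d
    } else if (ly$type == "conv") {
      B <- dim(dX)[3]
      dim(dX) <- c(length(dX) / ly$cout, ly$cout)
      grads[[ly$name]] <- list(W = crossprod(cache$cols, dX) + ly$l2 * p$W,
                               b = colSums(dX))
      dX <- col2im_same(dX %*% t(p$W), ly$h, ly$w, B, ly$cin, ly$kh, ly$kw)
      dim(dX) <- c(ly$h, ly$w, B, ly$cin)
    }
  }
  grads[names(model$params)]
}

# Sum of squared conv/FC kernel weights (the quantity weight decay
# penalizes); used to report the full regularized training loss.
l2_penalty <- function(model) {
  total <- 0
  for (ly in model$plan)
    if (ly$type %in% c("conv", "fc"))
      total <- total + ly$l2 * sum(model$params[[ly$name]]$W^2)
  total / 2
}

# Stack a list of (H, W, C) image arrays into the engine's (H, W, B, C)
# batch layout.
stack_images <- function(images) {
  d <- dim(images[[1]])
  arr <- array(unlist(images, use.names = FALSE), c(d[1], d[2], d[3],
                                                    length(images)))
  aperm(arr, c(1, 2, 4, 3))
}

#' Class probabilities for a batch of spectrogram images
#'
#' Runs a (trained or freshly initialized) network forward in inference
#' mode. Probabilities are softmax outputs and sum to 1 per image.
#'
#' @param model An `mi_cnn` (from [fit_cnn()]'s `$model` or internal
#'   initialization).
#' @param images A list of 40 x 32 x 3 arrays, a single such array, or a
#'   4-D `(H, W, B, C)` batch array.
#' @return An N x 2 matrix of probabilities with columns `left`, `right`.
#' @export
forward_classify <- function(model, images) {
  if (is.list(images)) images <- stack_images(images)
  if (length(dim(images)) == 3)
    images <- stack_images(list(images))
  expect <- model$arch$input_shape
  d <- dim(images)
  if (d[1] != expect[1] || d[2] != expect[2] || d[4] != expect[3])
    stopf("midecoder_error_shape", "images are %s, architecture expects %s",
          paste(d[c(1, 2, 4)], collapse = "x"),
          paste(expect, collapse = "x"))
  probs <- cnn_forward(model, images, training = FALSE)$probs
  colnames(probs) <- c("left", "right")
  probs
}
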