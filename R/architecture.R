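#' Convolution block specification
#'
#' One convolution block is a same-padded stride-1 2-D convolution,
#' batch normalization (epsilon 1e-5) and a ReLU. Blocks are the unit a
#' Mega Block repeats.
#'
#' @param n_filters Number of filters (output channels).
#' @param kernel Kernel size `c(h, w)` with odd dimensions.
#' @param l2 Weight-decay coefficient applied to the kernel weights.
#' @param bn_eps Batch-normalization variance offset.
#' @return A `conv_block_spec` object.
#' @export
conv_block_spec <- function(n_filters, kernel = c(3, 3), l2 = 0,
                            bn_eps = 1e-5) {
  if (n_filters < 1)
    stopf("midecoder_error_arch", "n_filters must be >= 1")
  if (any(kernel %% 2 != 1))
    stopf("midecoder_error_arch", "kernel dimensions must be odd, got %s",
          paste(kernel, collapse = "x"))
  structure(list(n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel), stride = c(1L, 1L),
                 l2 = l2, activation = "relu", bn_eps = bn_eps),
            class = "conv_block_spec")
}

#' Mega Block: a convolution block repeated 1--5 times
#'
#' A Mega Block stacks `repeats` copies of the same convolution block
#' (identical filter count, kernel, activation and regularization). The
#' repeat count is the architecture's capacity dial and is what Bayesian
#' optimization tunes per subject; it never changes the spatial output
#' size, only the depth.
#'
#' @param block A [conv_block_spec()].
#' @param repeats Integer in 1..5.
#' @return A `mega_block` object.
#' @export
mega_block <- function(block, repeats = 1) {
  if (repeats < 1 || repeats > 5 || repeats != round(repeats))
    stopf("midecoder_error_arch", "repeats must be an integer in 1..5, got %s",
          format(repeats))
  structure(list(block = block, repeats = as.integer(repeats)),
            class = "mega_block")
}

#' Build a decoding CNN architecture
#'
#' Two variants over 40 x 32 x 3 spectrogram images:
#' * `"arch1"` (intra-subject): conv16(3x3) -> maxpool -> conv32(3x3) ->
#'   maxpool -> conv64(3x3) -> avgpool(8x8, stride 1) -> FC -> softmax(2),
#'   each conv followed by batch norm + ReLU, L2 0.0014 on kernels.
#' * `"arch2"` (inter-subject transfer): three Mega Blocks of 9 (5x5),
#'   18 (3x3) and 36 (3x3) filters with per-block repeat counts 1..5,
#'   max pooling (3x3, stride 2, ceil mode) after the first two blocks,
#'   then avgpool(8x8) -> FC -> softmax(2).
#'
#' Convolutions are same-padded and pooling uses ceil-mode output sizes,
#' which makes the flattened feature size entering the dense layer 192
#' for arch1 and 108 for arch2 regardless of repeat counts.
#'
#' @param variant `"arch1"` or `"arch2"`.
#' @param repeats Length-3 integer vector of Mega Block repeats (arch2).
#' @param l2 Weight-decay coefficient for conv/FC kernels.
#' @param input_shape Image dimensions `c(height, width, channels)`.
#' @return An `mi_architecture` object.
#' @export
build_architecture <- function(variant = c("arch1", "arch2"),
                               repeats = c(1, 1, 1), l2 = 0.0014,
                               input_shape = c(40, 32, 3)) {
  variant <- match.arg(variant)
  if (variant == "arch1") {
    stages <- list(
      mega_block(conv_block_spec(16, c(3, 3), l2), 1),
      list(type = "maxpool", k = 3L, s = 2L),
      mega_block(conv_block_spec(32, c(3, 3), l2), 1),
      list(type = "maxpool", k = 3L, s = 2L),
      mega_block(conv_block_spec(64, c(3, 3), l2), 1),
      list(type = "avgpool", k = 8L, s = 1L))
  } else {
    if (length(repeats) != 3)
      stopf("midecoder_error_arch", "arch2 needs 3 repeat counts")
    stages <- list(
      mega_block(conv_block_spec(9, c(5, 5), l2), repeats[1]),
      list(type = "maxpool", k = 3L, s = 2L),
      mega_block(conv_block_spec(18, c(3, 3), l2), repeats[2]),
      list(type = "maxpool", k = 3L, s = 2L),
      mega_block(conv_block_spec(36, c(3, 3), l2), repeats[3]),
      list(type = "avgpool", k = 8L, s = 1L))
  }
  arch <- structure(list(variant = variant, input_shape = input_shape,
                         stages = stages, n_classes = 2L,
                         loss = "cross-entropy"),
                    class = "mi_architecture")
  shape_trace(arch)  # validates every layer output dimension
  arch
}

pool_out_size <- function(n, k, s) as.integer(ceiling((n - k) / s) + 1)

#' Trace layer output shapes through an architecture
#'
#' Same-padded stride-1 convolutions keep the spatial size; pooling uses
#' ceil-mode sizing `ceiling((n - k)/s) + 1`. The final row gives the
#' flattened size entering the fully connected layer (192 for arch1, 108
#' for arch2 on 40 x 32 x 3 inputs).
#'
#' @param arch An [build_architecture()] result.
#' @return A tibble with columns `layer`, `type`, `height`, `width`,
#'   `channels` and `flat` (= height * width * channels).
#' @export
shape_trace <- function(arch) {
  h <- arch$input_shape[1]; w <- arch$input_shape[2]; c <- arch$input_shape[3]
  rows <- list(tibble::tibble(layer = "input", type = "input",
                              height = h, width = w, channels = c))
  si <- 0
  for (stage in arch$stages) {
    si <- si + 1
    if (inherits(stage, "mega_block")) {
      for (r in seq_len(stage$repeats)) {
        name <- sprintf("conv%d_%d", si, r)
        if (h < 1 || w < 1)
          stopf("midecoder_error_shape", "layer %s input collapsed to %dx%d",
                name, h, w)
        c <- stage$block$n_filters
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = name, type = "conv-bn-relu", height = h, width = w,
          channels = c)
      }
    } else {
      name <- sprintf("%s%d", stage$type, si)
      h2 <- pool_out_size(h, stage$k, stage$s)
      w2 <- pool_out_size(w, stage$k, stage$s)
      if (h2 < 1 || w2 < 1)
        stopf("midecoder_error_shape", "layer %s output %dx%d is degenerate",
              name, h2, w2)
      h <- h2; w <- w2
      rows[[length(rows) + 1]] <- tibble::tibble(
        layer = name, type = stage$type, height = h, width = w, channels = c)
    }
  }
  flat <- h * w * c
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "flatten", type = "flatten", height = 1L, width = 1L,
    channels = flat)
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "fc", type = "fully-connected", height = 1L, width = 1L,
    channels = arch$n_classes)
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "softmax", type = "softmax", height = 1L, width = 1L,
    channels = arch$n_classes)
  out <- dplyr::bind_rows(rows)
  out$flat <- out$height * out$width * out$channels
  out
}

#' Per-layer trainable-parameter audit
#'
#' Counts convolution kernels and biases, batch-norm scale/offset pairs
#' and fully-connected weights and biases. The counting convention (all
#' trainable tensors, biases and batch-norm parameters included) is
#' deliberate and documented; see the methods vignette for the audit of
#' alternative conventions.
#'
#' @param arch An [build_architecture()] result.
#' @return A tibble with columns `layer`, `type`, and `n_params`.
#' @export
parameter_audit <- function(arch) {
  trace <- shape_trace(arch)
  c_in <- arch$input_shape[3]
  rows <- list()
  si <- 0
  for (stage in arch$stages) {
    si <- si + 1
    if (inherits(stage, "mega_block")) {
      for (r in seq_len(stage$repeats)) {
        f <- stage$block$n_filters
        kh <- stage$block$kernel[1]; kw <- stage$block$kernel[2]
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = sprintf("conv%d_%d", si, r), type = "conv",
          n_params = kh * kw * c_in * f + f)
        rows[[length(rows) + 1]] <- tibble::tibble(
          layer = sprintf("bn%d_%d", si, r), type = "batch-norm",
          n_params = 2L * f)
        c_in <- f
      }
    }
  }
  flat <- trace$flat[trace$layer == "flatten"]
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "fc", type = "fully-connected",
    n_params = flat * arch$n_classes + arch$n_classes)
  dplyr::bind_rows(rows)
}

#' Total trainable parameter count
#'
#' @param arch An [build_architecture()] result.
#' @return Integer: the sum of the [parameter_audit()] table.
#' @export
count_parameters <- function(arch) {
  as.integer(sum(parameter_audit(arch)$n_params))
}

#' @export
print.mi_architecture <- function(x, ...) {
  cat(sprintf("<mi_architecture %s> input %s, %d classes, %d parameters\n",
              x$variant, paste(x$input_shape, collapse = "x"), x$n_classes,
              count_parameters(x)))
  reps <- vapply(x$stages, function(s)
    if (inherits(s, "mega_block")) s$repeats else NA_integer_, integer(1))
  cat(sprintf("  Mega Block repeats: %s\n",
              paste(reps[!is.na(reps)], collapse = ", ")))
  invisible(x)
}
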