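# Helper: hand-built architecture objects for toy checks (same structure
# build_architecture() emits, but with custom stages).
toy_arch <- function(stages, input_shape = c(8, 8, 1)) {
  structure(list(variant = "toy", input_shape = input_shape, stages = stages,
                 n_classes = 2L, loss = "cross-entropy"),
            class = "mi_architecture")
}

test_that("Mega Block repeat counts control depth but not output shape", {
  tr1 <- shape_trace(build_architecture("arch2", c(1, 1, 1)))
  expect_equal(sum(tr1$type == "conv-bn-relu"), 3)
  tr5 <- shape_trace(build_architecture("arch2", c(5, 5, 5)))
  expect_equal(sum(tr5$type == "conv-bn-relu"), 15)
  expect_error(build_architecture("arch2", c(0, 1, 1)),
               class = "midecoder_error_arch")
  expect_error(build_architecture("arch2", c(1, 6, 1)),
               class = "midecoder_error_arch")
  expect_error(build_architecture("arch2", c(2, 2)),
               class = "midecoder_error_arch")

  # flatten size is repeat-invariant
  for (r in list(c(1, 1, 1), c(2, 3, 4), c(5, 5, 5)))
    expect_equal(shape_trace(build_architecture("arch2", r)) |>
                   dplyr::filter(layer == "flatten") |> dplyr::pull(flat),
                 108)
})

test_that("shape tracing reproduces the printed dense-layer sizes", {
  tr1 <- shape_trace(build_architecture("arch1"))
  expect_equal(tr1$flat[tr1$layer == "flatten"], 192)
  # ceil-mode pooling: 40x32 -> 20x16 -> 10x8
  mp <- tr1[tr1$type == "maxpool", ]
  expect_equal(mp$height, c(20, 10))
  expect_equal(mp$width, c(16, 8))
  # final average pooling leaves 3x1 maps
  ap <- tr1[tr1$type == "avgpool", ]
  expect_equal(c(ap$height, ap$width), c(3, 1))

  tr2 <- shape_trace(build_architecture("arch2", c(3, 3, 3)))
  expect_equal(tr2$flat[tr2$layer == "flatten"], 108)

  degenerate <- toy_arch(list(
    mega_block(conv_block_spec(4, c(3, 3)), 1),
    list(type = "avgpool", k = 8L, s = 1L)), input_shape = c(4, 4, 1))
  err <- expect_error(shape_trace(degenerate),
                      class = "midecoder_error_shape")
  expect_match(conditionMessage(err), "avgpool")
})

test_that("parameter audit counts each trainable tensor", {
  # one 3x3 conv, 3 -> 2 filters, with bias: 3*3*3*2 + 2 = 56
  a <- toy_arch(list(mega_block(conv_block_spec(2, c(3, 3)), 1),
                     list(type = "avgpool", k = 8L, s = 1L)),
                input_shape = c(8, 8, 3))
  audit <- parameter_audit(a)
  expect_equal(audit$n_params[audit$type == "conv"], 56)
  expect_equal(count_parameters(a), sum(audit$n_params))

  # monotone in repeats
  counts <- vapply(1:5, function(r)
    count_parameters(build_architecture("arch2", c(r, r, r))), integer(1))
  expect_true(all(diff(counts) > 0))

  expect_equal(count_parameters(build_architecture("arch1")),
               sum(parameter_audit(build_architecture("arch1"))$n_params))
})

test_that("softmax outputs are normalized and a zeroed head is uniform", {
  arch <- build_architecture("arch2", c(1, 1, 1))
  model <- midecoder:::init_cnn(arch, seed = 3)
  imgs <- lapply(1:4, function(i) array(runif(40 * 32 * 3), c(40, 32, 3)))
  probs <- forward_classify(model, imgs)
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-9)
  expect_true(all(probs >= 0))

  model$params$fc$W[] <- 0
  model$params$fc$b[] <- 0
  probs0 <- forward_classify(model, imgs)
  expect_equal(as.vector(probs0), rep(0.5, 8))

  bad <- lapply(1:2, function(i) array(0, c(20, 32, 3)))
  expect_error(forward_classify(model, bad), class = "midecoder_error_shape")
})

test_that("a 1x1-conv toy network matches a hand-evaluated forward pass", {
  a <- toy_arch(list(mega_block(conv_block_spec(1, c(1, 1)), 1),
                     list(type = "avgpool", k = 8L, s = 1L)),
                input_shape = c(8, 8, 1))
  model <- midecoder:::init_cnn(a, seed = 1)
  w0 <- 1.5; b0 <- -0.2
  model$params$conv1_1$W[] <- w0
  model$params$conv1_1$b[] <- b0
  model$params$bn1_1$gamma[] <- 1
  model$params$bn1_1$beta[] <- 0     # inference: running mean 0, var 1
  model$params$fc$W[] <- c(2, -1)
  model$params$fc$b[] <- c(0.1, 0.3)

  set.seed(4)
  x <- array(runif(8 * 8), c(8, 8, 1))
  got <- forward_classify(model, list(x))[1, ]

  # hand computation: conv, normalize by sqrt(1 + 1e-5), relu, mean,
  # dense layer, softmax — plain scalar arithmetic throughout
  h <- (w0 * x + b0) / sqrt(1 + 1e-5)
  h[h < 0] <- 0
  feat <- mean(h)
  z <- c(2 * feat + 0.1, -1 * feat + 0.3)
  want <- exp(z) / sum(exp(z))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences on a small block", {
  arch <- build_architecture("arch2", c(1, 1, 1), l2 = 0)
  model <- midecoder:::init_cnn(arch, 7)
  set.seed(42)
  X <- midecoder:::stack_images(list(array(rnorm(40 * 32 * 3), c(40, 32, 3)),
                                     array(rnorm(40 * 32 * 3), c(40, 32, 3))))
  y <- c(1L, 2L)
  loss_fn <- function(m)
    cross_entropy_loss(midecoder:::cnn_forward(m, X, training = TRUE)$probs, y)
  fwd <- midecoder:::cnn_forward(model, X, training = TRUE)
  grads <- midecoder:::cnn_backward(model, fwd$caches,
                                    (fwd$probs - midecoder:::one_hot(y)) / 2)
  eps <- 1e-6
  for (nm in c("conv1_1", "bn2_1", "fc")) {
    for (fld in names(model$params[[nm]])) {
      v <- model$params[[nm]][[fld]]
      k <- sample(length(v), 2)
      for (ki in k) {
        up <- model; up$params[[nm]][[fld]][ki] <- v[ki] + eps
        dn <- model; dn$params[[nm]][[fld]][ki] <- v[ki] - eps
        fd <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
        an <- grads[[nm]][[fld]][ki]
        # scaled difference guards against finite-difference noise at
        # near-zero gradients
        expect_lt(abs(fd - an) / max(1e-3, abs(fd) + abs(an)), 1e-4)
      }
    }
  }
})
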