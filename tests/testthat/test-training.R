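test_that("cross-entropy has its closed-form values and guards input", {
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(cross_entropy_loss(perfect, c(1L, 2L)), 0)

  uniform <- matrix(0.5, 3, 2)
  expect_equal(cross_entropy_loss(uniform, c(1L, 2L, 1L)), log(2))

  # hand-computed 3-sample batch
  p <- matrix(c(0.9, 0.1,
                0.3, 0.7,
                0.6, 0.4), 3, byrow = TRUE)
  y <- c(1L, 2L, 2L)
  want <- -(log(0.9) + log(0.7) + log(0.4)) / 3
  expect_equal(cross_entropy_loss(p, y), want, tolerance = 1e-15)

  expect_error(cross_entropy_loss(matrix(c(0.9, 0.1), 1), diag(2)),
               class = "midecoder_error_shape")
  expect_error(cross_entropy_loss(matrix(c(0.7, 0.7), 1), c(1L)),
               class = "midecoder_error_loss")
})

test_that("SGDM performs the exact two-line heavy-ball update", {
  # mu = 0 reduces to plain gradient descent
  s <- sgdm_step(1, 2, learning_rate = 0.1, momentum = 0)
  expect_equal(s$params, 1 - 0.1 * 2)

  # hand iteration: theta0=1, g=2, eta=0.1, mu=0.5
  # v1 = -0.2,  theta1 = 0.8;  v2 = 0.5*(-0.2) - 0.2 = -0.3, theta2 = 0.5
  s1 <- sgdm_step(1, 2, learning_rate = 0.1, momentum = 0.5)
  expect_equal(s1$params, 0.8, tolerance = 1e-15)
  expect_equal(s1$state$velocity, -0.2, tolerance = 1e-15)
  s2 <- sgdm_step(s1$params, 2, s1$state, learning_rate = 0.1, momentum = 0.5)
  expect_equal(s2$params, 0.5, tolerance = 1e-15)
  expect_equal(s2$state$velocity, -0.3, tolerance = 1e-15)

  # with zero gradient the velocity decays geometrically by mu
  s3 <- sgdm_step(s2$params, 0, s2$state, learning_rate = 0.1, momentum = 0.5)
  expect_equal(s3$state$velocity, -0.15, tolerance = 1e-15)
  s4 <- sgdm_step(s3$params, 0, s3$state, learning_rate = 0.1, momentum = 0.5)
  expect_equal(s4$state$velocity, -0.075, tolerance = 1e-15)

  expect_error(sgdm_step(1:2, 1:3), class = "midecoder_error_shape")
  expect_error(sgdm_step(1, 1, momentum = 1), class = "midecoder_error_config")
})

test_that("Adam matches its closed forms", {
  # first step magnitude: eta * |g| / (|g| + eps), approximately eta
  eta <- 0.01
  s <- adam_step(0, 3, learning_rate = eta)
  expect_equal(abs(s$params), eta * 3 / (3 + 1e-8), tolerance = 1e-12)
  expect_equal(abs(s$params), eta, tolerance = 1e-6)

  # zero gradients leave parameters untouched
  s0 <- adam_step(5, 0, learning_rate = eta)
  expect_equal(s0$params, 5)

  # three steps minimizing theta^2/2 (g = theta) against an explicit
  # scalar transcription of the moment updates
  theta_ref <- 1; m <- 0; v <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  refs <- numeric(3)
  for (t in 1:3) {
    g <- theta_ref
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    theta_ref <- theta_ref - eta * mh / (sqrt(vh) + eps)
    refs[t] <- theta_ref
  }
  theta <- 1; st <- NULL
  for (t in 1:3) {
    out <- adam_step(theta, theta, st, learning_rate = eta)
    theta <- out$params; st <- out$state
    expect_equal(theta, refs[t], tolerance = 1e-14)
  }
})

test_that("optimizers traverse nested parameter lists", {
  params <- list(a = matrix(1:4 / 4, 2), b = list(c = c(1, 2)))
  grads <- list(a = matrix(1, 2, 2), b = list(c = c(0.5, -0.5)))
  s <- sgdm_step(params, grads, learning_rate = 0.1, momentum = 0)
  expect_equal(s$params$a, params$a - 0.1)
  expect_equal(s$params$b$c, c(1, 2) - 0.1 * c(0.5, -0.5))
  a <- adam_step(params, grads, learning_rate = 0.1)
  expect_equal(dim(a$params$a), c(2, 2))
})

test_that("training is deterministic and learns a separable toy problem", {
  imgs <- toy_image_table(24, seed = 2)
  cfg <- train_config("adam", epochs = 5, batch_size = 8,
                      learning_rate = 1e-3, l2 = 0, validation_size = 0,
                      seed = 3)
  f1 <- fit_cnn(imgs, build_architecture("arch1"), cfg)
  f2 <- fit_cnn(imgs, build_architecture("arch1"), cfg)
  expect_identical(f1$history, f2$history)

  expect_true(all(diff(f1$history$train_loss) < 0))
  pred <- predict(f1, imgs)
  expect_equal(mean(pred$pred == pred$label), 1)
  expect_identical(predict(f1, imgs)$p_left, pred$p_left)
})

test_that("the learning-rate schedule drops at period boundaries", {
  imgs <- toy_image_table(8, seed = 4)
  cfg <- train_config("sgdm", epochs = 6, batch_size = 4,
                      learning_rate = 0.01, momentum = 0.5,
                      lr_drop_factor = 0.5, lr_drop_period = 2, l2 = 0,
                      validation_size = 0, seed = 5)
  f <- fit_cnn(imgs, build_architecture("arch2", c(1, 1, 1)), cfg)
  expect_equal(f$history$learning_rate,
               0.01 * c(1, 1, 0.5, 0.5, 0.25, 0.25))
  expect_equal(nrow(f$history), 6)
})

test_that("validation monitoring records losses without stopping training", {
  imgs <- toy_image_table(40, seed = 6)
  cfg <- train_config("adam", epochs = 3, batch_size = 16,
                      learning_rate = 1e-3, l2 = 1e-4,
                      validation_size = 8, seed = 7)
  f <- fit_cnn(imgs, build_architecture("arch2", c(1, 1, 1)), cfg)
  expect_equal(f$n_val, 8)
  expect_equal(f$n_train, 32)
  expect_true(all(is.finite(f$history$val_loss)))
  expect_true(all(f$history$val_error >= 0 & f$history$val_error <= 1))
  g <- glance(f)
  expect_equal(g$n_parameters, count_parameters(build_architecture("arch2", c(1, 1, 1))))
  expect_s3_class(tidy(f), "tbl_df")
})

test_that("a decoder trained on synthetic ERD recovers the class structure", {
  trials <- generate_dataset(1, 8, 5, synth_config(erd_depth = 0.7,
                                                   subject_shift_sd = 0,
                                                   seed = 41))
  sp <- split_intra_subject(trials, "S01")
  train <- trials_to_images(sp$train)
  test <- trials_to_images(sp$test)
  cfg <- train_config("adam", epochs = 5, batch_size = 32,
                      learning_rate = 1e-3, l2 = 1e-4, validation_size = 0,
                      seed = 8)
  f <- fit_cnn(train, build_architecture("arch2", c(1, 1, 1)), cfg)
  pred <- predict(f, test)
  acc <- mean(pred$pred == pred$label)
  n <- nrow(test)
  chance_99 <- qbinom(0.99, n, 0.5) / n
  expect_gt(acc, chance_99)
})
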