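#' Mean cross-entropy loss
#'
#' `-(1/N) * sum_ij t_ij * log(y_ij)` for predicted class probabilities
#' `y` and one-hot targets `t`. Zero exactly when every prediction puts
#' all mass on the true class; `log(2)` per sample for uniform two-class
#' predictions.
#'
#' @param predicted N x K matrix of probabilities (rows sum to 1).
#' @param targets N x K one-hot matrix (or a vector of 1-based class
#'   indices, which is expanded internally).
#' @param tolerance Allowed deviation of row sums from 1.
#' @return Non-negative scalar, the mean loss per sample.
#' @export
cross_entropy_loss <- function(predicted, targets, tolerance = 1e-6) {
  predicted <- rbind(predicted)
  if (is.vector(targets) && !is.matrix(targets)) {
    onehot <- matrix(0, nrow(predicted), ncol(predicted))
    onehot[cbind(seq_len(nrow(predicted)), targets)] <- 1
    targets <- onehot
  }
  if (!all(dim(predicted) == dim(targets)))
    stopf("midecoder_error_shape", "predictions %s and targets %s differ",
          paste(dim(predicted), collapse = "x"),
          paste(dim(targets), collapse = "x"))
  sums <- rowSums(predicted)
  if (any(abs(sums - 1) > tolerance))
    stopf("midecoder_error_loss",
          "prediction rows must sum to 1 (max deviation %.3g)",
          max(abs(sums - 1)))
  -sum(targets * log(pmax(predicted, 1e-300))) / nrow(predicted)
}

map_pair <- function(a, b, f) {
  if (is.list(a)) purrr::map2(a, b, map_pair, f = f) else f(a, b)
}

check_shapes <- function(params, grads) {
  ok <- if (is.list(params)) {
    is.list(grads) && length(params) == length(grads) &&
      all(purrr::map2_lgl(params, grads, function(p, g)
        isTRUE(all.equal(dim(p) %??% length(p), dim(g) %??% length(g)))))
  } else {
    !is.list(grads) &&
      isTRUE(all.equal(dim(params) %??% length(params),
                       dim(grads) %??% length(grads)))
  }
  if (!ok) stopf("midecoder_error_shape", "parameter/gradient shapes differ")
}

zeros_like <- function(x) if (is.list(x)) lapply(x, zeros_like) else x * 0

#' One step of stochastic gradient descent with momentum
#'
#' The classical two-line heavy-ball update:
#' `v <- momentum * v - learning_rate * g` then `theta <- theta + v`
#' (no dampening, no Nesterov look-ahead). With `momentum = 0` it reduces
#' to plain SGD `theta - learning_rate * g`.
#'
#' @param params Numeric vector/array, or a (nested) list of them.
#' @param grads Gradients with the same structure as `params`.
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   with zero velocity.
#' @param learning_rate Step size eta > 0.
#' @param momentum Momentum coefficient mu in `[0, 1)`.
#' @return A list with updated `params` and `state` (`state$velocity`).
#' @export
sgdm_step <- function(params, grads, state = NULL, learning_rate = 6.7929e-4,
                      momentum = 0.9799) {
  if (momentum < 0 || momentum >= 1)
    stopf("midecoder_error_config", "momentum must be in [0, 1)")
  check_shapes(params, grads)
  if (is.null(state)) state <- list(velocity = zeros_like(params))
  v <- map_pair(state$velocity, grads,
                function(v, g) momentum * v - learning_rate * g)
  list(params = map_pair(params, v, `+`), state = list(velocity = v))
}

#' One step of the Adam optimizer
#'
#' Exponential moving averages of the gradient and its square,
#' `m <- beta1*m + (1-beta1)*g` and `v <- beta2*v + (1-beta2)*g^2`, with
#' bias correction `m_hat = m/(1-beta1^t)`, `v_hat = v/(1-beta2^t)` and
#' update `theta <- theta - learning_rate * m_hat/(sqrt(v_hat) + epsilon)`
#' (epsilon added outside the square root).
#'
#' @inheritParams sgdm_step
#' @param beta1,beta2 Moment decay rates.
#' @param epsilon Numerical floor in the denominator.
#' @return A list with updated `params` and `state` (`m`, `v`, `t`).
#' @export
adam_step <- function(params, grads, state = NULL, learning_rate = 0.001,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  check_shapes(params, grads)
  if (is.null(state))
    state <- list(m = zeros_like(params), v = zeros_like(params), t = 0L)
  t <- state$t + 1L
  m <- map_pair(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  v <- map_pair(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  delta <- map_pair(m, v, function(m, v)
    learning_rate * (m / c1) / (sqrt(v / c2) + epsilon))
  list(params = map_pair(params, delta, `-`),
       state = list(m = m, v = v, t = t))
}
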