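# Gaussian-process Bayesian optimization of training/architecture
# hyperparameters. The GP uses a Matern 5/2 kernel on inputs scaled to
# the unit cube (log scale for rate-like axes); the acquisition is
# maximized by seeded random multi-start over >= 1000 candidate points.

#' Hyperparameter search space
#'
#' The default space mirrors the decoder's tuning problem: number of
#' convolution blocks per Mega Block (integer 1..5, one shared value for
#' all three blocks), learning rate (log-uniform 1e-6..1e-2), SGDM
#' momentum (0.6..0.98), and L2 regularization (log-uniform 1e-10..1e-2),
#' with a budget of 30 objective evaluations.
#'
#' @param ... Named parameter definitions created by [param_integer()],
#'   [param_uniform()] or [param_log_uniform()]; omit to get the default
#'   space.
#' @param budget Total number of objective evaluations.
#' @return A `search_space` object.
#' @export
search_space <- function(..., budget = 30) {
  params <- list(...)
  if (!length(params))
    params <- list(n_conv_layers = param_integer(1, 5),
                   learning_rate = param_log_uniform(1e-6, 1e-2),
                   momentum = param_uniform(0.6, 0.98),
                   l2 = param_log_uniform(1e-10, 1e-2))
  if (is.null(names(params)) || any(names(params) == ""))
    stopf("midecoder_error_config", "search-space parameters must be named")
  structure(list(params = params, budget = as.integer(budget)),
            class = "search_space")
}

#' @rdname search_space
#' @param lower,upper Bounds (inclusive).
#' @export
param_integer <- function(lower, upper)
  list(type = "integer", lower = lower, upper = upper)

#' @rdname search_space
#' @export
param_uniform <- function(lower, upper)
  list(type = "uniform", lower = lower, upper = upper)

#' @rdname search_space
#' @export
param_log_uniform <- function(lower, upper)
  list(type = "log_uniform", lower = lower, upper = upper)

# Map a unit-cube row to named parameter values. Integers round half up.
decode_point <- function(u, space) {
  vals <- purrr::imap(space$params, function(p, nm) {
    x <- switch(p$type,
      integer = floor(p$lower + u[[nm]] * (p$upper - p$lower) + 0.5),
      uniform = p$lower + u[[nm]] * (p$upper - p$lower),
      log_uniform = exp(log(p$lower) +
                          u[[nm]] * (log(p$upper) - log(p$lower))))
    min(max(x, p$lower), p$upper)
  })
  vals
}

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

scaled_dist <- function(X1, X2, lengthscales) {
  X1 <- sweep(X1, 2, lengthscales, "/")
  X2 <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  sqrt(pmax(d2, 0))
}

gp_neg_loglik <- function(log_par, X, y) {
  d <- ncol(X)
  ls <- exp(log_par[seq_len(d)])
  sf2 <- exp(log_par[d + 1])
  sn2 <- exp(log_par[d + 2])
  K <- sf2 * matern52(scaled_dist(X, X, ls)) + diag(sn2, nrow(X))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

#' Gaussian-process posterior over an objective
#'
#' Fits a zero-mean GP with Matern 5/2 covariance to observed
#' (point, value) pairs; values are internally standardized. Kernel
#' hyperparameters (per-dimension lengthscales, signal variance, noise
#' variance) are either supplied or estimated by maximizing the marginal
#' likelihood. A singular covariance is retried with growing jitter
#' before failing.
#'
#' @param X n x d matrix of observed input points.
#' @param y Length-n vector of observed objective values.
#' @param kernel_params Optional list with `lengthscales` (length d),
#'   `sigma_f2` and `sigma_n2`.
#' @return An `mi_gp` object; use [predict.mi_gp()] to query posterior
#'   mean and standard deviation anywhere.
#' @export
gp_posterior <- function(X, y, kernel_params = NULL) {
  X <- as.matrix(X)
  if (!nrow(X)) stopf("midecoder_error_config", "need >= 1 observation")
  y_mu <- mean(y)
  y_sd <- if (length(y) > 1 && sd(y) > 0) sd(y) else 1
  ys <- (y - y_mu) / y_sd
  d <- ncol(X)
  if (is.null(kernel_params)) {
    init <- c(rep(log(0.3), d), log(1), log(1e-4))
    est <- tryCatch(
      optim(init, gp_neg_loglik, X = X, y = ys, method = "L-BFGS-B",
            lower = c(rep(log(0.01), d), log(1e-3), log(1e-8)),
            upper = c(rep(log(10), d), log(100), log(1)))$par,
      error = function(e) init)
    kernel_params <- list(lengthscales = exp(est[seq_len(d)]),
                          sigma_f2 = exp(est[d + 1]),
                          sigma_n2 = exp(est[d + 2]))
  }
  kp <- kernel_params
  K <- kp$sigma_f2 * matern52(scaled_dist(X, X, kp$lengthscales))
  ch <- NULL
  jitter <- kp$sigma_n2
  for (i in 1:6) {
    ch <- tryCatch(chol(K + diag(jitter, nrow(X))), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- max(jitter * 10, 1e-10)
  }
  if (is.null(ch))
    stopf("midecoder_error_gp", "kernel matrix singular even after jitter")
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, y = y, y_mu = y_mu, y_sd = y_sd, kernel = kp,
                 chol = ch, alpha = alpha), class = "mi_gp")
}

#' Posterior mean and standard deviation of a fitted GP
#'
#' @param object An `mi_gp`.
#' @param newdata m x d matrix of query points.
#' @param ... Unused.
#' @return A tibble with columns `mean` and `sd` (on the original
#'   objective scale).
#' @export
predict.mi_gp <- function(object, newdata, ...) {
  Xq <- rbind(as.matrix(newdata))
  kp <- object$kernel
  Ks <- kp$sigma_f2 * matern52(scaled_dist(Xq, object$X, kp$lengthscales))
  mu <- as.vector(Ks %*% object$alpha)
  # predictive variance of the latent function
  var <- pmax(kp$sigma_f2 - colSums(forwardsolve(t(object$chol), t(Ks))^2), 0)
  tibble::tibble(mean = object$y_mu + object$y_sd * mu,
                 sd = object$y_sd * sqrt(var))
}

# Incumbent: the lowest posterior mean over the observed locations.
gp_incumbent <- function(gp) min(predict(gp, gp$X)$mean)

#' Expected-improvement acquisition
#'
#' For minimization, the Gaussian expectation of
#' `max(0, mu(x_b) - f(x))` where `x_b` is the observed location with the
#' lowest posterior mean: `EI = sd * (z * pnorm(z) + dnorm(z))` with
#' `z = (mu(x_b) - mu(x)) / sd(x)`. When the posterior is deterministic
#' (`sd = 0`) it degenerates to `max(0, mu(x_b) - mu(x))`.
#'
#' @param x Query point(s), vector or m x d matrix.
#' @param posterior An `mi_gp` from [gp_posterior()].
#' @return Non-negative EI value(s).
#' @export
acquisition_ei <- function(x, posterior) {
  p <- predict(posterior, x)
  best <- gp_incumbent(posterior)
  z <- ifelse(p$sd > 0, (best - p$mean) / p$sd, 0)
  ifelse(p$sd > 0,
         p$sd * (z * pnorm(z) + dnorm(z)),
         pmax(0, best - p$mean))
}

#' Probability-of-improvement acquisition
#'
#' `PI = pnorm((mu(x_best) - m - mu(x)) / sd(x))` with margin `m`
#' discounting improvements smaller than the noise scale. With `sd = 0`
#' the probability degenerates to a 0/1 step by the sign of the margin-
#' adjusted improvement.
#'
#' @inheritParams acquisition_ei
#' @param margin Non-negative margin `m`; defaults to the GP's estimated
#'   noise standard deviation.
#' @return Probability value(s) in `[0, 1]`.
#' @export
acquisition_pi <- function(x, posterior, margin = NULL) {
  margin <- margin %??% (posterior$y_sd * sqrt(posterior$kernel$sigma_n2))
  p <- predict(posterior, x)
  best <- gp_incumbent(posterior)
  ifelse(p$sd > 0,
         pnorm((best - margin - p$mean) / p$sd),
         as.numeric(p$mean < best - margin))
}

#' Bayesian hyperparameter optimization
#'
#' Minimizes a (possibly noisy) objective over a [search_space()] with a
#' fixed evaluation budget: a Latin-hypercube initial design, then one
#' GP-guided evaluation per round with the chosen acquisition maximized
#' over `n_candidates` random points plus local perturbations of the
#' best observed point. An objective that errors is recorded at the
#' worst value observed so far and optimization continues. The returned
#' best configuration is the argmin of the *observed* values.
#'
#' @param objective Function receiving a named list of parameter values
#'   and returning a scalar to minimize (e.g. validation error).
#' @param space A [search_space()].
#' @param acquisition `"ei"` or `"pi"`.
#' @param n_init Size of the initial Latin-hypercube design.
#' @param n_candidates Random acquisition candidates per round (>= 1000
#'   recommended).
#' @param seed Integer seed for the design and candidate draws.
#' @return A list with `best_config` (named list), `best_value`, and
#'   `history` — a tibble with one row per evaluation (parameters,
#'   `value`, `best_so_far`).
#' @export
optimize_hyperparameters <- function(objective, space = search_space(),
                                     acquisition = c("ei", "pi"),
                                     n_init = 5, n_candidates = 2000,
                                     seed = 1L) {
  acquisition <- match.arg(acquisition)
  d <- length(space$params)
  budget <- space$budget
  if (budget < 1) stopf("midecoder_error_config", "budget must be >= 1")
  n_init <- min(n_init, budget)
  U <- with_local_seed(substream_seed(seed, "design"),
                       lhs::randomLHS(n_init, d))
  colnames(U) <- names(space$params)
  evals <- list()
  values <- numeric(0)
  eval_point <- function(u) {
    cfg <- decode_point(as.list(setNames(u, names(space$params))), space)
    val <- tryCatch(objective(cfg), error = function(e) NA_real_)
    if (!is.finite(val)) {
      val <- if (length(values)) max(values) else 1
      rlang::warn("objective failed; recorded as worst observed value")
    }
    list(cfg = cfg, val = val)
  }
  for (i in seq_len(n_init)) {
    ev <- eval_point(U[i, ])
    evals[[i]] <- ev$cfg
    values[i] <- ev$val
  }
  while (length(values) < budget) {
    it <- length(values) + 1
    gp <- gp_posterior(rbind(U), values)
    cand <- with_local_seed(substream_seed(seed, paste0("cand", it)), {
      base <- matrix(runif(n_candidates * d), ncol = d)
      best_u <- U[which.min(values), , drop = FALSE]
      local <- matrix(pmin(pmax(rep(best_u, each = 200) +
                                  rnorm(200 * d, 0, 0.05), 0), 1), ncol = d)
      rbind(base, local)
    })
    acq <- switch(acquisition,
                  ei = acquisition_ei(cand, gp),
                  pi = acquisition_pi(cand, gp))
    u_next <- cand[which.max(acq), ]
    ev <- eval_point(u_next)
    U <- rbind(U, u_next)
    evals[[it]] <- ev$cfg
    values[it] <- ev$val
  }
  history <- dplyr::bind_cols(
    dplyr::bind_rows(lapply(evals, tibble::as_tibble)),
    tibble::tibble(value = values, best_so_far = cummin(values),
                   iteration = seq_along(values)))
  best <- which.min(values)
  list(best_config = evals[[best]], best_value = values[best],
       history = history)
}
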