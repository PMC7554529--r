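test_that("the GP posterior interpolates and reverts to the prior", {
  gp <- gp_posterior(matrix(0.5), 2,
                     kernel_params = list(lengthscales = 0.2, sigma_f2 = 1,
                                          sigma_n2 = 1e-10))
  at_obs <- predict(gp, matrix(0.5))
  expect_equal(at_obs$mean, 2, tolerance = 1e-4)
  expect_lt(at_obs$sd, 1e-3)

  far <- predict(gp, matrix(50))
  # far from all data the posterior reverts to the prior: mean of the
  # standardized process (the observed mean) and full prior sd
  expect_equal(far$mean, 2, tolerance = 1e-6)
  expect_equal(far$sd, gp$y_sd * sqrt(gp$kernel$sigma_f2), tolerance = 1e-6)
})

test_that("GP posterior mean agrees with a direct linear-algebra oracle", {
  set.seed(11)
  X <- matrix(seq(0.05, 0.95, length.out = 6))
  y <- 3 * (X[, 1] - 0.4)^2
  gp <- gp_posterior(X, y)
  grid <- matrix(seq(0, 1, length.out = 101))
  got <- predict(gp, grid)

  # oracle: same kernel evaluated with explicit loops and base solve()
  kp <- gp$kernel
  k_fun <- function(a, b) {
    r <- abs(a - b) / kp$lengthscales[1]
    kp$sigma_f2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- k_fun(X[i], X[j])
  ys <- (y - gp$y_mu) / gp$y_sd
  alpha <- solve(K + diag(kp$sigma_n2, n), ys)
  mu_oracle <- vapply(grid[, 1], function(g)
    gp$y_mu + gp$y_sd * sum(vapply(seq_len(n), function(i)
      k_fun(g, X[i]), numeric(1)) * alpha), numeric(1))
  expect_equal(got$mean, mu_oracle, tolerance = 1e-8)
  # and the posterior mean tracks the quadratic on the observed range
  expect_lt(max(abs(got$mean - 3 * (grid[, 1] - 0.4)^2)[grid[, 1] > 0.05 &
                                                          grid[, 1] < 0.95]),
            0.35)
})

test_that("expected improvement has its closed-form values", {
  gp <- gp_posterior(matrix(c(0.2, 0.8)), c(1, 1),
                     kernel_params = list(lengthscales = 0.1, sigma_f2 = 4,
                                          sigma_n2 = 1e-12))
  # at an observed point the posterior mean equals the incumbent and
  # the EI formula collapses to sd * dnorm(0)
  p_mid <- predict(gp, matrix(0.5))
  ei_mid <- acquisition_ei(matrix(0.5), gp)
  expect_equal(ei_mid, p_mid$sd * dnorm(0), tolerance = 1e-9)

  # Monte-Carlo oracle of the defining expectation
  set.seed(12)
  draws <- rnorm(1e6, p_mid$mean, p_mid$sd)
  mc <- mean(pmax(0, 1 - draws))
  se <- sd(pmax(0, 1 - draws)) / sqrt(1e6)
  expect_lt(abs(ei_mid - mc), 3 * se)

  # deterministic limit: no improvement, no EI
  at_obs <- acquisition_ei(matrix(0.2), gp)
  expect_lt(at_obs, 1e-4)
})

test_that("probability of improvement follows the normal-cdf form", {
  gp <- gp_posterior(matrix(c(0.1, 0.9)), c(2, 4),
                     kernel_params = list(lengthscales = 0.15, sigma_f2 = 9,
                                          sigma_n2 = 1e-12))
  best <- min(predict(gp, gp$X)$mean)
  # a point whose mean sits exactly margin below the incumbent has PI 0.5
  q <- matrix(0.5)
  pq <- predict(gp, q)
  m_star <- best - pq$mean
  expect_equal(acquisition_pi(q, gp, margin = m_star), 0.5, tolerance = 1e-12)

  # PI -> 0 as the margin grows
  expect_lt(acquisition_pi(q, gp, margin = 1e6), 1e-12)

  # hand evaluation at an arbitrary margin
  m <- 0.3
  want <- pnorm((best - m - pq$mean) / pq$sd)
  expect_equal(acquisition_pi(q, gp, margin = m), want, tolerance = 1e-12)
})

test_that("Bayesian optimization finds a 1-D quadratic minimum", {
  space <- search_space(x = param_uniform(-1, 1), budget = 15)
  objective <- function(p) p$x^2
  # independent oracle: dense grid search
  grid <- seq(-1, 1, length.out = 1e4)
  oracle_min <- min(grid^2)
  for (seed in c(1, 2)) {
    res <- optimize_hyperparameters(objective, space, acquisition = "ei",
                                    seed = seed)
    expect_equal(nrow(res$history), 15)
    expect_lt(abs(res$best_value - oracle_min), 0.01)
    expect_lt(abs(res$best_config$x), 0.1)
    expect_true(all(diff(res$history$best_so_far) <= 0))
    expect_true(all(res$history$x >= -1 & res$history$x <= 1))
  }
})

test_that("budget and integer dimensions are honoured", {
  space <- search_space(k = param_integer(1, 5), budget = 1)
  res <- optimize_hyperparameters(function(p) p$k, space, seed = 3)
  expect_equal(nrow(res$history), 1)

  space5 <- search_space(k = param_integer(1, 5),
                         lr = param_log_uniform(1e-4, 1e-1), budget = 8)
  res5 <- optimize_hyperparameters(function(p) (p$k - 2)^2 + log10(p$lr)^2,
                                   space5, seed = 4)
  expect_true(all(res5$history$k == round(res5$history$k)))
  expect_true(all(res5$history$k %in% 1:5))
  expect_true(all(res5$history$lr >= 1e-4 & res5$history$lr <= 1e-1))
  expect_equal(nrow(res5$history), 8)
})

test_that("objective failures are absorbed as worst-observed values", {
  space <- search_space(x = param_uniform(0, 1), budget = 6)
  objective <- function(p) if (p$x > 0.5) stop("boom") else p$x
  w <- capture_warnings(
    res <- optimize_hyperparameters(objective, space, seed = 5))
  expect_gte(length(w), 1)
  expect_true(all(grepl("worst observed", w)))
  expect_equal(nrow(res$history), 6)
  expect_true(all(is.finite(res$history$value)))
})
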