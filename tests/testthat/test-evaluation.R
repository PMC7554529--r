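test_that("gross accuracy counts every feedback instance", {
  preds <- fake_predictions(320, p_correct = 1, seed = 1)
  expect_equal(nrow(preds), 3520)  # 320 trials x 11 windows
  expect_equal(ca_gross(preds), 100)

  half <- fake_predictions(40, p_correct = 0.5, seed = 2)
  want <- 100 * mean(half$pred == half$truth)
  expect_equal(ca_gross(half), want)

  broken <- fake_predictions(10, seed = 3)[-1, ]
  expect_error(ca_gross(broken), class = "midecoder_error_format")
})

test_that("single-trial accuracy applies the 6-of-11 majority rule", {
  mk <- function(n_ok) {
    ok <- c(rep(TRUE, n_ok), rep(FALSE, 11 - n_ok))
    tibble::tibble(subject = "S01", session = 4L, trial = 1L,
                   segment = 1:11, time = seq(5, 7, 0.2),
                   truth = factor("left", c("left", "right")),
                   pred = factor(ifelse(ok, "left", "right"),
                                 c("left", "right")))
  }
  expect_equal(ca_st(mk(6)), 100)   # exactly 6 correct counts as correct
  expect_equal(ca_st(mk(5)), 0)     # 5 correct does not
  expect_equal(ca_st(mk(11)), 100)
})

test_that("optimal-instant accuracy picks the best column, earliest on ties", {
  preds <- fake_predictions(50, p_correct = 0.7, seed = 4)
  curve <- instant_accuracy(preds)
  expect_equal(nrow(curve), 11)
  expect_equal(curve$time, seq(5, 7, 0.2))
  opt <- ca_opt(preds)
  expect_equal(opt$accuracy, max(curve$accuracy))
  expect_equal(opt$time, curve$time[which.max(curve$accuracy)])

  # constant-curve identity: every column equal means ca_opt == ca_gross
  const <- fake_predictions(20, p_correct = 1, seed = 5)
  expect_equal(ca_opt(const)$accuracy, ca_gross(const))
  expect_equal(ca_opt(const)$time, 5)  # earliest instant on ties
})

test_that("metrics equal the exhaustive counting oracle on random grids", {
  for (seed in 1:25) {
    preds <- fake_predictions(20, p_correct = runif(1, 0.2, 0.9),
                              seed = 100 + seed)
    correct <- matrix(preds$pred == preds$truth, nrow = 20, ncol = 11,
                      byrow = TRUE)
    want <- oracle_metrics(correct)
    expect_equal(ca_gross(preds), want$ca_gross)
    expect_equal(ca_st(preds), want$ca_st)
    expect_equal(ca_opt(preds)$accuracy, want$ca_opt)
  }
})

test_that("kappa matches hand-computed contingency cases", {
  expect_equal(cohen_kappa(c("left", "right"), c("left", "right")), 1)

  # contingency (30,10;10,30): p_o = 0.75, p_e = 0.5, kappa = 0.5
  truth <- rep(c("left", "right"), each = 40)
  pred <- c(rep("left", 30), rep("right", 10), rep("left", 10),
            rep("right", 30))
  expect_equal(cohen_kappa(truth, pred), 0.5)

  # balanced marginals: kappa = 2 p_o - 1 exactly
  set.seed(6)
  t2 <- rep(c("left", "right"), 30)
  p2 <- c(t2[1:40], ifelse(t2[41:60] == "left", "right", "left"))
  expect_equal(cohen_kappa(t2, p2), 2 * mean(t2 == p2) - 1)

  expect_warning(k0 <- cohen_kappa(rep("left", 5), rep("left", 5)))
  expect_equal(k0, 0)
})

test_that("the paired Wilcoxon test is exact for small samples", {
  expect_equal(compare_methods(1:9, 1:9), 1)

  # nine strictly dominating pairs: two-sided p = 2/2^9
  a <- c(70, 72, 68, 75, 80, 71, 69, 77, 74)
  b <- a - c(1, 2, 1.5, 3, 2.5, 1, 0.5, 2, 1.2)
  expect_equal(compare_methods(a, b), 2 / 512, tolerance = 1e-12)

  # random pairs against full sign-assignment enumeration
  set.seed(7)
  for (i in 1:20) {
    x <- round(runif(9, 50, 90), if (i %% 2) 1 else 0)  # even i forces ties
    y <- round(runif(9, 50, 90), if (i %% 2) 1 else 0)
    expect_equal(compare_methods(x, y), oracle_signed_rank_p(x, y),
                 tolerance = 1e-12)
  }

  # cross-check against the standard implementation when ties are absent
  set.seed(8)
  x <- runif(9); y <- runif(9)
  expect_equal(compare_methods(x, y),
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("shuffled predictions sit at chance for all three measures", {
  set.seed(9)
  preds <- fake_predictions(200, p_correct = 0.8, seed = 10)
  shuffled <- preds
  shuffled$pred <- sample(shuffled$pred)
  g <- ca_gross(shuffled)
  expect_gt(g, 40); expect_lt(g, 60)
  s <- ca_st(shuffled)
  expect_gt(s, 35); expect_lt(s, 65)
})

test_that("the metrics report bundles summary, curve and kappa", {
  preds <- fake_predictions(60, p_correct = 0.75, seed = 11)
  m <- decoding_metrics(preds)
  g <- glance(m)
  expect_equal(g$n_trials, 60)
  expect_equal(g$n_instances, 660)
  expect_equal(g$ca_gross, ca_gross(preds))
  expect_equal(g$ca_st, ca_st(preds))
  expect_equal(g$ca_opt, ca_opt(preds)$accuracy)
  expect_equal(nrow(tidy(m)), 11)
  # gross accuracy equals the mean of the 11 per-instant accuracies
  expect_equal(g$ca_gross, mean(tidy(m)$accuracy))
  expect_true(g$kappa_gross >= -1 && g$kappa_gross <= 1)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
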