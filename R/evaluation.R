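# Continuous-decoding metrics. A segment-prediction table has one row per
# (trial, segment): identifier columns (subject, session, trial), `time`
# (window end in seconds), `truth` and `pred` factors.

check_predictions <- function(preds, n_segments = NULL) {
  need <- c("subject", "session", "trial", "time", "truth", "pred")
  missing <- setdiff(need, names(preds))
  if (length(missing))
    stopf("midecoder_error_format", "predictions lack column(s): %s",
          paste(missing, collapse = ", "))
  counts <- dplyr::count(preds, .data$subject, .data$session, .data$trial)
  k <- unique(counts$n)
  if (length(k) != 1)
    stopf("midecoder_error_format",
          "trials have unequal segment counts (%s)", paste(k, collapse = ", "))
  if (!is.null(n_segments) && k != n_segments)
    stopf("midecoder_error_format", "expected %d segments per trial, found %d",
          n_segments, k)
  invisible(as.integer(k))
}

#' Gross classification accuracy
#'
#' Percentage of correctly classified decoding windows over all windows
#' of all trials: with 11 windows per trial, 320 test trials give
#' 320 x 11 = 3,520 feedback instances in the denominator.
#'
#' @param preds A segment-prediction table (see [decode_trials()]).
#' @param n_segments Expected windows per trial (default 11); used for
#'   validation only.
#' @return Accuracy in percent.
#' @export
ca_gross <- function(preds, n_segments = 11) {
  check_predictions(preds, n_segments)
  100 * mean(preds$pred == preds$truth)
}

#' Single-trial classification accuracy (majority over windows)
#'
#' A trial counts as correctly classified when at least `threshold` of
#' its 11 windows carry the true label (6-of-11 majority by default; 11
#' is odd so there are no ties).
#'
#' @inheritParams ca_gross
#' @param threshold Minimum number of correct windows.
#' @return Accuracy in percent.
#' @export
ca_st <- function(preds, threshold = 6, n_segments = 11) {
  check_predictions(preds, n_segments)
  per_trial <- dplyr::summarise(
    dplyr::group_by(preds, .data$subject, .data$session, .data$trial),
    correct = sum(.data$pred == .data$truth) >= threshold, .groups = "drop")
  100 * mean(per_trial$correct)
}

#' Per-instant accuracy curve
#'
#' Accuracy computed separately at each of the 11 window end times
#' (5.0, 5.2, ..., 7.0 s for the default grid).
#'
#' @inheritParams ca_gross
#' @return A tibble with columns `time` and `accuracy` (percent).
#' @export
instant_accuracy <- function(preds, n_segments = 11) {
  check_predictions(preds, n_segments)
  dplyr::summarise(dplyr::group_by(preds, .data$time),
                   accuracy = 100 * mean(.data$pred == .data$truth),
                   .groups = "drop")
}

#' Optimal time-point accuracy
#'
#' The maximum of the per-instant accuracy curve and the instant at which
#' it is attained; ties resolve to the earliest instant (lower decoding
#' latency).
#'
#' @inheritParams ca_gross
#' @return A one-row tibble with `accuracy` (percent) and `time` (s).
#' @export
ca_opt <- function(preds, n_segments = 11) {
  curve <- instant_accuracy(preds, n_segments)
  curve <- curve[order(curve$time), ]
  best <- which.max(curve$accuracy)  # first maximum = earliest instant
  tibble::tibble(accuracy = curve$accuracy[best], time = curve$time[best])
}

#' Cohen's kappa for two-class agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the product of the marginal label frequencies.
#' Degenerate inputs where either labelling is single-class and the
#' correction is undefined return 0 with a warning.
#'
#' @param truth,pred Equal-length label vectors (2 classes).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stopf("midecoder_error_shape", "truth and pred lengths differ")
  classes <- sort(unique(c(truth, pred)))
  p_o <- mean(truth == pred)
  p_e <- sum(vapply(classes, function(k)
    mean(truth == k) * mean(pred == k), numeric(1)))
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    rlang::warn("degenerate single-class labelling; kappa defined as 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Exact null distribution for small samples (the typical use is nine
#' subjects' accuracies under two methods): zero differences are dropped;
#' without rank ties the exact distribution comes from the signed-rank
#' cdf, with ties it is enumerated by convolution over sign assignments
#' (n <= 20), falling back to the normal approximation beyond that.
#'
#' @param a,b Equal-length paired metric vectors.
#' @return Two-sided p-value.
#' @export
compare_methods <- function(a, b) {
  if (length(a) != length(b))
    stopf("midecoder_error_shape", "paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (!any(duplicated(r))) {
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
    return(min(p, 1))
  }
  if (n <= 20) {
    # Exact distribution of the positive-rank sum under random signs:
    # polynomial convolution over (1 + x^(2 r_i)) (doubling makes tied
    # half-ranks integral).
    r2 <- as.integer(round(2 * r))
    dist <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w2 <- round(2 * W)
    p <- 2 * min(sum(dist[seq_len(w2 + 1)]),
                 sum(dist[(w2 + 1):length(dist)]))
    return(min(p, 1))
  }
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(table(r)^3 - table(r)) / 48)
  min(1, 2 * pnorm(abs(W - mu) / sigma, lower.tail = FALSE))
}

#' Full continuous-decoding metrics report
#'
#' Bundles the three accuracy measures, their kappa values (kappa over
#' all windows for the gross accuracy; kappa over trial-level majority
#' labels for the single-trial accuracy) and the per-instant curve.
#'
#' @inheritParams ca_gross
#' @return An `mi_metrics` object with [glance()] (one-row summary),
#'   [tidy()] (per-instant curve) and [ggplot2::autoplot()] methods.
#' @export
decoding_metrics <- function(preds, n_segments = 11) {
  check_predictions(preds, n_segments)
  curve <- instant_accuracy(preds, n_segments)
  opt <- ca_opt(preds, n_segments)
  majority <- dplyr::summarise(
    dplyr::group_by(preds, .data$subject, .data$session, .data$trial),
    truth = .data$truth[1],
    pred = names(which.max(table(.data$pred))), .groups = "drop")
  summary <- tibble::tibble(
    ca_gross = ca_gross(preds, n_segments),
    ca_st = ca_st(preds, n_segments = n_segments),
    ca_opt = opt$accuracy, t_opt = opt$time,
    kappa_gross = cohen_kappa(preds$truth, preds$pred),
    kappa_st = cohen_kappa(majority$truth, majority$pred),
    n_trials = nrow(majority), n_instances = nrow(preds))
  structure(list(summary = summary, curve = curve), class = "mi_metrics")
}

#' @export
print.mi_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mi_metrics> %d trials (%d instances)\n  CA_gross %.2f%%  CA_ST %.2f%%  CA_opt %.2f%% @ %.1f s  kappa %.3f\n",
    s$n_trials, s$n_instances, s$ca_gross, s$ca_st, s$ca_opt, s$t_opt,
    s$kappa_gross))
  invisible(x)
}

#' @export
glance.mi_metrics <- function(x, ...) x$summary

#' @export
tidy.mi_metrics <- function(x, ...) x$curve

#' @export
autoplot.mi_metrics <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$time, .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = "window end time (s)", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
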