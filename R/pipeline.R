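# End-to-end orchestration of the two experimental protocols:
# intra-subject (train sessions 1-3, test 4-5) and inter-subject
# leave-one-subject-out transfer (train all sessions of the others,
# test the held-out subject's sessions 4-5).

subject_metrics <- function(train_images, test_images, architecture, config,
                            grid, subject, keep_models) {
  fit <- fit_cnn(train_images, architecture, config)
  preds <- decode_trials(fit, test_images)
  metrics <- decoding_metrics(preds, grid$n_segments)
  row <- dplyr::bind_cols(tibble::tibble(subject = subject),
                          glance(metrics))
  row$curve <- list(tidy(metrics))
  row$predictions <- list(preds)
  if (keep_models) row$fit <- list(fit)
  row
}

#' Run the intra-subject decoding protocol
#'
#' For every subject: train on sessions 1--3, decode every 2-s window of
#' sessions 4--5, and report the continuous-decoding metrics. Each
#' subject gets an independent model with a seed derived from
#' `config$seed`.
#'
#' @param trials A trial table with all 5 sessions per subject.
#' @param architecture An `mi_architecture` (the intra-subject network by
#'   default).
#' @param config A [train_config()].
#' @param grid,params,normalize Image-construction settings, see
#'   [trials_to_images()].
#' @param keep_models Keep the fitted networks in a list-column.
#' @return A tibble with one row per subject: the [decoding_metrics()]
#'   summary columns plus list-columns `curve` and `predictions`.
#' @export
run_intra <- function(trials, architecture = build_architecture("arch1"),
                      config = train_config(), grid = segment_grid(),
                      params = stft_params(),
                      normalize = c("minmax", "none"), keep_models = FALSE) {
  normalize <- match.arg(normalize)
  check_trial_table(trials)
  images <- trials_to_images(trials, grid, params, normalize)
  rows <- lapply(unique(trials$subject), function(subj) {
    split_intra_subject(trials, subj)  # validates the 5-session structure
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("intra/", subj))
    subject_metrics(
      images[images$subject == subj & images$session %in% 1:3, ],
      images[images$subject == subj & images$session %in% 4:5, ],
      architecture, cfg, grid, subj, keep_models)
  })
  dplyr::bind_rows(rows)
}

#' Run the inter-subject (leave-one-subject-out) transfer protocol
#'
#' For every held-out subject: pool all five sessions of the remaining
#' subjects as training data (an identifier audit asserts the held-out
#' subject never leaks into training), optionally tune hyperparameters
#' by Bayesian optimization on the training monitor split, fit the Mega
#' Block network and decode the held-out subject's sessions 4--5.
#'
#' When `tune = TRUE` the tuned variables are the shared Mega Block
#' repeat count, learning rate, momentum (SGDM only) and L2; the
#' objective is the validation misclassification rate of a fit under the
#' candidate configuration.
#'
#' @inheritParams run_intra
#' @param architecture Baseline Mega Block architecture used when
#'   `tune = FALSE`.
#' @param tune Enable Bayesian hyperparameter optimization per held-out
#'   subject.
#' @param tune_budget,acquisition Budget and acquisition for
#'   [optimize_hyperparameters()].
#' @return A tibble with one row per held-out subject (as [run_intra()]),
#'   plus a `tuning` list-column of optimization histories when tuning.
#' @export
run_inter <- function(trials,
                      architecture = build_architecture("arch2", c(1, 1, 1)),
                      config = train_config(), grid = segment_grid(),
                      params = stft_params(),
                      normalize = c("minmax", "none"), tune = FALSE,
                      tune_budget = 30, acquisition = "ei",
                      keep_models = FALSE) {
  normalize <- match.arg(normalize)
  check_trial_table(trials)
  images <- trials_to_images(trials, grid, params, normalize)
  rows <- lapply(unique(trials$subject), function(subj) {
    assemble_inter_subject(trials, subj)  # validates the LOSO structure
    train_images <- images[images$subject != subj, ]
    test_images <- images[images$subject == subj & images$session %in% 4:5, ]
    if (subj %in% unique(train_images$subject))
      stopf("midecoder_error_leakage",
            "held-out subject %s found in the training pool", subj)
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("inter/", subj))
    arch <- architecture
    tuning <- NULL
    if (tune) {
      space <- if (config$optimizer == "sgdm") search_space(
        n_conv_layers = param_integer(1, 5),
        learning_rate = param_log_uniform(1e-6, 1e-2),
        momentum = param_uniform(0.6, 0.98),
        l2 = param_log_uniform(1e-10, 1e-2), budget = tune_budget)
      else search_space(
        n_conv_layers = param_integer(1, 5),
        learning_rate = param_log_uniform(1e-6, 1e-2),
        l2 = param_log_uniform(1e-10, 1e-2), budget = tune_budget)
      objective <- function(p) {
        cand_cfg <- cfg
        cand_cfg$learning_rate <- p$learning_rate
        cand_cfg$l2 <- p$l2
        if (!is.null(p$momentum)) cand_cfg$momentum <- p$momentum
        cand_arch <- build_architecture("arch2", rep(p$n_conv_layers, 3),
                                        l2 = p$l2)
        f <- fit_cnn(train_images, cand_arch, cand_cfg)
        f$history$val_error[nrow(f$history)]
      }
      tuning <- optimize_hyperparameters(objective, space,
                                         acquisition = acquisition,
                                         seed = cfg$seed)
      best <- tuning$best_config
      cfg$learning_rate <- best$learning_rate
      cfg$l2 <- best$l2
      if (!is.null(best$momentum)) cfg$momentum <- best$momentum
      arch <- build_architecture("arch2", rep(best$n_conv_layers, 3),
                                 l2 = best$l2)
    }
    row <- subject_metrics(train_images, test_images, arch, cfg, grid,
                           subj, keep_models)
    if (tune) row$tuning <- list(tuning$history)
    row
  })
  dplyr::bind_rows(rows)
}

#' Summarise a per-subject metrics table
#'
#' Mean and standard deviation of each accuracy/kappa column across
#' subjects, the shape in which transfer-learning results are usually
#' reported.
#'
#' @param results Output of [run_intra()] or [run_inter()].
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`.
#' @export
summarise_metrics <- function(results) {
  cols <- intersect(c("ca_gross", "ca_st", "ca_opt", "kappa_gross",
                      "kappa_st"), names(results))
  tidyr::pivot_longer(results[cols], dplyr::everything(),
                      names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
}
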