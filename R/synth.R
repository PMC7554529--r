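#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Defines the statistical structure of simulated two-class (left vs. right
#' hand) motor-imagery trials on the three bipolar channels C3, Cz, C4.
#' Each trial is 1/f background noise plus amplitude-modulated mu (centred
#' at 10 Hz) and beta (centred at 22 Hz) oscillations on every channel;
#' during the imagery interval the oscillation amplitude at the channel
#' contralateral to the imagined hand (C4 for left, C3 for right) is scaled
#' by `sqrt(1 - erd_depth)`, emulating event-related desynchronization
#' (ERD). Trials follow the standard cue paradigm: fixation from 0 s, cue
#' at 3 s, motor imagery over 3--7 s, trial length 8 s.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_length Trial duration in seconds.
#' @param mi_interval Motor-imagery interval `c(start, end)` in seconds.
#' @param channels Ordered channel names; must be C3, Cz, C4.
#' @param erd_depth Fractional band-power reduction in `[0, 1]` at the
#'   contralateral channel during imagery. `0` means no class contrast.
#' @param mu_band,beta_band Frequency bands in Hz for the two rhythms.
#' @param noise_exponent Spectral slope of the 1/f^a background noise.
#' @param snr Amplitude ratio of the mu oscillation to the background noise
#'   (the beta oscillation gets half the mu amplitude).
#' @param subject_shift_sd Log-scale standard deviation of the per-subject
#'   multiplicative variability of `erd_depth`.
#' @param seed Integer seed consumed by [generate_dataset()].
#'
#' @return An object of class `synth_config`.
#' @seealso [generate_trial()], [generate_dataset()]
#' @export
synth_config <- function(sampling_rate = 250, trial_length = 8,
                         mi_interval = c(3, 7),
                         channels = c("C3", "Cz", "C4"),
                         erd_depth = 0.5, mu_band = c(8, 13),
                         beta_band = c(13, 32), noise_exponent = 1,
                         snr = 1, subject_shift_sd = 0.1, seed = 1L) {
  if (erd_depth < 0 || erd_depth > 1)
    stopf("midecoder_error_config", "erd_depth must be in [0, 1], got %g", erd_depth)
  if (mi_interval[1] < 0 || mi_interval[2] > trial_length ||
      mi_interval[1] >= mi_interval[2])
    stopf("midecoder_error_config", "mi_interval must lie within [0, %g]", trial_length)
  if (sampling_rate <= 2 * max(beta_band))
    stopf("midecoder_error_config",
          "sampling_rate (%g) must exceed twice the beta band edge (%g)",
          sampling_rate, 2 * max(beta_band))
  if (!identical(channels, c("C3", "Cz", "C4")))
    stopf("midecoder_error_config", "channels must be C3, Cz, C4 in that order")
  structure(list(
    sampling_rate = sampling_rate, trial_length = trial_length,
    mi_interval = mi_interval, channels = channels, erd_depth = erd_depth,
    mu_band = mu_band, beta_band = beta_band,
    noise_exponent = noise_exponent, snr = snr,
    subject_shift_sd = subject_shift_sd, seed = seed
  ), class = "synth_config")
}

# 1/f^a background noise by spectral shaping of white Gaussian noise,
# rescaled to unit standard deviation.
pink_noise <- function(n, sampling_rate, exponent = 1) {
  white <- rnorm(n)
  X <- fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * sampling_rate / n   # two-sided frequency axis
  shape <- c(0, f[-1]^(-exponent / 2))      # kill DC
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x / sd(x)
}

# Amplitude gain profile implementing ERD: 1 outside the imagery interval,
# sqrt(1 - depth) inside, with `ramp`-second raised-cosine transitions so
# the first/last analysis windows see no step edge.
erd_gain <- function(t, mi_interval, depth, ramp = 0.25) {
  g_mi <- sqrt(1 - depth)
  gain <- rep(1, length(t))
  on <- mi_interval[1]; off <- mi_interval[2]
  inside <- t >= (on + ramp) & t <= (off - ramp)
  gain[inside] <- g_mi
  up <- t >= on & t < (on + ramp)
  gain[up] <- 1 + (g_mi - 1) * (1 - cos(pi * (t[up] - on) / ramp)) / 2
  dn <- t > (off - ramp) & t <= off
  gain[dn] <- g_mi + (1 - g_mi) * (1 - cos(pi * (t[dn] - (off - ramp)) / ramp)) / 2
  gain
}

# One amplitude-modulated narrowband oscillation: random phase, small
# centre-frequency jitter, slow sinusoidal amplitude modulation.
am_oscillation <- function(t, centre_freq, amplitude) {
  f <- centre_freq + rnorm(1, 0, 0.3)
  phase <- runif(1, 0, 2 * pi)
  f_am <- runif(1, 0.2, 1)
  ph_am <- runif(1, 0, 2 * pi)
  m <- 1 + 0.4 * sin(2 * pi * f_am * t + ph_am)
  amplitude * m * sin(2 * pi * f * t + phase)
}

#' Generate one synthetic motor-imagery trial
#'
#' Draws a single labelled trial from the generative model described in
#' [synth_config()]. Randomness comes from the current R random stream;
#' seed it (or use [generate_dataset()]) for reproducibility.
#'
#' @param label `"left"` or `"right"` hand motor imagery.
#' @param config A [synth_config()].
#' @param erd_depth Optional per-call override of the configured ERD depth
#'   (used internally for subject-level variability).
#'
#' @return An object of class `mi_trial`: a list with `data` (3 x samples
#'   matrix, rows C3, Cz, C4, microvolt-scale arbitrary units), `label`,
#'   `sampling_rate` and `mi_interval`.
#' @export
generate_trial <- function(label, config = synth_config(), erd_depth = NULL) {
  if (!is.character(label) || length(label) != 1 ||
      !label %in% c("left", "right"))
    stopf("midecoder_error_label", "label must be \"left\" or \"right\", got %s",
          deparse(substitute(label)))
  depth <- erd_depth %??% config$erd_depth
  depth <- min(max(depth, 0), 1)
  fs <- config$sampling_rate
  n <- round(config$trial_length * fs)
  t <- (seq_len(n) - 1) / fs
  contralateral <- if (label == "left") "C4" else "C3"
  mu_c <- mean(config$mu_band) - 0.5    # 10 Hz for the 8-13 Hz band
  beta_c <- mean(config$beta_band) - 0.5  # 22 Hz for the 13-32 Hz band
  data <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(config$channels, NULL))
  for (ch in config$channels) {
    osc <- am_oscillation(t, mu_c, config$snr) +
      am_oscillation(t, beta_c, config$snr / 2)
    gain <- if (ch == contralateral)
      erd_gain(t, config$mi_interval, depth) else rep(1, n)
    data[ch, ] <- pink_noise(n, fs, config$noise_exponent) + gain * osc
  }
  structure(list(data = data, label = label, sampling_rate = fs,
                 mi_interval = config$mi_interval),
            class = "mi_trial")
}

#' Generate a multi-subject, multi-session synthetic dataset
#'
#' Simulates `n_subjects` subjects recorded over `n_sessions` sessions with
#' `trials_per_session` trials each, exactly balanced between left and
#' right within every session. Each subject receives an individual ERD
#' depth drawn once from a lognormal distribution centred (in the median)
#' on `config$erd_depth` with log-sd `config$subject_shift_sd`, then
#' clamped to `[0, 1]`. Output is fully determined by `config$seed`.
#'
#' @param n_subjects,trials_per_session,n_sessions Positive counts;
#'   `trials_per_session` must be even so classes balance exactly.
#' @param config A [synth_config()].
#'
#' @return A tibble with one row per trial: `subject` (e.g. `"S01"`),
#'   `session` (integer 1..n_sessions), `trial` (within-session index),
#'   `label` (factor left/right), `sampling_rate`, `erd_depth` (the
#'   subject's realized depth), and a `data` list-column of 3 x samples
#'   matrices.
#' @export
generate_dataset <- function(n_subjects, trials_per_session, n_sessions = 5,
                             config = synth_config()) {
  if (n_subjects < 1 || trials_per_session < 1 || n_sessions < 1)
    stopf("midecoder_error_config", "counts must all be >= 1")
  if (trials_per_session %% 2 != 0)
    stopf("midecoder_error_balance",
          "trials_per_session must be even for exact class balance, got %d",
          trials_per_session)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  depths <- with_local_seed(substream_seed(config$seed, "subject-depths"), {
    pmin(pmax(config$erd_depth *
                exp(rnorm(n_subjects, 0, config$subject_shift_sd)), 0), 1)
  })
  rows <- vector("list", n_subjects * n_sessions)
  i <- 0
  for (s in seq_len(n_subjects)) {
    for (sess in seq_len(n_sessions)) {
      i <- i + 1
      rows[[i]] <- with_local_seed(
        substream_seed(config$seed, paste(subjects[s], sess, sep = "/")), {
          labels <- sample(rep(c("left", "right"), trials_per_session / 2))
          trials <- lapply(labels, function(lab)
            generate_trial(lab, config, erd_depth = depths[s]))
          tibble::tibble(
            subject = subjects[s], session = as.integer(sess),
            trial = seq_along(labels),
            label = factor(labels, levels = c("left", "right")),
            sampling_rate = config$sampling_rate,
            erd_depth = depths[s],
            data = lapply(trials, `[[`, "data")
          )
        })
    }
  }
  dplyr::bind_rows(rows)
}
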