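# Independent oracles used across the suite. These are deliberately
# written against first principles (explicit DFT sums, exhaustive
# counting, full enumeration) and never call the implementation paths
# they check.

# Naive windowed DFT spectrogram: frames the signal exactly as specified
# (start 0, step = window - overlap, frames that would overrun dropped),
# multiplies by the taper and evaluates the DFT from its definition via
# an explicit basis matrix. No FFT anywhere.
naive_dft_spectrogram <- function(x, window, overlap, n_fft, taper) {
  step <- window - overlap
  n_frames <- (length(x) - window) %/% step + 1
  n_bins <- n_fft / 2 + 1
  k <- 0:(n_bins - 1)
  n <- 0:(n_fft - 1)
  basis <- exp(-2i * pi * outer(k, n) / n_fft)  # n_bins x n_fft
  out <- matrix(0, n_bins, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1) * step + 1):((f - 1) * step + window)] * taper
    padded <- c(seg, rep(0, n_fft - window))
    out[, f] <- Mod(basis %*% padded)
  }
  out
}

# Band power of one channel within a time window, from the raw
# periodogram (|DFT|^2 / n), summed over bins inside `band`.
oracle_band_power <- function(x, fs, band, t_window) {
  idx <- (round(t_window[1] * fs) + 1):round(t_window[2] * fs)
  seg <- x[idx]
  n <- length(seg)
  spec <- Mod(fft(seg))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(spec[freqs >= band[1] & freqs <= band[2]])
}

# Exhaustive counting oracle for the three continuous-decoding
# accuracies, operating on a trials x segments logical matrix of
# per-window correctness.
oracle_metrics <- function(correct) {
  n_trials <- nrow(correct)
  n_seg <- ncol(correct)
  gross <- 0
  st <- 0
  for (i in seq_len(n_trials)) {
    n_ok <- 0
    for (j in seq_len(n_seg)) if (correct[i, j]) n_ok <- n_ok + 1
    gross <- gross + n_ok
    if (n_ok >= 6) st <- st + 1
  }
  per_instant <- numeric(n_seg)
  for (j in seq_len(n_seg)) {
    ok <- 0
    for (i in seq_len(n_trials)) if (correct[i, j]) ok <- ok + 1
    per_instant[j] <- 100 * ok / n_trials
  }
  list(ca_gross = 100 * gross / (n_trials * n_seg),
       ca_st = 100 * st / n_trials,
       ca_opt = max(per_instant),
       t_opt_index = which.max(per_instant),
       per_instant = per_instant)
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n
# sign assignments (ties handled by using the midrank values directly).
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_lo <- mean(W_all <= W_obs)
  p_hi <- mean(W_all >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Random segment-prediction table with known structure.
fake_predictions <- function(n_trials, n_segments = 11, p_correct = 0.6,
                             seed = 1) {
  set.seed(seed)
  truth <- sample(c("left", "right"), n_trials, replace = TRUE)
  rows <- lapply(seq_len(n_trials), function(i) {
    ok <- runif(n_segments) < p_correct
    pred <- ifelse(ok, truth[i],
                   ifelse(truth[i] == "left", "right", "left"))
    tibble::tibble(subject = "S01", session = 4L, trial = i,
                   segment = seq_len(n_segments),
                   time = 5 + 0.2 * (seq_len(n_segments) - 1),
                   truth = factor(truth[i], c("left", "right")),
                   pred = factor(pred, c("left", "right")))
  })
  dplyr::bind_rows(rows)
}

# Competition-shaped trial table (sessions of 140/140/140/160/160 trials)
# with placeholder signals; used where only the counting structure
# matters, never for signal processing.
fake_competition_subject <- function(subject = "S01") {
  sizes <- c(140, 140, 140, 160, 160)
  rows <- lapply(seq_along(sizes), function(sess) {
    n <- sizes[sess]
    tibble::tibble(
      subject = subject, session = as.integer(sess), trial = seq_len(n),
      label = factor(rep(c("left", "right"), n / 2), c("left", "right")),
      sampling_rate = 250,
      data = replicate(n, matrix(0, 3, 4,
                                 dimnames = list(c("C3", "Cz", "C4"), NULL)),
                       simplify = FALSE))
  })
  dplyr::bind_rows(rows)
}

# Small toy segment-image table: two visually distinct constant patterns
# plus light noise, linearly separable.
toy_image_table <- function(n = 24, seed = 1, noise_sd = 0.01) {
  set.seed(seed)
  labs <- rep(c("left", "right"), length.out = n)
  imgs <- lapply(labs, function(l) {
    base <- if (l == "left") 0.25 else 0.75
    array(base + rnorm(40 * 32 * 3, 0, noise_sd), c(40, 32, 3))
  })
  tibble::tibble(subject = "S01", session = 1L, trial = seq_len(n),
                 label = factor(labs, c("left", "right")),
                 segment = 1L, time = 5,
                 image = imgs)
}
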