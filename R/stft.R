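#' Sliding-window grid over the motor-imagery interval
#'
#' The decoder classifies 2-s windows slid in 200-ms steps across the
#' 3--7 s imagery interval, which yields 11 windows per trial whose end
#' times 5.0, 5.2, ..., 7.0 s are the continuous-decoding instants.
#'
#' @param window_length Window length in seconds.
#' @param hop Shift between consecutive windows in seconds.
#' @param interval Imagery interval `c(start, end)` in seconds.
#' @return A `segment_grid` object with `n_segments` and `window_end_times`.
#' @export
segment_grid <- function(window_length = 2, hop = 0.2, interval = c(3, 7)) {
  len <- interval[2] - interval[1]
  if (window_length > len)
    stopf("midecoder_error_config", "window (%g s) longer than interval (%g s)",
          window_length, len)
  n <- floor((len - window_length) / hop + 1e-9) + 1
  starts <- interval[1] + hop * (seq_len(n) - 1)
  structure(list(window_length = window_length, hop = hop,
                 interval = interval, n_segments = as.integer(n),
                 window_end_times = starts + window_length),
            class = "segment_grid")
}

#' Short-time Fourier transform parameters
#'
#' Defaults give a 257 x 32 magnitude spectrogram for a 2-s, 500-sample
#' segment at 250 Hz: 64-sample Hamming windows shifted by 14 samples
#' (overlap 50) and zero-padded to 512 FFT points, so the frequency
#' resolution is 250/512 = 0.488 Hz.
#'
#' @param window_samples,overlap_samples,n_fft Integer STFT geometry.
#' @param window_function Taper name; only `"hamming"` and `"hann"` are
#'   provided.
#' @return An `stft_params` object.
#' @export
stft_params <- function(window_samples = 64, overlap_samples = 50,
                        n_fft = 512, window_function = "hamming") {
  if (overlap_samples >= window_samples)
    stopf("midecoder_error_config", "overlap must be < window length")
  if (n_fft < window_samples)
    stopf("midecoder_error_config", "n_fft must be >= window length")
  structure(list(window_samples = as.integer(window_samples),
                 overlap_samples = as.integer(overlap_samples),
                 n_fft = as.integer(n_fft),
                 window_function = window_function),
            class = "stft_params")
}

taper <- function(params) {
  n <- params$window_samples
  switch(params$window_function,
         hamming = signal::hamming(n),
         hann = signal::hanning(n),
         stopf("midecoder_error_config", "unknown window function %s",
               params$window_function))
}

#' Cut a trial into sliding 2-s segments
#'
#' Segment `k` (1-based) spans `[interval[1] + hop*(k-1), + window_length)`
#' seconds, half-open in samples: at 250 Hz segment 1 covers samples
#' 750..1249 (0-based) and segment 11 starts at sample 1250.
#'
#' @param trial An `mi_trial`, or a 3 x samples matrix.
#' @param grid A [segment_grid()].
#' @param sampling_rate Required when `trial` is a bare matrix.
#' @return A list of `n_segments` matrices, 3 x (window samples), with the
#'   grid's `window_end_times` attached as an attribute.
#' @export
segment_trial <- function(trial, grid = segment_grid(), sampling_rate = NULL) {
  if (inherits(trial, "mi_trial")) {
    data <- trial$data
    fs <- trial$sampling_rate
  } else {
    data <- trial
    fs <- sampling_rate %??%
      stopf("midecoder_error_config", "sampling_rate needed for matrix input")
  }
  need <- round(grid$interval[2] * fs)
  if (ncol(data) < need)
    stopf("midecoder_error_segment",
          "trial has %d samples but the grid needs %d (%g s at %g Hz)",
          ncol(data), need, grid$interval[2], fs)
  win <- round(grid$window_length * fs)
  segs <- lapply(seq_len(grid$n_segments), function(k) {
    start <- round((grid$interval[1] + grid$hop * (k - 1)) * fs)  # 0-based
    data[, (start + 1):(start + win), drop = FALSE]
  })
  attr(segs, "window_end_times") <- grid$window_end_times
  segs
}

#' Magnitude spectrogram of one channel segment
#'
#' Frames the signal (no padding at the edges: frames that would overrun
#' the signal are dropped), applies the taper, zero-pads each frame to
#' `n_fft` points and returns one-sided DFT magnitudes. For the default
#' geometry a 500-sample input gives floor((500-64)/14)+1 = 32 frames and
#' 512/2+1 = 257 frequency bins.
#'
#' @param x Numeric signal of one channel (length 500 for the defaults).
#' @param params An [stft_params()].
#' @param sampling_rate Sampling rate in Hz (for the bin-frequency axis).
#' @return A 257 x 32 non-negative matrix with attributes `freq` (Hz per
#'   row) and `time` (frame-centre seconds per column).
#' @export
compute_spectrogram <- function(x, params = stft_params(),
                                sampling_rate = 250) {
  win <- params$window_samples
  step <- win - params$overlap_samples
  if (length(x) < win)
    stopf("midecoder_error_segment", "signal (%d samples) shorter than window (%d)",
          length(x), win)
  n_frames <- (length(x) - win) %/% step + 1
  starts <- (seq_len(n_frames) - 1) * step
  idx <- outer(seq_len(win), starts, `+`)          # win x n_frames
  frames <- matrix(x[idx], nrow = win) * taper(params)
  padded <- rbind(frames, matrix(0, params$n_fft - win, n_frames))
  spec <- Mod(mvfft(padded))[seq_len(params$n_fft / 2 + 1), , drop = FALSE]
  structure(spec,
            freq = (seq_len(nrow(spec)) - 1) * sampling_rate / params$n_fft,
            time = (starts + win / 2) / sampling_rate)
}

# 1-based row indices of the spectrogram covering [f_lo, f_hi]:
# bins floor(f_lo*n_fft/fs) .. ceiling(f_hi*n_fft/fs) inclusive (0-based).
# At fs=250, n_fft=512 this selects 20 rows for 4-13 Hz and 41 for 13-32 Hz.
band_rows <- function(band, n_fft, sampling_rate) {
  lo <- floor(band[1] * n_fft / sampling_rate)
  hi <- ceiling(band[2] * n_fft / sampling_rate)
  if (hi < lo) stopf("midecoder_error_config", "empty band slice %g-%g Hz",
                     band[1], band[2])
  (lo:hi) + 1L
}

# Cubic-spline reduction matrix M (n_out x n_in): interpolation is linear
# in the column values, so M is precomputed from unit responses and the
# whole 41 x 32 beta block reduces to 20 x 32 as one matrix product.
interp_matrix <- function(n_in, n_out) {
  xout <- seq(1, n_in, length.out = n_out)
  cols <- vapply(seq_len(n_in), function(j) {
    e <- numeric(n_in); e[j] <- 1
    spline(seq_len(n_in), e, xout = xout, method = "fmm")$y
  }, numeric(n_out))
  cols
}

the <- new.env(parent = emptyenv())  # cache for interpolation matrices

#' Build the 40 x 32 x 3 network input image for one segment
#'
#' Per channel: compute the 257 x 32 magnitude spectrogram, slice the
#' theta-alpha band (4--13 Hz, 20 rows) and the beta band (13--32 Hz, 41
#' rows), reduce the beta slice to 20 x 32 by cubic interpolation along
#' frequency so both bands carry equal weight, and stack the two 20 x 32
#' blocks vertically (theta-alpha on top). The three channel images
#' C3, Cz, C4 are stacked depthwise like RGB planes.
#'
#' @param segment A 3 x 500 matrix (channels C3, Cz, C4).
#' @param params An [stft_params()].
#' @param sampling_rate Sampling rate in Hz.
#' @param mu_theta_band,beta_band Frequency bands in Hz.
#' @param normalize `"minmax"` rescales the whole image to `[0, 1]`
#'   (all-constant images map to 0); `"none"` keeps raw magnitudes.
#' @return A 40 x 32 x 3 array.
#' @export
build_input_image <- function(segment, params = stft_params(),
                              sampling_rate = 250,
                              mu_theta_band = c(4, 13), beta_band = c(13, 32),
                              normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  if (nrow(segment) != 3)
    stopf("midecoder_error_format", "segment must have 3 channels, got %d",
          nrow(segment))
  rows_top <- band_rows(mu_theta_band, params$n_fft, sampling_rate)
  rows_bot <- band_rows(beta_band, params$n_fft, sampling_rate)
  key <- sprintf("interp_%d_%d", length(rows_bot), length(rows_top))
  if (is.null(the[[key]]))
    the[[key]] <- interp_matrix(length(rows_bot), length(rows_top))
  M <- the[[key]]
  n_t <- (ncol(segment) - params$window_samples) %/%
    (params$window_samples - params$overlap_samples) + 1
  img <- array(0, dim = c(2 * length(rows_top), n_t, 3))
  for (ch in 1:3) {
    spec <- compute_spectrogram(segment[ch, ], params, sampling_rate)
    img[, , ch] <- rbind(spec[rows_top, , drop = FALSE],
                         M %*% spec[rows_bot, , drop = FALSE])
  }
  if (normalize == "minmax") {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
    else array(0, dim = dim(img))
  }
  img
}

#' Convert a trial table to a segment-image table
#'
#' Applies [segment_trial()] and [build_input_image()] to every trial.
#' All 11 segment images of a trial inherit the trial's class label, which
#' both provides a training example per decoding instant and grows the
#' training set elevenfold (420 trials become 4,620 images).
#'
#' @param trials A trial table.
#' @param grid A [segment_grid()].
#' @param params An [stft_params()].
#' @param normalize Passed to [build_input_image()].
#' @return A tibble with one row per (trial, segment): the trial columns
#'   plus `segment` (1..11), `time` (window end, s) and an `image`
#'   list-column of 40 x 32 x 3 arrays.
#' @export
trials_to_images <- function(trials, grid = segment_grid(),
                             params = stft_params(),
                             normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  check_trial_table(trials)
  rows <- purrr::pmap(
    list(trials$data, trials$sampling_rate, seq_len(nrow(trials))),
    function(data, fs, i) {
      segs <- segment_trial(data, grid, sampling_rate = fs)
      imgs <- lapply(segs, build_input_image, params = params,
                     sampling_rate = fs, normalize = normalize)
      tibble::tibble(
        subject = trials$subject[i], session = trials$session[i],
        trial = trials$trial[i], label = trials$label[i],
        segment = seq_along(imgs), time = grid$window_end_times,
        image = imgs)
    })
  dplyr::bind_rows(rows)
}
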