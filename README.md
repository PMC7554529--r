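# midecoder

Continuous decoding of two-class motor-imagery EEG from spectrogram
images, with repeatable "Mega Block" convolutional networks and
Gaussian-process hyperparameter optimization.

## The problem

Imagining a left- or right-hand movement suppresses the sensorimotor mu
(8–13 Hz) and beta (13–32 Hz) rhythms over the *contralateral* motor
cortex — event-related desynchronization (ERD). Brain–computer
interfaces for neurofeedback and motor rehabilitation decode this
lateralized band-power change from a three-channel bipolar montage
(C3, Cz, C4) at 250 Hz, trial by trial: fixation from 0 s, cue at 3 s,
imagery over 3–7 s. `midecoder` is for BCI researchers who want this
decoding chain — including the *continuous* variant that emits a
decision every 200 ms rather than once per trial, and the
*cross-subject transfer* variant that needs no calibration data from
the test subject — as tested, scriptable R functions.

## The method

1. **Images.** Each trial is cut into 11 sliding 2-s windows
   (end times 5.0–7.0 s). Per window and channel a 64-sample-Hamming /
   50-overlap / 512-point STFT gives a 257×32 magnitude spectrogram;
   the 4–13 Hz slice (20×32) is stacked over the cubically-interpolated
   13–32 Hz slice (41×32 → 20×32), and channels stack depthwise:
   a 40×32×3 image per window.
2. **Networks.** An intra-subject CNN
   (conv16–conv32–conv64, 3×3, each with batch norm + ReLU) and an
   inter-subject **Mega Block** CNN (blocks of 9/18/36 filters, each
   block repeated 1–5 times with identical parameters). Same padding and
   ceil-mode pooling give dense-layer widths 192 and 108 respectively.
3. **Training.** SGD with momentum (v ← μv − η∇l; θ ← θ + v) or Adam
   (bias-corrected first/second moments), cross-entropy loss, L2 decay,
   stepwise learning-rate drops. Hyperparameters (Mega Block repeats,
   learning rate, momentum, L2) can be tuned by Bayesian optimization:
   a Matérn-5/2 Gaussian process with expected-improvement
   EI(x) = E[max(0, μ(x_b) − f(x))] or probability-of-improvement
   Φ((μ(x_best) − m − μ(x))/σ(x)) acquisitions over a 30-evaluation
   budget.
4. **Metrics.** CA_gross (percent of all trial×11 windows correct),
   CA_ST (trial correct iff ≥6 of 11 windows correct), CA_opt (best
   single decoding instant, earliest on ties), Cohen's κ, and exact
   paired Wilcoxon signed-rank comparisons.
5. **Protocols.** `run_intra()` trains on sessions 1–3 and tests on
   sessions 4–5 per subject; `run_inter()` is leave-one-subject-out
   over all five sessions of the remaining subjects.

A bundled generator synthesizes trial-structured EEG — 1/f background,
amplitude-modulated 10/22 Hz rhythms, contralateral amplitude scaling
√(1−erd_depth) during imagery, lognormal between-subject variability,
balanced sessions — so the whole chain runs and is tested without any
recording. Real BCI Competition IV-2b GDF files can be ingested through
`read_trials(dialect = "gdf")` (requires Python with `mne`).

## Worked example

```r
library(midecoder)

trials <- generate_dataset(n_subjects = 1, trials_per_session = 12,
                           n_sessions = 5,
                           config = synth_config(erd_depth = 0.6, seed = 42))

cfg <- train_config("adam", epochs = 4, batch_size = 32,
                    learning_rate = 1e-3, l2 = 1e-4,
                    validation_size = 0, seed = 1)
res <- run_intra(trials, build_architecture("arch1"), cfg)
res[, c("subject", "ca_gross", "ca_st", "ca_opt", "t_opt", "kappa_gross")]
#> # A tibble: 1 × 6
#>   subject ca_gross ca_st ca_opt t_opt kappa_gross
#>   <chr>      <dbl> <dbl>  <dbl> <dbl>       <dbl>
#> 1 S01         94.3  91.7    100     5       0.886

res$curve[[1]]
#> # A tibble: 11 × 2
#>     time accuracy
#>    <dbl>    <dbl>
#>  1   5      100
#>  2   5.2     95.8
#>  3   5.4     95.8
#>  4   5.6     91.7
#>  ...
#> 11   7       95.8
```

Read: after training on 36 calibration trials (sessions 1–3, 11 window
images each), the decoder classified 94.3% of the 24×11 = 264 test
windows of sessions 4–5 correctly (κ = 0.886); 91.7% of test trials had
a correct 6-of-11 majority; the best single decoding instant was the
5.0 s window end, at 100%. `tidy()`/`glance()` methods expose training
history and summaries; `autoplot()`, `plot_trial()` and
`plot_input_image()` draw the loss curves, raw traces and input images.

Shape arithmetic is available without training anything:

```r
shape_trace(build_architecture("arch2", c(3, 3, 3)))  # dense width 108
count_parameters(build_architecture("arch1"))         # audited total 24194
```

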