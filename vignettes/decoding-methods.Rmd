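---
title: "Continuous motor-imagery decoding with spectrogram-image CNNs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous motor-imagery decoding with spectrogram-image CNNs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(midecoder)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a hand movement — suppresses
the sensorimotor mu (8–13 Hz) and beta (13–32 Hz) rhythms over the
contralateral motor cortex. This *event-related desynchronization* (ERD)
is the physiological signal that two-class (left vs. right hand)
MI brain–computer interfaces decode. `midecoder` implements a complete
decoding chain for the standard three-channel bipolar montage (C3, Cz,
C4) sampled at 250 Hz, organised around cue-paradigm trials: fixation
from 0 s, cue at 3 s, imagery over 3–7 s, 8 s total.

The chain has five stages, each a small module of the package:

1. **Trials → sliding windows.** A 2-s window shifted in 200-ms steps
   across the 3–7 s imagery interval gives 11 windows per trial, with
   end times 5.0, 5.2, …, 7.0 s. Decoding each window separately turns
   one trial into eleven feedback instants — the "continuous decoding"
   setting — and multiplies the training set elevenfold, since every
   window inherits its trial's label.
2. **Windows → images.** Each 500-sample window is turned into a
   40×32×3 time–frequency image (below).
3. **Images → class probabilities.** A small CNN — either the fixed
   intra-subject network or a "Mega Block" network whose depth is a
   tuning variable — maps images to left/right probabilities.
4. **Training.** SGD with momentum or Adam, cross-entropy loss, L2
   weight decay and a piecewise learning-rate schedule; hyperparameters
   optionally chosen by Gaussian-process Bayesian optimization.
5. **Evaluation.** Three accuracy measures over the 11-slot prediction
   grid (CA_gross, CA_ST, CA_opt), Cohen's kappa, and exact paired
   Wilcoxon tests for method comparisons.

## Input image construction

For each channel of a 500-sample window the short-time Fourier
transform uses 64-sample Hamming windows with 50-sample overlap
(14-sample hop) and 512 FFT points, giving a 257×32 magnitude
spectrogram: floor((500−64)/14)+1 = 32 frames and 512/2+1 = 257 bins at
250/512 ≈ 0.488 Hz spacing.

Two band slices are taken with the bin rule
floor(f_lo·n_fft/fs) … ceiling(f_hi·n_fft/fs) (0-based, inclusive):
4–13 Hz yields 20 rows (bins 8–27) and 13–32 Hz yields 41 rows (bins
26–66). This is the only simple selection rule consistent with both
printed slice heights, and it is frozen as the package's convention.
The beta slice is reduced to 20×32 by cubic-spline interpolation along
frequency so both bands contribute equally, then the two 20×32 blocks
are stacked vertically (theta–alpha on top) and the three channels
depthwise, giving 40×32×3. Because interpolation is linear in the
interpolated values, the 41→20 reduction is precomputed once as a 20×41
matrix of unit-response splines (`stats::spline`, "fmm" end conditions)
and applied as a single matrix product per channel; tests verify it
matches per-column `spline()` calls to machine precision.

Magnitude (not power, not dB) is used, and each finished image is
min–max normalized to [0, 1]; both choices are exposed as arguments
(`normalize = "none"` keeps raw magnitudes) because the bounded input
range is a training-stability choice, not part of the time–frequency
definition.

## Network architectures

Both architectures operate on 40×32×3 inputs and end in average pooling
→ fully connected → softmax over 2 classes, with cross-entropy loss.
Convolutions are stride-1 and *same*-padded; pooling uses *ceil-mode*
output sizes, `ceiling((n−k)/s)+1`, with border windows clamped to the
valid region. These two conventions are load-bearing: they are the ones
that reproduce the published flattened widths of the dense layers —
40×32 → 20×16 → 10×8 through two 3×3 stride-2 max pools, so the final
8×8 stride-1 average pool leaves 3×1 maps and the flatten sizes are
3·1·64 = 192 (intra-subject) and 3·1·36 = 108 (inter-subject).

* **Intra-subject network** (`build_architecture("arch1")`):
  conv16(3×3) → maxpool → conv32(3×3) → maxpool → conv64(3×3) →
  avgpool(8×8) → FC(2), every convolution followed by batch
  normalization (ε = 1e-5) and ReLU, L2 coefficient 0.0014 on kernels.
* **Inter-subject Mega Block network** (`build_architecture("arch2",
  c(r1, r2, r3))`): three Mega Blocks of 9 (5×5), 18 (3×3) and 36 (3×3)
  filters. A *Mega Block* repeats its convolution block `r` ∈ 1…5 times
  with identical parameters; repeats change depth and parameter count
  but never the spatial chain, so the dense width stays 108 for every
  repeat setting. Pooling sits after the first two blocks.

`count_parameters()` counts every trainable tensor: convolution kernels
and biases, batch-norm scale/offset pairs, and dense weights and biases;
`parameter_audit()` emits the per-layer table. Under this convention
arch1 has 24,194 parameters (448+32 + 4,640+64 + 18,496+128 + 386).
Published counts for these networks (23,269, and 7,578–40,914 across
repeat settings) do not match this or any neighbouring convention we
audited (dropping biases gives 24,082; dropping batch-norm parameters
23,970), so the package documents its own audited numbers rather than
forcing agreement; the discrepancy does not affect any shape or any
learning behaviour.

### Eq-level conventions in the engine

The CNN is implemented in the package (R orchestration over C++
im2col/col2im, pooling and batch-norm kernels, with BLAS matrix
products): no deep-learning runtime is involved. Choices a reader may
want stated:

* ReLU is exact max(0, a); the softplus sometimes written next to it in
  textbook treatments is not used.
* Batch normalization uses biased batch variance in training, running
  moments (momentum 0.9) at inference, ε = 1e-5.
* Weight decay: the penalty λ/2·Σw² is added to the reported loss and
  λ·w to kernel gradients, for convolution and dense kernels only —
  never biases or batch-norm parameters.
* SGDM is the exact two-line update v ← μv − η∇l, θ ← θ + v (no
  dampening, no Nesterov); Adam uses the standard bias-corrected
  moments with β₁ = 0.9, β₂ = 0.999 and ε = 1e-8 added *outside* the
  square root.
* Initialization is uniform fan-in scaling U(±√(6/fan_in)) for kernels,
  γ = 1, β = 0 for batch norm; the exact scheme of the original work is
  unpublished, so this conventional choice is fixed and seeded.
* Gradient correctness is pinned by finite-difference tests through
  every layer type.

## Training protocol

`train_config()` defaults mirror the within-subject recipe: SGDM with
learning rate 6.7929e-4 and momentum 0.9799, batch 40, 55 epochs, L2
0.0014, learning rate multiplied by 0.1 every 20 epochs; the
inter-subject recipe in the source work used up to 50 epochs, batch 64
and a drop period of 40, and Adam variants started at 0.01. One reading
note: the phrase "dropout rate 0.1, drop period 20" in the source is
interpreted here as the learning-rate *drop factor and period* — no
dropout layer appears in either architecture table and the wording
parallels the explicit learning-rate schedule of the transfer
experiments. No dropout layers are implemented.

500 segment images (capped at a quarter of the data for small runs) are
sampled without replacement and held out purely to monitor validation
loss and error; there is no early stopping. Mini-batches are reshuffled
every epoch from a named substream of the root seed, which also drives
initialization and validation sampling, so `fit_cnn()` is bit-for-bit
reproducible.

## Hyperparameter optimization

`optimize_hyperparameters()` minimizes a noisy objective (by default,
validation misclassification rate) over the tuning space: number of
convolution blocks per Mega Block (integer 1–5, one shared value — the
published per-subject settings always use equal repeats), learning rate
(log-uniform 1e-6–1e-2), momentum (0.6–0.98, SGDM only) and L2
(log-uniform 1e-10–1e-2), with a budget of 30 evaluations.

The surrogate is a zero-mean Gaussian process with Matérn 5/2
covariance on inputs scaled to the unit cube (log scale for rate-like
axes), standardized outputs, and kernel hyperparameters estimated by
marginal likelihood (L-BFGS-B, jitter-and-retry on Cholesky failure).
Acquisitions are expected improvement — the closed-form Gaussian
expectation of max(0, μ(x_b) − f(x)) with the incumbent x_b the lowest
posterior mean over observed points — and probability of improvement
Φ((μ(x_best) − m − μ(x))/σ(x)) with margin m defaulting to the
estimated noise scale. EI is the default; the source work does not say
which acquisition produced its published settings, so both are provided.
Each round maximizes the acquisition over ≥1000 seeded uniform
candidates plus 200 local perturbations of the best point; integer
dimensions round half-up. A failed objective is recorded as the worst
value observed so far and the search continues. After exactly `budget`
evaluations the argmin of *observed* values is returned.

## Evaluation measures

With 11 predictions per trial:

* **CA_gross** — percent of correct windows over all trials × 11
  instances (320 evaluation trials give 3,520 instances).
* **CA_ST** — a trial is correct when ≥6 of its 11 windows are correct
  (11 is odd, so the majority rule needs no tie-break); CA_ST is the
  percent of correct trials.
* **CA_opt** — accuracy per window end time (5.0–7.0 s), maximised over
  the 11 instants; ties resolve to the earliest instant, favouring
  lower feedback latency.

Kappa is the two-class chance-corrected agreement; it is computed over
all window instances for CA_gross and over trial-level majority labels
for CA_ST (the level at which each measure is defined — the source does
not state its choice). `compare_methods()` is the paired two-sided
Wilcoxon signed-rank test with an exact null: `psignrank` when ranks are
untied, full convolution over sign assignments up to n = 20 with ties,
and the tie-corrected normal approximation beyond.

Two experiment drivers assemble everything: `run_intra()` (train
sessions 1–3, test sessions 4–5, per subject) and `run_inter()`
(leave-one-subject-out: train on *all five* sessions of every other
subject, test on the held-out subject's sessions 4–5, with an identifier
audit that training never contains the held-out subject).

## The synthetic ERD generator

Real MI-EEG benchmark recordings must be downloaded from their
distributor, so the package ships a generator that emulates the
statistical structure the decoder relies on, making the entire chain
testable offline:

* background 1/f noise (spectrally shaped white noise, unit variance);
* amplitude-modulated sinusoids at the mu and beta rhythm peaks (10 and
  22 Hz), with per-trial random phase, ~N(0, 0.3 Hz) centre jitter and
  slow sinusoidal amplitude modulation; `snr` sets the mu amplitude
  relative to the noise (beta gets half);
* ERD: during 3–7 s the oscillation amplitude at the contralateral
  channel (C4 for left, C3 for right) is scaled by √(1−erd_depth), with
  250-ms raised-cosine ramps so no analysis window sees a step edge;
* subject variability: each subject's depth is drawn once from a
  lognormal centred (median) on the configured depth with log-sd
  `subject_shift_sd`, clamped to [0, 1];
* sessions of exactly balanced left/right trials; five sessions mirror
  the calibration (1–3) / evaluation (4–5) structure.

The published experiments report no quantitative ERD depth for their
participants, so the default depth (0.5) and the depths used in tests
(0.7 for recovery, 0 for the null) are chosen for *testability*: deep
enough that a correct implementation must separate the classes, and
exactly zero when no class information exists. What passing tests show
is therefore that the chain recovers planted contralateral band-power
structure and never invents structure from noise — not that it attains
any particular accuracy on real recordings, which carry artifacts,
non-stationarity, volume conduction and feedback-dependent dynamics the
generator deliberately omits.

## Problem sizes and numerical choices in the test suite

The recovery experiments run 3 subjects × 5 sessions × 40 trials
(600 trials, 6,600 images): intra-subject fits use the intra network
with Adam (lr 1e-3, batch 64, 5 epochs, L2 1e-4), transfer fits the
Mega Block network with repeats (1,1,1) and 3 epochs. These sizes keep
a full double run (ERD 0.7 and ERD 0) near ten minutes on one CPU while
leaving the planted effect far above the 99% binomial chance bound —
in development runs both protocols saturated at 100% single-trial
accuracy, so the epoch counts are set by compute budget, not by the
difficulty of the recovery. Statistical assertions use fixed seeds and
chance bounds from `qbinom` rather than asymptotic approximations.

Other conventions: window/sample indexing is 0-based and half-open
([start, start+2 s) in samples; segment k starts at sample
750 + 50(k−1) at 250 Hz); spectrogram frames that would overrun the
signal are dropped; min–max normalization maps an all-constant image to
zero; degenerate single-class kappa is defined as 0 with a warning;
zero paired differences are dropped before the signed-rank test.

## Known limitations

* The generator's lognormal subject shift perturbs only ERD depth, not
  spectral shape, noise level or rhythm frequency; transfer learning on
  synthetic data is therefore easier than across real subjects.
* GDF ingestion delegates to a bundled Python/mne converter and is an
  optional interface; only the plain-text fixture format is exercised
  by the test suite.
* The published parameter totals cannot be reconciled with any counting
  convention we audited (see above); shapes, not counts, are treated as
  the architecture ground truth.
* Training is CPU-only and single-threaded beyond BLAS; the engine is
  sized for the 40×32×3 problem, not as a general-purpose CNN library.
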