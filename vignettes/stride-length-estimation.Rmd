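---
title: "Estimating gait stride length from a foot-worn IMU: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gait stride length from a foot-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gaitstride` estimates the length of individual gait strides, in
centimetres, from the six-axis signal of an inertial measurement unit
(IMU) worn on the instep of the right foot. The estimator is a small 1D
convolutional network sized for microcontroller deployment, together
with everything around it: a synthetic signal generator with known
ground truth, file I/O, the signal pre-processing chain, post-training
int8 quantization with a reference integer inference engine, and
Bland-Altman agreement statistics. This vignette explains the science
and the design choices; the README shows the worked example.

## The estimation problem

A *stride* is one full gait cycle of one foot, from an initial contact
(IC, heel strike) to the next ipsilateral IC; its length is the ground
distance covered. Optical or pressure-based reference systems measure
stride length directly but are confined to the lab. A foot-worn IMU
measures triaxial acceleration (within ±16 g) and angular velocity
(within ±1000 °/s) at 128 Hz; stride length must then be inferred from
signal shape. Classical approaches double-integrate the accelerations;
the approach implemented here instead learns a direct regression from a
fixed-length window of one gait cycle to the stride length, which
avoids drift correction entirely and produces a model small enough for
a Cortex-M-class microcontroller.

## Pre-processing chain

The chain is implemented stage by stage in `preprocess_trial()` and
runs strictly in this order (each recording carries stage tags, and
event detection refuses unfiltered input):

1. **Normalisation** (`normalize_recording()`): accelerations are
   divided by the 16 g range and angular velocities by the 1000 °/s
   range, so all channels are dimensionless in [-1, 1]. Division is by
   the full range value, not the half-range.
2. **Resampling to 60 Hz** (`resample_recording()`): an anti-aliasing
   zero-phase Butterworth low-pass (order 4, cutoff 0.45 × target rate)
   followed by cubic-spline interpolation onto the new grid. Output
   length is `round(T × 60/128)`.
3. **Zero-phase low-pass filtering** (`lowpass_zero_phase()`): a
   second-order Butterworth with 10 Hz cutoff, applied forward and
   backward so phase is zero and waveform features keep their timing.
   Edges are padded by odd reflection (at least 3 × order samples, and
   at least two cutoff periods) and the signal is centred on its mean
   before filtering so the filter's zero initial conditions introduce
   no start-up step; unity DC gain is then exact for constants. The
   digital design uses the bilinear transform; its effective
   forward-backward magnitude is |H(f)|² with the prewarped frequency
   ratio tan(πf/fs)/tan(πfc/fs). At 25 Hz and fs = 60 Hz this
   attenuates to ≈ 5.7 × 10⁻⁴ — markedly stronger than the analog
   prototype's 0.025, because 25 Hz sits close to the 30 Hz Nyquist
   limit where bilinear warping compresses the response. This is a
   known property of all standard digital Butterworth implementations,
   and the favourable direction for noise suppression.
4. **Initial-contact detection** (`detect_initial_contacts()`): during
   walking the sagittal-plane angular velocity of the foot (channel
   `gy` by default; configurable, since the sagittal axis depends on
   sensor mounting) shows a large positive mid-swing peak followed by a
   sharp negative trough when the foot strikes the ground. The detector
   finds local maxima above a threshold (0.1 of the gyro range, in
   normalised units) and takes the following local minimum within
   0.6 s as the IC; events closer than 0.6 s resolve in favour of the
   deeper trough; per-event quality is the trough depth relative to the
   threshold, clamped to [0, 1]. A recording with no supra-threshold
   peak yields an empty event list with a warning, not an error.
5. **Segmentation** (`segment_strides()`): one segment per consecutive
   IC pair `[IC_k, IC_{k+1})`. The first measured cycle of every trial
   is removed (motion-initiation artefacts). Cycles longer than the
   fixed window cannot be represented and are discarded and counted —
   truncating them would silently decouple the signal from its label.
6. **Labelling** (`attach_labels()`): each segment is matched to the
   reference stride whose timestamp is nearest its IC time, within
   0.25 s, one-to-one; when two segments contend for one label the
   earlier segment wins. These rules are deterministic and
   conservative; unmatched segments are dropped and counted.
7. **Padding** (`pad_segment()`): trailing zeros bring every axis to
   108 samples = 1.8 s × 60 Hz, keeping the IC-aligned onset at the
   first column.

Splits are always by subject identifier (`split_by_subject()`), never
by stride: strides of one subject are strongly correlated, and a
stride-level split would leak subject identity into the test set.

## The regression network

`model_spec()` defaults to the reference architecture: three Conv1D +
max-pool blocks (32 filters of width 5, 16 of width 5, 32 of width 15),
a 128-unit dense layer, and a linear scalar output. Convolutions use
'same' padding with stride 1; pooling is size 2, stride 2, flooring odd
lengths; activations are ReLU except the linear output. With a
108 × 6 input the sequence shortens 108 → 54 → 27 → 13, the flattened
feature has 416 entries, and the network carries 64 785 trainable
parameters, which `model_summary()` reports and the tests recompute by
brute force. Hidden activations are ReLU — unstated in the lineage this
architecture follows, but the standard choice there.

Training (`train_cnn()`) minimises mean squared error in cm² with Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8), kernel initialisation truncated
normal(0, 0.1) (truncated at ±2 sd), biases constant 0.1. The reference
configuration is batch 64, learning rate 1e-4, 1500 epochs. Targets
stay in centimetres; no target normalisation is applied. There is no
early stopping, weight decay or dropout. Convolutions are evaluated as
im2col gathers feeding BLAS matrix products; backpropagation computes
the input gradient as a 'same' convolution with the offset-flipped,
channel-transposed kernel, so the whole training loop is vectorised R.

`grid_search()` evaluates the hyperparameter grid (batch sizes
{32, 64, 128, 256}, learning rates {1e-3, 1e-4, 1e-5}, filters
{16, 32}, kernels {5, 15}, dense units {128, 256, 512, 1024}) on a
subject-wise hold-out split, selecting the lowest validation MSE with
ties broken by parameter count. Whether filter/kernel values are tied
across the three convolution layers is genuinely ambiguous in the
source material (the grid lists single sets, the selected model differs
per layer), so both modes exist; `per_layer_independent = TRUE`
(3072 grid points) is the default, the tied mode has 192.

`retrain_final()` mirrors the final training phase: a random
stride-level (not subject-wise) 80/20 train/validation division of the
full training set, no further tuning. The 20% validation portion is
kept on the model because it doubles as the representative dataset for
quantization.

## The synthetic cohort: what it emulates and what it does not

No public stride-level dataset ships with the package, so every claim
is exercised on `simulate_trial()` / `make_cohort()`, which emulate the
acquisition conditions of a treadmill study: 15 young healthy subjects,
three speeds each ({0.8, 1.0, 1.2} × a preferred walking speed drawn
from N(3.9, 0.5²) km/h truncated to [3.1, 4.9]; the speed fractions are
an assumption, as the emulated protocol does not state them),
two-minute trials, right-instep sensor at 128 Hz. Subject leg length is
drawn from the anthropometric range 76–95 cm (mean 86.2, sd 4.3) and
sets the preferred stride length (1.5 × leg); cadence then follows from
speed = stride length × cadence, with both scaling as √speed.

The signal model is deliberately minimal — per stride, the sagittal
gyro carries a small toe-off trough (60% of the cycle), a positive
mid-swing Gaussian pulse (80%), and a sharp trough exactly at the next
IC; the vertical accelerometer carries 1 g plus a damped 12 Hz impact
transient at each IC; remaining channels are low-amplitude stride-locked
sinusoids plus AR(1) noise. White sensor noise is a fraction
`noise_sd` (default 0.02) of each range, and stride-period jitter
scales with the same parameter so that a noiseless simulation is
exactly periodic. A slow gyro bias drift (0.5 °/s per minute) is
included.

The load-bearing design choice is the amplitude law
`A = k · (L / 86.2 cm) · cadence` with k = 5: the swing-peak angular
velocity is proportional to the planted stride length L and to
cadence, normalised by the *cohort reference* leg length. Normalising
by each subject's own leg was considered and rejected: leg length would
then enter the label mapping without being observable in the signal,
making stride length unidentifiable for a held-out subject no matter
how good the regressor — the generator's contract is precisely that the
mapping be invertible from the recording (L = A · period · 86.2 / 300).
For the same reason the impact transient has a fixed amplitude: a
leg-scaled impact would be a nuisance covariate inviting spurious
subject-specific shortcuts.

What passing tests on this cohort do **not** show: robustness to real
foot kinematics (no double-pendulum dynamics, no overground turning,
no pathological gait), to sensor calibration error or mounting
variation, or to reference-system noise. The synthetic study validates
the *pipeline* — segmentation, learning capacity, quantization,
statistics — not clinical accuracy.

## The replication study and its configuration

`run_synthetic_study()` is the one-call experiment used by the
reproduction script and the acceptance tests: 15 subjects × 3 speeds,
45-second trials (≈ 1600 strides — the study is scaled to desk
minutes; the emulated protocol's full two-minute trials behave the
same, only slower), subject-wise 12/3 split, reference architecture,
and a 300-epoch training budget. Within that budget the learning rate
follows a two-phase schedule: 250 epochs at 1e-3 (a value from the
search grid) followed by 50 epochs at the reference 1e-4. The rationale
is compute honesty rather than tuning: at 1e-4 alone, 300 epochs is
roughly 6 000 Adam steps, an order of magnitude short of what the
reference configuration (1500 epochs on a larger training set) allows,
and the network only reaches the label mean. The coarse phase learns
the amplitude-to-length mapping; the short fine phase at the reference
rate settles the oscillation the larger step size leaves behind, which
otherwise appears as a ±1 cm global calibration offset visible on the
training set itself. Across the seeds run while developing the package,
held-out results (three unseen subjects, ~300–360 strides) were ME
within ±1 cm, SD between about 2 and 4.5 cm, and R² between 0.93 and
0.98.

## Quantization

`quantize_model()` implements the standard full-integer post-training
path: asymmetric per-tensor int8 activations (scale = (max−min)/255
over the representative dataset, range widened to include zero, zero
point chosen so real 0 is exact), symmetric per-output-channel int8
weights (scale = max|w|/127, so the largest weight maps to exactly
±127 and no clamping occurs), int32 biases at the combined
input × weight scale. Whether the emulated toolchain quantizes weights
per channel or per tensor is not documented; per-channel is the
implemented default because it is the standard modern choice.

`int8_predict()` is a reference integer engine: int8 tensors, exact
32-bit accumulation (checked; integers are represented in doubles,
which is exact far beyond the int32 range), requantization by a
double-precision multiplier with round half to even, ReLU as
max(zero_point, q), max-pooling on the int8 lattice, and a final
dequantization to cm — so its output lives on the output tensor's int8
grid, one LSB apart. A fixed-point integer multiplier would match
deployed kernels more closely but is deliberately not the default: the
double multiplier is bit-exact across platforms, which is what a
reference implementation is for. The engine is tested against an
independent oracle that dequantizes every tensor and redoes the
arithmetic in float: agreement within one output LSB on 100% of
random networks.

`export_c_array()` emits the weights as C99 `const int8_t` arrays with
scales and zero points, plus a transparent memory estimate: flash =
weights + biases + scale/zero-point constants; RAM = the peak of a
ping-pong two-buffer activation schedule. These are arithmetic
estimates of the model data, not toolchain measurements, and are never
compared against any device figure.

On the synthetic study the int8 model's held-out MSE tracked the
float32 model's closely (about 1% relative difference at seed 1, where
the float MSE was ≈ 19 cm²). The absolute quantization noise is roughly
constant (≈ 0.5 cm RMS from per-tensor activation grids), so for seeds
where the float model happens to fit the synthetic task much better
(MSE ≈ 4 cm²) the same noise shows up as a relative MSE change of up to
~17% — a property of the relative metric, not a degradation of the
quantizer.

## Agreement statistics

`bland_altman()` uses differences d = estimate − reference (positive
bias = overestimation; the direction is a package convention), bias
ME = mean(d), SD with n−1, limits of agreement ME ± 1.96·SD (fixed
multiplier, no t correction), and MDC = 1.96·SD — the definition
consistent with the arithmetic of the agreement tables this package
reproduces; √2-SEM variants are not used. R² is the coefficient of
determination against the evaluation set's reference variance, and is
undefined (NA) when that variance is zero. Every report asserts its own
invariants on construction, including mse ≥ me² and the exact identity
mse = me² + (n−1)/n · sd².

`loso_cv()` implements leave-one-*subject*-out cross-validation (the
only consistent reading for a 15-subject cohort): each fold retrains on
all other subjects and predicts the held-out subject's strides; fold
seeds derive from one master seed; the pooled report is computed over
all held-out predictions.

## Numerical and degenerate-input choices

* All randomness flows from one master seed; per-subject, per-trial and
  per-fold substreams are derived by a deterministic string hash, so
  cohorts are reproducible file-for-file and subject streams do not
  depend on enumeration order.
* Max-pool ties take the earlier sample; label-matching ties take the
  earlier segment; grid-search ties take the smaller model.
* Out-of-range samples in input files are clipped to the declared range
  (real IMUs saturate) and counted in a warning.
* An all-zero weight tensor gets a floored quantization scale (1e-8)
  with a warning, and biases that would overflow int32 at a degenerate
  scale are saturated with a warning.
* Fewer than two detected ICs, an empty event list, or an unlabelable
  segment are warnings plus empty results; schema violations, negative
  stride lengths, decreasing timestamps and overlapping split ids are
  errors.

## Known limitations

* The synthetic generator is a feature-level emulation, not a
  biomechanical simulation; transfer of the trained network to real
  IMU data is untested here by construction.
* Stride length for a held-out subject is identifiable only because the
  generator plants it so; with real anthropometric confounds a
  per-subject calibration or richer cues would be needed.
* The filter's digital response deviates from the analog Butterworth
  prototype near Nyquist (see above) — irrelevant below ~15 Hz at
  60 Hz sampling, where all gait features live.
* `loso_cv()` retrains one network per subject; on a 15-subject cohort
  that is 15 full trainings and is meant for scaled-down studies or
  injected mock trainers in tests.
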