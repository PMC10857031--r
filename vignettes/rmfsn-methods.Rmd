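---
title: "Residual multifeature fusion shrinkage networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual multifeature fusion shrinkage networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmfsn)
```

## The problem and the model

Wearable-sensor human activity recognition classifies short fixed-length
windows of multichannel inertial signal (tri-axial accelerometer and
gyroscope traces) into activity classes. Activities differ in oscillation
amplitude and frequency — jogging swings harder and faster than walking;
sitting and standing barely oscillate at all and differ mainly in static
posture offsets — and subjects differ systematically from one another, which
is why honest evaluation must hold out whole subjects.

The network implemented here is a residual multifeature fusion shrinkage
architecture. A window $x \in \mathbb{R}^{C \times T}$ is embedded by a stem
1-D convolution into $F$ feature channels, and the $F \times T$ map feeds
three branches whose outputs are summed:

* **Temporal branch.** Two stacked GRU layers treat the $F$ channels as the
  per-timestep input vector, with hidden size $F$. The gates follow the
  classic formulation with the reset gate applied *before* the candidate
  matrix product:
  $$r_t = \sigma(W_r[x_t, h_{t-1}] + b_r), \quad
    z_t = \sigma(W_z[x_t, h_{t-1}] + b_z),$$
  $$n_t = \tanh(W_n[x_t,\; r_t \odot h_{t-1}] + b_n), \quad
    h_t = (1 - z_t) \odot n_t + z_t \odot h_{t-1}.$$
  The trainable layer stores an input-side and a hidden-side bias per gate
  (the two only ever enter as a sum; `gru_step()` exposes the single-bias
  form, and the test suite verifies the batched layer against it). A
  lightweight temporal attention follows: a kernel-1 convolution collapses
  each timestep's channel vector to one score $c_i$, $a = \mathrm{softmax}(c)$
  over timesteps, and timestep $i$ is scaled by $a_i$. Because multiplying by
  a probability shrinks the sequence norm by roughly $1/T$, the scaled
  sequence is multiplied back by $T$ (`attention_scale = "n"`, the default;
  `"none"` disables the rescale).
* **Multi-scale branch.** Four dilated 1-D convolutions with dilation rates
  $(1, 2, 4, 6)$, kernel sizes $(k_1, k_1, k_2, k_2)$ from the configured
  pair, each as Conv(no bias)–BatchNorm–ReLU. The stack's receptive field
  follows $r_i = r_{i-1} + d_i (k - 1) \prod_{n \le i} s_{n-1}$
  (`receptive_field()`), and the test suite confirms the measured
  impulse-response support of the real stack equals the formula. This branch
  consumes the sum of the stem features and the temporal branch's output, so
  multi-scale filters see temporally re-weighted features.
* **Convolutional branch.** Two residual blocks of pointwise
  (kernel-1) Conv(no bias)–BatchNorm–ReLU pairs with identity skips. The
  pointwise choice is deliberate: the other two branches own the temporal
  structure, this branch mixes channels instantaneously, and — decisively —
  it is the only residual-branch width at which the published
  trainable-parameter totals of all three reference configurations can be
  met exactly (see the next section).

The fused map enters the **channel-attention shrinkage block**: global
average pooling gives $Z_k = \frac{1}{L}\sum_i x_{k,i}$; a bottleneck MLP
$\alpha = \sigma(W_2\,\mathrm{ReLU}(W_1 Z + b_1) + b_2)$ gives per-channel
weights in $(0,1)$; thresholds are $\tau_k = \overline{|Z|}\,\alpha_k$, so
$0 \le \tau_k \le \overline{|Z|}$ by construction; and the map is shrunk
elementwise by the standard soft-thresholding operator
$S(x, \tau) = \mathrm{sign}(x)\max(|x| - \tau, 0)$. (A shrinkage operator
must contract: the occasionally seen variant $\mathrm{sign}(x)(x + \tau)$
for $x > \tau$ expands magnitudes instead, so the standard contracting form
is used.) As $\alpha \to 0$ the thresholds vanish and the block degenerates
to its identity pass-through, which is also exactly how the `enable_casb`
ablation flag bypasses it.

The **classifier head** concatenates global average and global max pooling
over time ($2F$ values), applies one hidden FC layer with ReLU and dropout,
then an FC layer to the classes and a softmax.

## Resolving the two unpublished widths

The reference configurations of this architecture publish the input
geometry, filter count, stem kernel, dilated kernel pair, dilation rates,
depths, and the total number of trainable parameters — but not the
classifier's hidden width (`fc_width`) nor the squeeze-excitation bottleneck
(`se_width`). The package treats the published totals as a hard constraint
and solves for the two missing integers. With $F$ filters, $C$ input
channels, stem kernel $q$, dilated kernels summing to $K = 2k_1 + 2k_2$,
$R$ residual blocks, $m$ classes, bottleneck $h$ and hidden width $w$, the
total is

$$\underbrace{FCq}_{\text{stem}}
 + \underbrace{2\,(6F^2 + 6F)}_{\text{GRUs}}
 + \underbrace{F + 1}_{\text{attention}}
 + \underbrace{F^2 K + 8F}_{\text{dilated + BN}}
 + \underbrace{2R\,(F^2 + 2F)}_{\text{pointwise residual + BN}}
 + \underbrace{2Fh + h + F}_{\text{excitation}}
 + \underbrace{(2F + 1)\,w + (w + 1)\,m}_{\text{head}}.$$

For the first two reference geometries the solution $(h, w)$ is *unique*
over the positive integers — (28, 869) and (4, 979) — and for the third,
several pairs exist and the profile fixes the one whose bottleneck is
closest to the customary $F/4$ reduction, (24, 175). The derivation note
travels inside each shipped YAML profile, and `parameter_ledger()` makes the
accounting auditable tensor by tensor; an independent closed-form recount is
asserted in the test suite, and `scripts/acceptance.R` recomputes the three
totals from the instantiated models at run time. Residual-branch width is
the one point where a plainer reading (stem-width residual kernels) was
tried and rejected: it overshoots the third configuration's published total
before the classifier is even attached, so no choice of $(h, w)$ can close
the ledger.

## Preprocessing

* **Missing samples** are filled per channel by linear interpolation between
  the nearest observed neighbours; leading/trailing gaps take the nearest
  observed value (pure interpolation is undefined there). The operation is
  idempotent and never touches observed samples.
* **Body/gravity separation** uses a low-pass Butterworth filter
  (default cutoff 0.3 Hz, order 3 — the de-facto convention for this sensor
  family; both exposed) applied forward-backward for zero phase. The filter
  *design* comes from the `signal` package; the zero-phase *application* is
  implemented here, because plain `signal::filtfilt` applies no edge
  handling and visibly distorts exactly the near-DC content this step is
  meant to isolate. The implementation runs a direct-form-II-transposed pass
  with steady-state initial conditions and symmetric-reflection padding over
  the whole recording. Symmetric (even) reflection matters: odd reflection
  mirrors the signal about its endpoint *value*, which injects a step the
  size of that value — a 0.3 Hz low-pass passes such a step happily, and a
  test tone at 10 Hz then leaks percent-level energy into the "gravity"
  output. With even reflection the leak is at the $10^{-5}$ level and
  constants reconstruct to $10^{-11}$. `body + gravity` equals the input to
  floating-point accuracy by construction.
* **Standardization** is per-channel $(x - \mu)/s$ with statistics from
  training data only; standard deviations below $10^{-8}$ are floored so
  constant channels map to zero.
* **Windowing** starts windows at $0, \Delta, 2\Delta, \dots$ with
  $\Delta = \max(1, \mathrm{round}(w(1 - \text{overlap})))$, giving
  $\lfloor (N - w)/\Delta \rfloor + 1$ windows. Per-sample labels resolve by
  majority vote, ties broken by the window's last sample; windows whose
  majority is the designated null/background class are dropped.
* **Dataset readers** cover the three public layouts (fixed-width inertial
  signal files; raw comma-separated accelerometer logs with malformed-line
  and duplicate-timestamp cleaning; space-separated wide sensor tables).
  The wearable-channel column subset for the third layout is not enumerated
  in its published description; the packaged `opportunity_columns.json`
  follows the standard selection used by that dataset's deep-learning
  baselines and is explicitly marked a reconstruction.

Convolution padding is computed internally to preserve sequence length
(left pad $d\lfloor (k-1)/2 \rfloor$, remainder right), so a "centre" tap
exists for even kernels too; the configured padding tuple is carried as
documentation but not used for arithmetic — parameter counts are unaffected
by padding.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the network
exploits, not biomechanics: each activity is a per-channel amplitude vector
times a sum of harmonics of a base frequency (walking 2.0 Hz, jogging
2.8 Hz at strictly larger amplitude, upstairs 1.4 Hz, downstairs 1.7 Hz)
with uniform random phase per window; sitting and standing are static
profiles distinguished only by opposite per-channel offsets, deliberately
confusable the way they are in real data. Per-subject log-normal
multipliers on amplitude and frequency (sd 0.08) create the between-subject
variation that makes LOSO non-trivial; additive Gaussian noise (sd 0.15 in
sensor units against order-1 amplitudes) plays the role of sensor noise.
The default geometry mirrors the smallest reference configuration:
3 channels, 100-sample windows at 20 Hz, 4 subjects, 10 windows per class
per subject. One seeded random stream is consumed in a fixed order
(subjects, then classes, then windows), so datasets are bit-reproducible.
With `missing_rate > 0` the generator instead emits continuous raw
recordings with Bernoulli missing masks so the preprocessing chain can be
exercised end to end.

What passing tests on this generator do **not** show: robustness to
non-stationary activity transitions inside a window, sensor drift and
orientation changes, class imbalance, or real gait harmonics — real-data
conclusions still require the public datasets, whose readers the package
provides but whose downloads its tests never require.

## Training and evaluation

Training minimizes multinomial cross-entropy with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) over shuffled
mini-batches for a fixed number of epochs (no early stopping). All
randomness — initialization, shuffling, dropout — derives from the training
seed. Initialization is uniform fan-in, except the output FC layer, which
starts one order of magnitude smaller so that an untrained network predicts
near-uniform probabilities (initial loss $\approx \log m$); the test suite
asserts this. Batch normalisation uses batch statistics during training and
exponentially tracked running statistics (momentum 0.1) at inference;
running statistics are buffers, never counted as parameters.

Leave-one-subject-out is the primary protocol: fold $s$ tests only subject
$s$ and trains on the rest, each fold re-initialized from a fold-indexed
seed, with mean and standard deviation over folds reported for every
statistic. Stratified ratio and k-fold splits are provided as comparators;
they split at the window level, so overlapping neighbour windows can land
on both sides — the neighbourhood bias that motivates LOSO — and are
documented as such. Stratified assignment uses per-class floor allocation
with largest-remainder distribution guided by the global group targets, so
per-class and overall proportions are honoured simultaneously.

Metrics come from the pooled confusion matrix: one-vs-rest precision,
recall and F1 per class, overall accuracy, and macro (unweighted) averages,
with support-weighted averaging available. Zero-denominator classes score 0
and raise a report flag so macro averages stay defined. The implementation
is cross-checked in the tests against `caret::confusionMatrix` to
$10^{-9}$ on randomized matrices.

The ablation runner evaluates the six canonical configurations (without the
shrinkage block C, temporal branch T, multi-scale branch M, without T and
M, without all three, and the full model) under one protocol and seed. A
disabled block is bypassed with the identity on its input, so the baseline
is the stem plus the residual branch and the classifier. The
channel-selection heatmap records, per window, either post-shrinkage
magnitudes or the binary survival mask $|x| > \tau$ per feature channel and
timestep (both are offered since either convention is found in practice).

## Problem sizes used by the shipped tests

The test suite trains a width-16 model (fc width 32, bottleneck 4, ~8.8k
parameters) for 20 epochs with Adam at $2 \times 10^{-3}$ on the default
240-window synthetic dataset for the end-to-end LOSO check, and smaller
width-4/6/8 models on 20–36-window datasets for plumbing checks; gradient
correctness is verified by central finite differences at randomly chosen
scalars in every tensor family. These sizes were chosen as the smallest at
which the end-to-end claims are meaningful (the noiseless spectral-centroid
oracle separates the synthetic classes perfectly, so a trained network is
expected to clear 95% LOSO accuracy under the default noise and jitter).

## Known limitations

* The exact wiring of the reference architecture between its published
  equations is not fully recoverable; the fusion rule (sum), the
  multi-scale branch's input (stem + temporal output) and the pointwise
  residual branch are this package's documented readings, chosen for
  coherence and for exact parameter-ledger agreement.
* Second-order-section filtering is not implemented; for the very low
  normalized cutoffs used here the transfer-function form with full-length
  reflection padding was measured adequate (stopband leak $\sim 10^{-5}$),
  but extreme cutoff/order combinations may lose precision.
* Training is pure R on CPU. It is comfortable at the shipped problem
  sizes; the full public-dataset configurations (hundreds of thousands of
  parameters, tens of thousands of windows, 100 epochs) are supported but
  slow — expect hours, not minutes.
* The GRU depth is fixed at two layers, matching every reference
  configuration.
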