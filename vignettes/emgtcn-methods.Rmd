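---
title: "Temporal convolutional sEMG classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal convolutional sEMG classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgtcn)
```

## The problem

Surface electromyography (sEMG) measures the electrical activity of
forearm muscles with skin electrodes. In myoelectric control, a
multichannel sEMG recording of a hand gesture must be mapped to a gesture
label, both offline (the whole repetition is available) and in real time
(samples arrive one by one and a decision is wanted within a few hundred
milliseconds). `emgtcn` implements a sequence classifier for this task — a
temporal convolutional network (TCN) — together with the augmentation,
evaluation and real-time simulation machinery needed to study it on
Ninapro-DB1-structured data (10 electrode channels at 100 Hz, 52 gestures
plus rest, 10 repetitions per gesture and subject).

## The model

An input sequence is $x \in \mathbb{R}^{N \times C}$. The network stacks
$L$ residual blocks. Block $l$ applies one causal dilated convolution with
kernel length $2p + 1$ and dilation $d_l$:

$$y^{l+1}_{n,k} = \sum_{j=0}^{K_l-1} \sum_{i=0}^{2p} y^l_{n - d i,\, j}\, h_{i,j,k},$$

with zeros for indices before the sequence start (left zero-padding, never
look-ahead), so every layer maps length $N$ to length $N$ and output $n$
depends only on inputs at or before $n$. The dilation doubles after every
convolutional layer, $d_l = 2^{l-1}$, continuing across block boundaries.
The receptive field after $L$ layers follows the recursion
$RF_l = RF_{l-1} + 2 p\, d_l$, $RF_0 = 0$: with $p = 1$, four layers give
30 samples (300 ms at 100 Hz) and seven give 254 samples (nominally the
"2500 ms" long-RF variant; the recursion gives exactly 2540 ms, and the
package always reports the exact value).

Each block computes `shortcut(x) + dropout(relu(conv(x)))`. The shortcut
is the identity when the width is unchanged and a dilation-1, kernel-1
convolution otherwise. We place exactly one convolution per block, so the
advertised layer counts of the two standard configurations
(`db1_tcn_config()`) are literal convolution counts. The kernel half-width
is fixed at $p = 1$ (length-3 kernels) because that is the unique value
for which the recursion yields 300 ms for the 4-layer model; per-layer
filter counts are free parameters chosen so total sizes land in the tens
of thousands of weights.

Two pooling heads turn the last feature map $y^L$ into a label
distribution over the $G$ classes:

* **AoT** (average over time): $s = \frac{1}{N}\sum_n y^L_n$, then
  $\hat{o} = \mathrm{softmax}(s W_o + b_o)$.
* **Att** (attention): $v = \tanh(y^L W_a + b_a)$,
  $a = \mathrm{softmax}(v\, u_a)$ over valid timesteps,
  $s = \sum_n a_n y^L_n$, then the same output layer. With $u_a = 0$ the
  attention collapses to the uniform distribution and the head reproduces
  AoT exactly — a property the test suite asserts to floating tolerance.

Batches are zero-padded to a common length with a validity mask. Because
convolutions are causal, tail padding cannot influence valid timesteps;
the heads use masked reductions (the masked mean divides by the valid
count, the masked softmax assigns $-\infty$ logits to padded steps), so a
sequence's padded-batch output equals its solo output. Dropout
(default rate 0.05, appended after each convolution) is active only
during training; inference is deterministic.

## Augmentation

Repetition-based splits leave only $53 \times 7 = 371$ training sequences
per subject, so the training set is expanded tenfold by three stochastic
operators applied in the order WD → MW → GN (amplitude noise last, so the
target SNR is measured against the already-warped signal):

* **Wavelet decomposition (WD)** — per channel, a multilevel periodized
  orthogonal DWT (sym4 by default); the detail coefficients of the
  selected level are scaled by $1 + U(-b, b)/10$ (one factor per channel
  and level); inverse transform; truncation to $N$. Wavelet, level and
  $b$ are sampled per application from `{sym4}`, `{2, 3, 4}` and
  `{0, 2.5, 5}`, applied with probability 0.75. The literature this
  scheme descends from states only the hyperparameters, not the
  perturbation law; the multiplicative-detail form above is this
  package's documented choice, kept behind `augmentation_config()` so
  alternatives can be swapped in. The DWT itself is implemented in the
  package (no R wavelet dependency): with orthonormal filters, periodic
  boundary handling and signals zero-padded to even length at every
  level, single-level analysis is an orthogonal map whose transpose is
  the exact inverse, so the `b = 0` round trip reproduces the input to
  machine precision.
* **Magnitude warping (MW)** — each channel is multiplied by a smooth
  random gain: a natural cubic spline through knots drawn from
  $\mathcal{N}(1, \sigma^2)$ at five evenly spaced positions (spacing
  about $N/4$); $\sigma = 0.2$, probability 0.75.
* **Gaussian noise (GN)** — additive white noise scaled per channel over
  the whole sequence so that
  $10 \log_{10}(P_\text{signal}/P_\text{noise})$ equals the target
  (30 dB), probability 0.25.

Copy 1 of the expanded set is the untouched originals; all operators
preserve shape, label, repetition and subject, and the whole expansion is
a deterministic function of the configuration seed.

## Training and offline evaluation

`tcn_train()` minimizes class-weighted cross-entropy (weights inversely
proportional to per-label sequence counts, normalized to mean 1 — the
mean-1 convention is ours; only proportionality is prescribed) with Adam
at a constant learning rate of 0.01, batch size 128, for up to 100
epochs. The early-stopping criterion is not prescribed anywhere, so the
package adopts: hold out 10% of training sequences stratified by label,
monitor validation loss, stop after 10 stale epochs, restore the best
weights. Training is single-threaded deterministic given the seed. A
sliding-window mode (window 20 samples, step 1) trains on 200 ms segments
instead of full repetitions, matching the real-time input length; the
model is length-agnostic, so window-trained models still evaluate on full
sequences.

Offline metrics are class-weighted top-1/top-3 accuracies and a
$G \times G$ confusion matrix; top-k ties break towards the lowest label
id (documented, deterministic). For attention models,
`extract_attention_profile()` linearly resamples each repetition's weight
vector to the gesture's median duration, renormalizes to sum 1 and
averages, recording the peak time.

## Real-time simulation and the vote classifier

`simulate_stream()` reproduces the streaming protocol: iteration 0 feeds
only $x_0$; while the 200 ms buffer (20 samples at 100 Hz) fills, all
samples so far; afterwards the most recent 20 — one prediction per input
sample. The vote post-classifier counts label occurrences in a trailing
analysis window of $w$ ms and emits the label whose count is maximal and
at least $\tau$, else $-1$ ("no gesture"). The source material states the
operating point once as "$w$ and $\tau$ were set to 12 and 300 ms" and
once as "$w = 300$ ms and $\tau = 12$"; only the latter is dimensionally
consistent ($\tau$ is a count, $w$ a duration), so that is the default.
Three further choices are under-specified and resolved as follows:

* **Ties** (two labels at the maximal count $\ge \tau$): the label whose
  $\tau$-th most recent occurrence is latest wins — most recent evidence,
  deterministic.
* **Which vote scores a repetition**: the first decisive vote
  ($\Psi \neq -1$), consistent with the response-time definition; the
  modal vote is reported as a secondary metric.
* **Response time** is measured from the first iteration of the analysis
  window current at the first decisive vote.

`grid_search_wt()` evaluates accuracy and mean response time over
$w \in \{0.3, \ldots, 2.0\,\mathrm{s}\}$ and $\tau \in \{10, \ldots, 80\}$
by default, skipping infeasible cells ($\tau$ exceeding the window in
samples). `attention_correlation()` computes the Pearson coefficient
between attention-peak times and times to the first correct prediction,
erroring below 3 pairs and returning `NA` with a warning under zero
variance.

## Synthetic data

Real DB1 records require a download, so `generate_dataset()` emulates the
database's structure: per subject, every label 0..52 (0 = rest) appears
with repetitions 1..10. Each gesture owns a fixed per-channel amplitude
pattern drawn once; a raised-cosine rise–hold–fall envelope built from it
modulates band-limited Gaussian noise (20–45 Hz — the dominant portion of
sEMG power representable at 100 Hz sampling), on top of a baseline noise
floor; repetitions jitter amplitude (±5%) and duration (±10% around a
5 s mean, so attention profiles live on a 0–5 s axis as on real data).
Rest is noise floor only. The `difficulty` parameter blends gesture
patterns towards their common mean: 0 gives well-separated classes for
recovery tests, 1 makes classes indistinguishable. Class identity is
carried by amplitude envelopes, not phase — mirroring how RMS-like
features discriminate gestures in practice.

What the generator deliberately does **not** model: motor-unit action
potentials, electrode crosstalk with realistic spatial correlation,
inter-subject variability of electrode placement, label noise at gesture
onsets. Passing recovery tests on this data therefore demonstrates that
the pipeline is implemented correctly and can fit separable
envelope-coded classes — not that the published DB1 accuracies are
reproduced, which would require the real recordings.

## Problem sizes and numerical choices

The test suite and worked examples run at desk scale by design: recovery
training uses 8 gestures + rest, 10 repetitions, 1.5 s sequences and a
4-layer, 16-filter TCN (a few seconds of CPU); structural checks of the
53-class layout use 1 s sequences. Tolerances: padded-vs-solo agreement
is asserted at $10^{-6}$, wavelet reconstruction at $10^{-8}$, analytic
gradients against central finite differences at $10^{-6}$, hand oracles
at $10^{-12}$. Degenerate inputs are errors, not silent results:
all-masked batches, all-zero signals for SNR, $\tau$ larger than the
analysis window, absent labels in weight computation.

## Known limitations

* Training is plain R with BLAS matrix kernels: ample for the package's
  study sizes, not for full 27-subject DB1 sweeps.
* The WD/MW perturbation laws are faithful to the published
  hyperparameters but their exact stochastic form is this package's
  choice (see above).
* The long-RF configuration reports its exact receptive field (2540 ms),
  not the nominal 2500 ms.
* `read_db1_record()` reads the delimited-text record layout; MATLAB
  container files must be exported to text first (the layout and key
  dialects — `stimulus`/`restimulus`, `repetition`/`rerepetition` — are
  accepted as-is).
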