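---
title: "Multi-view brain-network sleep staging: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view brain-network sleep staging: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the signal model, every tunable that matters, the numerical choices made
where the design was genuinely open, and what the synthetic benchmark does
and does not demonstrate.

## The model

Each 30-s epoch of 8-channel EEG (F3, F4, C3, C4, T3, T4, P3, P4 at
100 Hz after preprocessing) is summarized as a stack of 8×8 functional
connectivity matrices ("views"), one per (measure, band) pair. Five
measures cover three complementary notions of coupling:

* **Linear temporal correlation** — the Pearson coefficient (PCC),
  bounded in [−1, 1], sensitive to amplitude covariation at zero lag.
* **Information-theoretic dependence** — mutual information (MI) of the
  two channels' amplitude distributions, estimated with a 16-bin
  equal-width joint histogram, in bits. The plug-in histogram estimator is
  biased upward for finite samples; with 3000 samples per epoch and 256
  joint cells the bias is a few hundredths of a bit and, crucially,
  common to all channel pairs, so it shifts but does not reorder the
  matrix.
* **Phase dynamics** — from each channel's analytic-signal (Hilbert)
  instantaneous phase, the wrapped pairwise difference Δφ(t) feeds three
  statistics: the phase-locking value PLV (modulus of the mean unit
  phasor), the phase-lag index PLI (absolute mean sign; blind to zero-lag
  coupling and hence to simple volume conduction), and a phase-instability
  index PSI (mean absolute wrapped first difference of Δφ). This PSI is
  the mean absolute derivative of the phase difference — a volatility
  measure, zero for a constant lag — and is deliberately *not* the
  classical phase-slope index, whose name it shares; it is implemented
  exactly as the model defines it.

The classifier applies, per view, a trainable 8×8 weight matrix
elementwise, a ReLU, and a softmax over the view's 64 entries
("data-driven attention"; each view then sums to 1), followed by three
convolution layers (16@3×3, 32@3×3, 64@2×2, stride 1, no padding, each
with ReLU) and five linear layers 576/256/128/64/n, trained with Adam on
cross-entropy. On an 8×8 input the conv stack's spatial maps are
6×6 → 4×4 → 3×3, so the flatten width is 64·3·3 = 576. (A published
description of this architecture tabulates a flatten width of 1152, which
is inconsistent with its own conv shapes; the conv arithmetic is taken as
authoritative here.) ReLU is used between the linear layers: without an
activation a five-deep linear stack collapses to a single linear map, and
the conv arithmetic only fixes the layer widths, not the head's
nonlinearity.

### Channel masking

Electrode dropout is emulated by an 8×8 all-ones matrix with the masked
channels' rows and columns set to zero, multiplied elementwise into every
view **before** the attention step. Applying the mask to the connectivity
matrices themselves (rather than after the attention softmax) is the only
order under which masked channels provably cannot influence the output:
the softmax couples all 64 entries of a view, so a mask applied after it
would still let masked entries shift the normalization of unmasked ones.
With mask-first, logits are exactly invariant to arbitrary perturbation of
masked channels' data, and the loss gradient with respect to masked tensor
entries is identically zero — both are asserted in the test suite.

### The default view set

The architecture consumes 10 views, but 5 measures × 5 bands would give
25 candidates; the published description does not enumerate its 10. This
package's default (`view_spec()`) is all five measures on the broadband
(0.3–35 Hz) signal plus all five on the delta band, on the grounds that
delta activity dominates neonatal EEG. The view set is fully
configurable — any (measure, band) list can be passed — so other
combinations are one argument away. Two caveats are documented rather
than hidden: instantaneous phase on a broadband signal is only weakly
defined (the analytic-signal phase of a multi-component signal mixes
components), and MI/PSI are unbounded, so those views are min–max
normalized to [0, 1] per view by default to keep all views on a
comparable scale for the shared attention/conv stack.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| band-pass | 0.3–35 | Hz | clinical neonatal EEG band |
| notch | 50, Q = 30 | Hz | powerline; ~1.7 Hz wide biquad |
| filter order | 5 (one-pass) | — | Butterworth, applied forward–backward (zero phase, magnitude order doubles) |
| working rate | 100 | Hz | halves of data volume; β band (≤30 Hz) still below Nyquist |
| epoch length | 30 | s | sleep-scoring unit |
| MI bins | 16 | — | 256 joint cells vs 3000 samples per epoch |
| views | 10 | — | 5 measures × {broadband, delta} |
| learning rate | 1e-3 | — | Adam default scale |
| iterations | 150 | passes | training budget; loss typically plateaus ~30 passes then drops sharply |
| batch size | 64 | epochs | memory/SGD-noise compromise |
| class weights | off | — | synthetic study is balanced by construction |

## Numerical choices

* **Zero-phase filtering** uses forward–backward application with
  odd-reflection edge padding (3 time constants of the slowest pole), so
  start-up transients decay inside the discarded padding. "5th order"
  refers to the one-pass design; the effective magnitude response is
  10th order.
* **Filtering precedes epoching**: filters run over the whole recording,
  so epochs carry no per-epoch filter transients. Notch and band-pass are
  LTI and zero-phase, so their order is irrelevant; notch runs first. For
  recordings already at 100 Hz the 50 Hz notch center sits at Nyquist and
  the notch is skipped with a message.
* **Down-sampling** is spectrum-truncation resampling: FFT, discard bins
  above the new Nyquist, inverse FFT at the new length. DC and all
  in-band tones are preserved essentially exactly; out-of-band content is
  removed rather than aliased. Classical decimation filters (e.g. an
  8th-order Chebyshev or a short FIR) attenuate appreciably below the new
  Nyquist — at 40 Hz against a 50 Hz Nyquist they lose more than 10% —
  which this choice avoids.
* **Degenerate inputs**: a constant channel has no defined correlation —
  PCC returns 0 with a warning; a constant vector collapses into one MI
  bin (MI 0); `sign(0) = 0` in the PLI. Diagonals use the measures'
  self-value conventions (PCC 1, PLV 1, MI 0, PLI 0, PSI 0) so that
  unbounded self-information never dominates the attention softmax.
* **Phase wrapping**: Δφ and the PSI's first differences are wrapped to
  (−π, π] before use.
* **Initialization**: attention weights start at all ones (the initial
  attention output is then just the normalized networks); conv/linear
  layers draw from U(−1, 1)/√fan-in. All randomness — initialization,
  batch shuffling, data generation — derives from user-supplied seeds,
  and training is bit-reproducible given the seed.
* **Attention softmax axis**: "view-level normalization" is read as a
  softmax within each view over its 64 entries (each view sums to 1).
  Normalizing across views per entry would tie the views' scales
  together; it is not what a per-view weight matrix suggests, and is not
  provided.

One invariance that does *not* hold, deliberately documented: jointly
permuting channel order in the data, the attention weights and the mask
leaves the attention+mask stage exactly equivariant (this is tested), but
not the logits — a row/column permutation of an 8×8 image is not a
translation, and a 3×3 convolution is not equivariant to it. The channel
order is therefore part of the model definition, fixed to the canonical
montage order.

## The synthetic benchmark

Clinical neonatal recordings cannot be shipped. The generator emulates
the one property the model consumes — stage-dependent cross-channel
coupling:

* **QS-like** epochs share a 2 Hz oscillator within (F3,F4) and (C3,C4);
* **AS-like** epochs share a 6 Hz oscillator within (T3,T4) and (P3,P4);
* **W-like** epochs have no coupled pairs and extra β-band noise.

Every channel receives independent 1/f^0.8 noise (spectrally shaped white
noise); the oscillator enters both channels of a pair with mixing weight
a (default 0.9) against noise amplitude 0.3, scaled to ~30 µV. Each
subject carries deterministic frequency (±10%) and amplitude (±20%)
jitter so leave-one-subject-out validation is not trivially easy. The
standard study is 6 subjects × 60 epochs per class.

These templates are test fixtures, not physiological claims: no trace
alternant, no delta brushes, no artifacts, no inter-rater ambiguity. A
perfect LOSO score on this benchmark therefore demonstrates that the
pipeline — filters, connectivity estimators, attention, CNN, training
loop, evaluation protocol — is wired correctly and can recover coupling
structure through subject variability; it says nothing about accuracy on
clinical data, where reported accuracies for methods of this class are in
the 0.7–0.85 range. The shuffled-label control (LOSO accuracy at chance
when labels are permuted) guards against information leaking through the
evaluation protocol itself.

Problem sizes used by the test suite and the acceptance script — 6
subjects, 180 epochs each, 150 training iterations, three seeds — were
chosen as the package's standard study conditions; smaller configurations
appear in unit tests only to exercise interfaces.

## Known limitations

* Only undirected connectivity; no directed/effective measures (Granger,
  transfer entropy) and no volume-conduction correction beyond what PLI
  itself provides.
* The conv stack is hard-wired to 8 channels (kernel arithmetic
  8 → 6 → 4 → 3); other montages require reordering/subsetting to the
  canonical eight.
* Histogram MI on 30-s epochs is biased; comparisons are meaningful
  within an epoch's matrix, not across recordings with very different
  amplitude distributions (the per-view min–max normalization mitigates
  this).
* The EDF reader supports the plain-EDF subset it writes (equal-duration
  records, one rate per signal, no embedded annotation streams); stage
  labels travel in plain-text sidecar files.
* Epoch exclusion emulates manual artifact rejection by index lists plus
  an optional amplitude criterion (|x| > 500 µV or a flat channel,
  off by default); no automated artifact detection is attempted.
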