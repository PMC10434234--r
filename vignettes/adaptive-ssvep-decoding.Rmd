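---
title: "Adaptive SSVEP decoding: model, implementation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SSVEP decoding: model, implementation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepuac)
```

## The decoding model

An SSVEP epoch is a channels × samples matrix $X \in \mathbb{R}^{N_c \times
N_t}$ recorded while the user gazes at one of $N_f$ targets flickering at
known frequencies $f_1 < \dots < f_{N_f}$. Decoding rests on canonical
correlation analysis: for a harmonic reference
$$Y_f = \big[\cos 2\pi f t;\ \sin 2\pi f t;\ \dots;\ \cos 2\pi k f t;\
\sin 2\pi k f t\big],\qquad t = \tfrac{1}{f_s}, \dots, \tfrac{N_s}{f_s},$$
the statistic $\rho(X, Y_f) = \max_{w_X, w_Y}\ \mathrm{corr}(w_X^\top X,
w_Y^\top Y_f)$ measures how much of the epoch's subspace oscillates at $f$
and its harmonics.

**FBCCA** refines this with a filter bank: $D$ band-pass copies
$X_{SB,1..D}$ are scored separately and combined as
$$\tilde\rho_f = \sum_{d=1}^{D} w(d)\,\rho^2_{SB,d}, \qquad
w(d) = d^{-a} + b,$$
down-weighting the higher sub-bands in proportion to the decaying harmonic
energy of real SSVEPs. The decision is $\arg\max_f \tilde\rho_f$.

**The unsupervised adaptive classifier (UAC)** adds a per-frequency template
bank $Z \in \mathbb{R}^{N_f \times N_c \times N_t}$, initialized to zero.
For each epoch it computes, per frequency $i$,
$$p_i = \mathrm{FBCCA}(X + Z_i,\ Y_i), \qquad p'_i = \mathrm{FBCCA}(X,\ Y_i),
\qquad \tilde p_i = p'_i + w\,p_i,$$
decides $\hat i = \arg\max_i \tilde p_i$, and updates only the decided slot:
$$Z_{\hat i} \leftarrow \tfrac{1}{2}\big(X + Z_{\hat i}\big).$$
The key physical assumption is phase-locking: same-frequency epochs share the
stimulus phase, so their sum grows the stimulus component linearly while
noise grows only as $\sqrt{n}$; superimposing a matched template therefore
raises $\rho$ at the true frequency and depresses it elsewhere. Because the
labels driving the update are the classifier's own estimates, no calibration
recordings are needed — but wrong decisions do write into templates, which
is why the raw template score $p_i$ is blended with the static $p'_i$ rather
than trusted alone: the two make different mistakes and the integrated
statistic is the stronger classifier.

### Exact reductions (useful invariants)

* $w = 0$ ⇒ the UAC decision equals static FBCCA, label for label.
* An all-zero bank ⇒ $p_i = p'_i$ for every $i$, so the first decisions of a
  session are exactly FBCCA decisions.
* $n$ identical epochs routed to one slot ⇒ $Z = X(1 - 2^{-n})$: the halving
  recursion is an exponentially weighted average favoring recent trials, not
  a running mean. A count-weighted running mean is available as
  `update_policy = "running_mean"` but is not the default, because the
  halving form is the method's defining recursion and its recency weighting
  is what lets the bank track slow non-stationarity.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_subbands` (D) | 5 (40-class) / 3 (12-class) | — | more sub-bands help dense 40-class vocabularies; the presets mirror the two public-dataset settings |
| `n_harmonics` (k) | 5 / 3 | — | harmonics above k carry little SSVEP energy at these frequencies |
| `weight_a`, `weight_b` | 1.25, 0.25 | — | standard FBCCA sub-band weighting |
| band edges | sub-band $d$: $[8d, 88]$ Hz | Hz | standard FBCCA bank: band $d$ removes content below the $d$-th harmonic range; fully overridable via `filter_bank_spec()` |
| filter | Chebyshev I, order 4, 0.5 dB ripple, zero-phase | — | the de-facto FBCCA filter family; forward–backward application squares the magnitude response and cancels phase |
| `integration_weight` (w) | 0.45 (40-class) / 0.65 (12-class) | — | tuned presets; `weight_sweep()` reproduces the tuning curve on any cohort instead of trusting them |
| `latency_offset` | 0.14 | s | visual-pathway delay before the SSVEP stabilizes; changes accuracy, so it is an explicit manifest field |
| gaze-shift time | 0.5 | s | ITR trial-time convention for cue-guided protocols; a convention, not a measurement, hence configurable |

## The synthetic generator

`synth_config()` + `generate_epoch()` emulate the properties the method
actually relies on: a per-target sinusoidal response at the stimulus
frequency and `n_harmonics_signal = 3` harmonics with geometric amplitude
decay (`harmonic_decay = 0.5`), a fixed per-target phase (phase-locked across
trials; harmonic $h$ carries phase $h\phi$), a fixed seeded orthonormal
channels × harmonics mixing topography, and additive $1/f$-shaped,
channel-correlated background noise scaled to a prescribed SNR. SNR is
defined as total harmonic signal power over total noise power in the 6–90 Hz
band, measured on the discrete spectrum — pinned so thresholds are
reproducible. Optional `block_drift` multiplies the signal amplitude per
block to emulate non-stationarity. Every epoch is a pure function of
`(seed, target, block, trial)` via an integer hash into per-epoch RNG
streams.

The default `snr_db = -10` was calibrated once so that static FBCCA on the
40-class vocabulary with 1 s epochs scores in the 0.55–0.75 accuracy band —
the regime where adaptation has room to help and the published datasets'
typical subjects sit. Study sizes used by the tests and the acceptance
script: ten 40-class subjects × 6 blocks × 40 trials (1 s, 250 Hz, 8
channels) and five 12-class subjects × 15 runs (1 s, 256 Hz).

What the generator does **not** emulate: volume-conducted dipole topographies,
eye-blink/EMG artifacts, line noise, inter-subject variability in harmonic
structure, or latency jitter. Passing tests on this generator therefore show
that the algorithm exploits phase-locked self-similarity under realistic
noise levels — not that any particular accuracy will transfer to a given
human subject.

## Numerical choices

* **CCA route.** Both variable sets are mean-centered; orthonormal bases of
  the centered sample spaces are taken by thin SVD with effective-rank
  truncation (singular values $< 10^{-10}\sigma_{\max}$ dropped); $\rho$ is
  the largest singular value of the basis cross-product, clipped to $[0,1]$.
  This avoids explicit covariance inversion and survives flat or duplicated
  channels; the test suite checks it against an independent brute-force
  covariance-eigendecomposition oracle to $10^{-8}$. An all-constant input
  has an empty centered subspace and scores 0 by definition.
* **Orientation.** All internal math is variables-in-rows; `eeg_epoch()`
  accepts either orientation only through an explicit flag.
* **Filtering.** Zero-phase forward–backward IIR with odd (mirrored-edge)
  extension of length 3 × (filter length) to absorb the boundary transient.
  Zero-phase filtering is linear, so filtering commutes with template
  superposition — the sequential harness exploits this by caching filtered
  templates and recombining them instead of re-filtering (bit-for-bit
  equivalent up to float associativity, verified to $10^{-8}$).
* **Tie-breaks.** All argmax decisions take the lowest index. Ties have
  measure zero in floats but must be defined for determinism.
* **Scoring order.** Within a trial the decision always uses the pre-update
  bank; the update happens strictly after scoring (the causal online order).
  When templates are built from a batch, both estimated-label and true-label
  construction are possible by driving `classify_and_update()` or
  `update_bank` order explicitly; the harness uses estimated labels
  throughout, as the unsupervised setting requires.
* **No gating, no normalization.** Templates are updated on every decision,
  including wrong ones, and epochs are superimposed raw (no amplitude
  normalization): both choices follow the method's definition, and the
  error-propagation cost at very low SNR is a documented limitation rather
  than something the implementation papers over.

## Dataset readers

`read_benchmark_subject()` / `read_ucsd_subject()` parse the two public
layouts from MATLAB v5 files through a minimal internal MAT reader
(real numeric arrays, zlib-compressed elements, either endianness). MATLAB
v7.3/HDF5 files are not supported. Channel subsetting is by index; montage
name tables are not bundled. `write_synthetic_subject()` emits fully
synthetic files in both layouts so the round-trip is testable offline; such
files are synthetic by construction and labeled so.

## Limitations

* At very low SNR the estimated labels are mostly wrong, templates fill with
  mixed-frequency averages, and the adaptive gain shrinks toward zero — the
  documented error-propagation regime. The classifier never falls below its
  own static term's information (the $p'$ component is always present), but
  it cannot manufacture gain where FBCCA is at chance.
* The integration weight presets were tuned on the public datasets'
  vocabulary sizes; for other vocabularies run `weight_sweep()`.
* ITR comparisons depend on the trial-time convention (stimulation time +
  gaze-shift time); reported bits/min move with that choice, which is why it
  is an explicit argument.
* Templates are stored per frequency only; phase-coded vocabularies with
  duplicate frequencies are out of scope, as are supervised template
  seeding, spatial-filter transfer across frequencies, and confidence-gated
  updates.
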