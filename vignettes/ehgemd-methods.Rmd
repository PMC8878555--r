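---
title: "Methods: single-channel EHG preterm-labor prediction with ehgemd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel EHG preterm-labor prediction with ehgemd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The working hypothesis is physiological: uterine recordings that end in
preterm delivery contain contractions that are *stronger* — higher in
amplitude and richer in high-frequency content — than those of term
pregnancies. `ehgemd` turns that single hypothesis into a classifier with
three deliberately simple features, rather than a large feature bank plus
selection machinery, and handles the severe class imbalance (roughly 13%
preterm) by stratified cross-validation instead of synthetic minority
oversampling: oversampled sensitivities conflate real and fabricated
positives, which is precisely what a clinical screening claim cannot
afford.

The pipeline per record and channel:

1. band-pass 0.08–4 Hz (4th-order Butterworth, causal), trim 180 s per end;
2. cut into non-overlapping 1-min windows (1200 samples at 20 Hz);
3. EMD each window; keep IMF1 and IMF2;
4. compute RMS, SampEn(m = 3, r = 0.15·SD), MTKE on each IMF;
5. average the 6 values over windows; z-normalize columns across records;
6. evaluate kNN / SVM / decision tree under repeated stratified 10-fold CV.

## Empirical mode decomposition

EMD extracts oscillatory modes by *sifting*: find the local extrema, fit
cubic-spline upper and lower envelopes, subtract their mean, and repeat on
the result until it qualifies as an intrinsic mode function — (a) extrema
and zero-crossing counts equal or differing by one, and (b) a near-zero
local-mean envelope. The residue is then re-sifted for the next IMF. Two
readings of the usual "0.2" stopping threshold are implemented because the
phrase "mean of the envelopes below 0.2" does not map uniquely onto one
criterion:

* `criterion = "sd"` (default): the normalized squared difference between
  consecutive candidates, `SD = Σ(h_{k−1} − h_k)² / Σ h_{k−1}² < 0.2`
  (Huang's classical rule);
* `criterion = "envelope_mean"`: the literal reading,
  `mean(|m|) / mean(|amplitude envelope|) < 0.2`.

Either way the candidate must **also** satisfy counting condition (a)
before sifting stops. This matters: on broadband signals the SD measure
converges within two passes while the candidate still has up to ~12 more
extrema than zero-crossings, so a threshold-only stop would emit
non-IMFs. With the joint rule, every returned IMF passes `is_imf()`
(checked over 50 noise seeds in the suite); a hard cap of 100 iterations
guarantees termination and is recorded in `sift_counts` when hit.

Other numerical choices, all config-exposed with these defaults:

* **Splines.** `stats::splinefun(method = "fmm")` — cubic through the
  extrema with Forsythe–Malcolm–Moler end conditions (base R's analogue of
  not-a-knot); `"natural"` is selectable. The choice is invisible away
  from the window edges.
* **Boundaries.** The two extrema nearest each end are mirrored across it
  before fitting, and an endpoint is pinned as a knot when it exceeds the
  adjacent extremum — standard end-effect mitigation; without it envelope
  splines diverge at the edges and leak low-frequency error into IMF1.
* **Plateaus.** A run of equal samples contributes one extremum at its
  midpoint (rounded down).
* **Degenerate inputs.** Too few extrema to build envelopes ends the
  decomposition; the remainder stays in the residue, so the reconstruction
  identity `x = ΣIMF + r` holds *exactly* (it is algebraic, and the suite
  checks it to 1e−9 relative on random windows). A constant signal yields
  zero IMFs.

## Features

* **RMS** tracks burst amplitude directly.
* **SampEn** (−ln of the conditional probability that templates matching
  for `m = 3` points, Chebyshev distance, still match at `m + 1`)
  tracks irregularity. Tolerance `r = 0.15` is interpreted as
  0.15 × SD *of the analyzed IMF window* — the SD-relative convention of
  the entropy literature; an absolute-tolerance mode exists but is not the
  default. SD-relative tolerance makes SampEn exactly scale-invariant
  (identical match counts, asserted in the suite). When no templates match
  (A or B = 0) the entropy is undefined; the window is dropped from the
  record average and counted, never replaced by a surrogate value. At
  n = 1200 this is rare.
* **MTKE**, the mean of `x(n)² − x(n−1)x(n+1)`, grows with both amplitude
  and frequency — for a sinusoid it equals `A² sin²(ω)` — making it the
  most direct readout of "stronger and faster" contractions.

Features are averaged over a record's windows (windows are independent
evidence of the same physiological state; averaging suppresses window
noise) and z-normalized per column. Global normalization — statistics over
*all* records — is the default because it matches the protocol this
pipeline reproduces, but it leaks test-set statistics; a `train_only` mode
computes fold statistics strictly from training rows, results are tagged
with the mode used, and the two must not be pooled.

## Classifiers and evaluation

kNN (Euclidean; even-K ties go to the nearest neighbour among the tied
classes), SVM (exact dual QP via `quadprog`; box constraint 1; polynomial
kernel degree 3 by default — the degree is otherwise unspecified in the
protocol being reproduced — with an optional inner 5-fold grid search over
cost and kernel scale on training data only), and a CART-style tree (Gini,
best-first growth, internal-node budget `dt_max_splits` = 6, minimum leaf
size swept in practice over 10–50).

Evaluation pools the confusion counts over the 10 folds *within* a
repetition before computing Se/Sp/Acc, then averages across repetitions
(default 30). Fold-level sensitivity on 3–4 positives is quantized to
~25% steps; pooling is what makes percentages like 99.5 meaningful.
Whether the original protocol pooled or fold-averaged is not stated; the
pooled choice is documented, not asserted. ROC points come from the pooled
out-of-fold scores of the first repetition (seed recorded), with AUC by
trapezoid — identical to the Mann–Whitney concordance, which the suite
checks to 1e−12. Preterm is the positive class everywhere.

## The synthetic generator: what a green test establishes

`generate_record` builds each channel as 1/f background noise (SD
0.02 mV) plus Poisson-placed contraction bursts — Hann-windowed sinusoidal
packets, duration ~ N(45 s, 10 s), shared event times across the three
channels with per-channel gain jitter. Class defaults: term 2.0 bursts /
10 min, 0.05 mV, 0.2–0.6 Hz; preterm 3.5 / 10 min, 0.12 mV, 0.4–1.2 Hz.
Records are 30 min at 20 Hz; metadata assigns delivery weeks consistent
with the 37-week threshold; everything is bit-for-bit reproducible from
the seed.

The generator encodes *exactly the discriminative structure the method
hypothesizes*, and nothing else: no fetal/maternal ECG artifacts, motion,
electrode noise, inter-subject variability, or gestational-age drift. A
green end-to-end test therefore establishes that the pipeline's plumbing
is correct and that it detects the hypothesized structure when present
(and nothing when absent — the null-generator control with identical class
parameters sits at chance AUC); it does **not** establish clinical
performance on real EHG, which requires the actual database.

Burst parameters were chosen once so that bursts survive the 0.08–4 Hz
band-pass and produce between-class contrasts comfortably above the noise
floor at the default 30-min record length; they were not tuned against any
test outcome.

## Design choices where the design was open

* **Raw vs pre-filtered channels.** TPEHG-style records store both; the
  reader's `channel_map` selects either, and the default filters raw
  signals in-package so the pipeline is self-contained. Which variant the
  original analysis consumed is unknowable from its description; neither
  is claimed faithful.
* **Causal filtering.** Single forward pass by default, because the 180-s
  trim exists precisely to absorb the causal transient; `zero_phase`
  (forward–backward) is available but changes the magnitude response to
  its square.
* **WFDB support** is a minimal in-package format-16 reader/writer
  (single interleaved `.dat`, gain/baseline, checksum, `#`-comment
  metadata) — sufficient for TPEHG-style records, not a general WFDB
  implementation.
* **Missing metadata is an error.** A record with no delivery week in
  header comments or the sidecar table refuses to load rather than
  defaulting to a label.

## Known limitations

* EMD here is the plain algorithm — no ensemble variants (EEMD/CEEMDAN),
  no Hilbert spectrum; mode mixing on real, artifact-laden EHG is not
  addressed.
* The SVM's automatic kernel-parameter tuning in the original environment
  is under-specified; with fixed defaults the headline database numbers
  should not be expected to reproduce exactly even on the real data.
* `fs` is taken from the file header and never inferred or resampled.
* Global z-normalization is kept as the faithful default despite its
  leakage; use `train_only` for honest generalization estimates.
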