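---
title: "Spectro-temporal feature learning for bird sound classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectro-temporal feature learning for bird sound classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **spectrodict**, the
assumptions behind it, the parameters that matter, and the design decisions
taken where the method left genuine freedom. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The model

The pipeline treats species classification as ranking: for each recording it
emits a probability per species, and quality is measured by how reliably
true species outrank absent ones (AUC) and how near the top of the ranked
list they sit (mean average precision). The stages are:

**Mel front-end.** Audio is downmixed to mono and resampled to a standard
rate (default 44.1 kHz; the synthetic benchmarks use 22.05 kHz, which fully
contains their band content). Frames are 1024 samples, Hamming-windowed,
*non-overlapping* — halving data volume at a small cost in temporal
resolution — and mapped through a 40-band triangular, area-normalised
(Slaney-style) Mel filterbank from 500 Hz to Nyquist. The 500 Hz cutoff is a
deliberately blunt noise gate: most wind/traffic energy sits below it, at
the cost of species that vocalise lower. Each spectrogram is divided by its
root-mean-square value, making everything downstream invariant to recording
level. The filterbank's lower edge, not STFT-bin zeroing, implements the
cutoff.

**Median noise subtraction** (optional, per recording): subtract each band's
median magnitude over time and clip at zero. Whatever rises above the
bandwise median survives. The estimator assumes *stationary* background
noise; fluctuating noise (rain bursts, passing cars) violates it, which is
why the flag is an experimental axis rather than always-on. With an even
frame count the median is the mean of the two central order statistics.

**Spherical k-means dictionary learning.** Δ consecutive frames are stacked
into an `M·Δ`-dimensional patch (Δ ∈ {1, 2, 3, 4, 8}; Δ = 1 captures no
modulation, larger Δ captures chirp-like frequency sweeps). Patches are
per-patch normalised (mean subtracted, divided by the norm), PCA-whitened,
and clustered into `k` unit *directions* under cosine distance
`1 − cosθ`. The learned bases act like a bank of data-derived
spectro-temporal templates; projection (`x′(n,j) = Σ_{δ,i} b_j(δ,i)
x(n+δ,i)`) is mathematically cross-correlation with those templates.
Projections keep their sign: rectification discards which side of a
direction a patch falls on, and nothing downstream requires non-negative
features.

**Two-layer variant.** Layer-1 projections are max-pooled by 8 along time
and a second dictionary is learned on Δ-frame patches of the pooled
sequence. One layer-2 patch therefore spans `8·Δ + Δ − 1` original frames —
with defaults about 0.8 s at 44.1 kHz — so it can encode syllable *ordering*
that layer 1 cannot. The test suite verifies this directly with a
two-syllable ordering task that layer-1 summaries cannot solve at high
frame noise.

**Summarisation.** Three per-dimension schemes: mean plus population
standard deviation (`2·width` values), maximum (`width`), or modulation
coefficients (`10·width`): the magnitude spectrum of one full-length Fourier
transform along time, averaged into 10 equal-width bins from 0 to the frame
rate's Nyquist. A single full-length transform — rather than a literal
short-time analysis — keeps the output length independent of recording
duration, which fixed classifier dimensionalities require. Magnitudes are
divided by the frame count so long recordings do not dominate; bins that
receive no spectrum point (very short inputs) are zero. Learned features use
only the mean/std summary; their patches already encode short-term temporal
structure.

**Classification.** A 200-tree probability random forest (via `ranger`),
deliberately untuned, in three modes: `single_label` (one forest over
mutually exclusive classes), `binary_relevance` (one forest per species),
and `multilabel` (a single forest over observed label *powersets*, with the
per-species score the summed probability of the combinations containing the
species — R's tree libraries have no multi-output trees, and the powerset
construction keeps mode 3 a single joint model). Two departures from
library defaults, both restoring reference forest behaviour rather than
tuning: `min.node.size = 1` (ranger's probability-forest default of 10
produces splitless trees, i.e. constant class priors, on small training
folds) and the Gini split criterion (neither installed forest library
exposes an information-gain rule; with fully grown, bagged trees the
criterion choice is second-order).

**Decision windows.** Long recordings can be classified in non-overlapping
1/5/60-s windows (converted to frames via the frame duration; a trailing
partial window is kept), every window inheriting the recording's labels;
per-window probabilities are pooled per recording by mean or max. All
windows of a recording stay in the same crossvalidation fold — splitting
them would leak near-duplicate material across folds.

## Streaming and numerical choices

* **Two-pass training.** Pass 1 reservoir-samples up to `capacity` patches
  (default 100,000) in one forward stream, shuffles them, fits whitening,
  seeds the centroids and runs the online update over the sample; pass 2
  streams every patch through the update. Online k-means is
  order-sensitive; the shuffled first pass reduces that sensitivity while
  keeping memory bounded by the reservoir, not the corpus.
* **Online update.** Winner (by cosine distance; ties go to the lowest
  index) moves by `w = 1/(n_j + 1)` towards the whitened, unit-normalised
  patch and is renormalised — an online count-weighted mean projected back
  to the sphere. The weight schedule is a function argument; pass 2
  continues pass-1 tallies by default (`reset_tallies_pass2` flips this).
* **Seeding.** Centroids are seeded from the shuffled sample by
  k-means++-style sampling under cosine distance (each next seed drawn with
  probability proportional to its distance from the nearest chosen seed,
  from a pool capped at `max(1000, 10k)` rows). A plain "first k distinct
  patches" rule was tried first and regularly placed two seeds in one
  angular cluster; because the online rule updates only winners, such
  duplicates never separate and a true cluster goes unserved. Distance-
  weighted seeding is the standard data-driven initialisation for the
  k-means family and removes that failure mode.
* **Whitening.** Eigendecomposition with eigenvalues floored at
  `epsilon = 1e-8`; per-patch mean subtraction makes exactly one direction
  structurally flat, which the floor absorbs silently (further degeneracy
  warns). `whiten = FALSE` stores an identity transform: useful when data
  are genuine rays through the origin — whitening subtracts the mixture
  mean and so bends ray structure, which is also why the planted-direction
  recovery tests run unwhitened — and when too few patches exist to
  estimate a covariance (whitening estimated from a few dozen patches only
  injects noise).
* **Degenerate inputs.** Zero-norm patches are skipped and tallied;
  all-zero audio, too-short clips, empty streams and undefined AUC (single-
  class labels) raise explicit errors rather than returning sentinels.
  Rarely-updated centroids are kept, not re-seeded; the exposed
  `update_counts` let callers detect dead bases.
* **Determinism.** Every stochastic step (reservoir, shuffle, seeding,
  forests, generator) is governed by explicit integer seeds, and seeded
  helpers restore the caller's RNG state. Identical seeds give bit-identical
  dictionaries, predictions and synthetic audio.

## Evaluation choices

AUC uses the Mann–Whitney midrank form (ties get half credit), matching the
probabilistic reading "a random positive outranks a random negative";
chance is 0.5 regardless of class balance. For multilabel runs the headline
is the **micro** average — all (recording, species) pairs pooled into one
ranking — with the macro average (mean of per-class AUCs over classes with
both labels present) computed alongside, since either aggregation is
defensible and they can disagree. Per-run statistics are the mean of
per-fold values; statistics recomputed on pooled scores are stored
separately because pooled AUC need not lie between per-fold AUCs.

## What the synthetic generator does and does not emulate

Each synthetic species is a set of 2–4 syllable kernels — stationary tones,
up/down chirps (2–8 kHz/s sweeps), or 2–3-component harmonic stacks — with
centre frequencies in 1.2–6 kHz, durations of 80–250 ms, a song rate of
0.8–2 events/s and a species-level amplitude. Events are placed by a Poisson
process (with at least one event per listed species, so annotations are
exact) in pink background noise. Two regimes mirror real corpus structure:
short single-label clips (10 s, 20 dB SNR, random 2-fold splits) and longer
multilabel choruses (12 s, 10 dB SNR, 2–4 concurrent species, recordings
grouped under three synthetic "recordists" with group-preserving 3-fold
splits). The 10-s clip length also keeps the two-layer path well-posed: a
25-clip training fold then yields more layer-2 patches than the default
`k = 500`, whereas much shorter clips leave the second layer underdetermined
after 8× pooling.

The generator is deliberately *not* a birdsong model: no syllable syntax,
amplitude modulation within syllables, reverberation, microphone colouring,
or fluctuating noise. Passing tests therefore demonstrate that the
implementation is correct and that the pipeline separates spectro-temporally
structured sources from noise at realistic SNRs — not that any particular
accuracy will transfer to field recordings.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own desk-scale benchmark: the end-to-end acceptance
experiment uses 5 species × 50 ten-second clips at 22.05 kHz with two-fold
crossvalidation and `k = 500`, running every one of the twelve feature
configurations; chance-level behaviour is checked on 40 noise-only clips
with uninformative labels; clustering properties use planted-direction
problems with `N ≤ 1000`, `dim ≤ 20`, `k ≤ 8`; metric oracles use ≤ 100-item
instances. The acceptance script's chance-AUC estimate uses 1,000 replicates
of 1,000 items.

## Known limitations

* The noise-floor estimator cannot track non-stationary noise.
* The powerset multilabel forest cannot predict label combinations absent
  from training data (their probability mass is zero); binary relevance has
  no such restriction.
* Whitening is estimated from the reservoir sample only; with very small
  corpora the estimate is noisy, and `whiten = FALSE` may behave better.
* FLAC input is not decoded; convert to WAV upstream.
* Dictionary learning cost grows as `k × M·Δ` per patch; the two-layer
  variant roughly doubles front-end-to-feature time and is the slowest
  configuration, consistent with its larger patch dimension.
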