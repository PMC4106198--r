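# spectrodict

Automatic species classification of bird sound at scale, built around
**unsupervised spectro-temporal feature learning**. Instead of classifying
hand-designed summaries such as MFCCs, the package learns an overcomplete
dictionary of spectro-temporal patterns directly from Mel spectrogram data
with **online streaming spherical k-means**, projects recordings into that
learned space, and classifies the summarised projections with a random
forest. It is aimed at bioacousticians and ML-for-ecology researchers who
need species classifiers that run over large, noisy, unsegmented audio
collections, and at anyone who wants a compact, fully tested reference
implementation of the method.

## The method

1. **Front-end.** Audio is converted to mono at a standard rate and cut into
   non-overlapping 1024-sample Hamming-windowed frames; linear STFT
   magnitudes are mapped through a 40-band Mel filterbank spanning
   500 Hz–Nyquist (the sub-500 Hz band is dropped as environmental noise),
   and each spectrogram is RMS-normalised. Optionally, stationary noise is
   removed by **median spectral subtraction**: per band, subtract the median
   magnitude and clip negatives to zero.
2. **Dictionary learning.** Sequences of Δ consecutive Mel frames are stacked
   into patches `x(n+δ, i)`, normalised and PCA-whitened, and clustered by
   spherical k-means, which minimises the cosine distance

   `d(A, B) = 1 − cos θ = 1 − (A·B) / (‖A‖‖B‖)`

   over `k = 500` unit basis vectors `b_j`. Training is streamed in two
   passes: a reservoir-sampled, shuffled pass that fits the whitening and
   runs the online updates on the sample, then a second pass over every
   patch. The online rule is count-weighted (Hartigan-style): the winning
   centroid moves towards the unit-normalised patch with weight `1/(n_j+1)`
   and is renormalised, so bases are always unit vectors.
3. **Projection.** A recording's feature sequence is the dot product of each
   whitened patch with every basis:
   `x′(n, j) = Σ_δ Σ_i b_j(δ, i) x(n+δ, i)`.
   A **two-layer** variant max-pools the layer-1 projections by a factor of 8
   along time and learns a second dictionary on the pooled sequence,
   capturing structure at an 8× longer timescale.
4. **Summarisation and classification.** Variable-length sequences are
   collapsed per feature dimension by mean and standard deviation, by
   maximum, or by 10 binned modulation-spectrum coefficients — twelve
   feature × summary configurations in total. A 200-tree probability random
   forest classifies the summaries in single-label, binary-relevance, or
   full multilabel mode, optionally on 1/5/60-s decision windows whose
   per-window scores are pooled by mean or max.
5. **Evaluation.** Two- or three-fold crossvalidation (feature learning
   restricted to training folds), scored by ROC AUC (Mann–Whitney, micro or
   macro averaged) and mean average precision.

A seeded synthetic-soundscape generator (species = sets of tone / chirp /
harmonic-stack syllable templates placed by a Poisson process in pink noise)
provides datasets with the same structure as real corpora, so the entire
pipeline is testable offline.

## Worked example

Learned features versus MFCC baselines on a synthetic 5-species benchmark:

```r
library(spectrodict)

ds <- generate_dataset(n_species = 5, n_recordings = 30,
                       regime = "single_label_clip", seed = 42,
                       sample_rate = 22050)
fe <- front_end_config(sample_rate = 22050)
mels <- lapply(ds$clips, compute_mel_spectrogram, cfg = fe)

run_crossvalidation(mels, ds$annotations, ds$folds,
                    feature = "mfcc-ms", mode = "multilabel", seed = 1)
#> Crossvalidated evaluation (mfcc-ms, multilabel mode)
#>   AUC (micro, mean over folds): 0.963
#>   AUC (macro, mean over folds): 0.992
#>   MAP  (mean over folds):       0.858
#>   folds: 2

run_crossvalidation(mels, ds$annotations, ds$folds,
                    feature = "melspec-kfl4-ms", mode = "multilabel",
                    k = 500, seed = 1)
#> Crossvalidated evaluation (melspec-kfl4-ms, multilabel mode)
#>   AUC (micro, mean over folds): 0.982
#>   AUC (macro, mean over folds): 1.000
#>   MAP  (mean over folds):       0.961
#>   folds: 2
```

`melspec-kfl4-ms` learns a 500-basis dictionary over 4-frame patches inside
each training fold and summarises the 500 projection coefficients by mean
and standard deviation (1,000 features); it clearly improves on the
26-coefficient MFCC summary, most visibly in the ranking quality (MAP 0.96
vs 0.86). The configuration labels accepted by `feature_configs()` name all
twelve variants (`mfcc-ms` … `melspec-kfl4pl8kfl4-ms`).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/spectrodict.R synth --regime single_label_clip --species 5 --recordings 30 --seed 1 --out data/
Rscript inst/cli/spectrodict.R run   --config experiment.yaml
Rscript inst/cli/spectrodict.R learn --config experiment.yaml --out dict.bin
```

where the YAML config names the dataset directory, feature label, classifier
mode, windowing, seeds and caching/output directories (see
`?load_pipeline_config`).

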