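---
title: "Screening image features for category information: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening image features for category information: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featscreen)
```

## The problem

Experiments that compare responses to two or more categories of complex
images (faces with open versus closed mouths, threatening versus neutral
scenes, chosen versus rejected stimuli) face a basic interpretive hazard:
natural images differ along many dimensions at once — luminance, contrast,
spatial-frequency content, local edge structure, color — and any of these can
drive the measured response instead of the category construct of interest.
`featscreen` quantifies *which measurable image features carry information
about the category labels*, so that those features can be reported, matched,
or entered as covariates.

The package answers that question with machine-learning feature selection
rather than mass-univariate testing, because features can be informative
jointly that are unremarkable alone, and because a classifier's holdout
performance is a directly interpretable effect size (proportion of correctly
decoded images).

## Feature spaces

Images are converted into five interpretable descriptor families
(`extract_features()`), each configurable via `feature_config()`:

* **Fourier magnitude bands** — the 2-D FFT magnitude spectrum summed in
  `24 x 16` spatial-frequency-by-orientation sections. Discarding phase and
  pooling bands makes these features position-invariant descriptors of
  global contrast structure. Frequency bands are equal-width annuli of
  normalized frequency radius (Nyquist = 1); the grid is *linear* in
  frequency, a documented choice where a logarithmic grid would be equally
  defensible. The DC term joins the lowest band at the sector containing 0
  degrees, and the spectrum corners beyond Nyquist are clamped into the top
  band, so the band sums exactly partition the spectrum (a property the test
  suite checks to machine tolerance).
* **Fourier phase** (with linked magnitudes) — the image is first downscaled
  to `25 x 25` pixels; the phase and magnitude of each coefficient form a
  link group, so the pair enters or leaves every selection together.
* **HOG** — unsigned histograms of oriented gradients: 9 orientation bins
  over [0°, 180°) in non-overlapping `10 x 10` pixel cells. Gradients are
  centered finite differences with replicated borders, the gradient
  magnitude is linearly interpolated between the two adjacent orientation
  bins, and *no block normalization* is applied: each feature keeps the
  interpretation "edge energy of one orientation in one image cell", and
  maps of feature relevance can be drawn directly on the cell grid.
* **Color value distributions** — per layer, the probability of pixel values
  falling into each of 25 bins. Bin edges are fixed per colorspace
  (`[0, 1]` for gray/RGB; `[0, 100]` and `[-128, 127]` for CIELAB) rather
  than per image, because per-image min–max binning would destroy
  between-image comparability. Distribution bins of different layers are
  never linked: "the same bin" has no joint meaning across layers.
* **Pixel intensities** — the image downscaled to `25 x 25` and vectorized
  row-major, fully position-specific.

Downscaling uses separable bicubic interpolation (Keys kernel, `a = -0.5`)
with the kernel support widened by the scale factor when shrinking
(antialiasing), matching mainstream image-processing resizers. sRGB input is
converted to CIELAB under a D65 white point. Color layers can be linked so
that corresponding positions across layers are selected as one unit.

## Cross-validation and data splitting

Relevance is estimated with stratified `k`-fold cross-validation
(default `k = 10`). Within a fold, the holdout set touches nothing but final
evaluation. The remaining examples are repeatedly split into a *balanced*
training half and a validation half (`fresh_training_split()`): the training
set draws an equal number of examples per class (`train_fraction`, default
0.5, of the minority count), and a *new* split is drawn at every step where
features are scored, which reduces overfitting to any single split. For
small samples, `cv_config(small_data_mode = TRUE)` replaces the `k`-fold
partition with `k` independent 50/50 train/holdout partitions.

All randomness descends from one root seed through per-fold substreams, so
fold-level work could run in any order (or concurrently) without changing
results.

## Ranking, correlated features, and the four selections

Per fold, every feature is scored with the Kruskal–Wallis H statistic (the
rank-based one-way analysis of variance; mid-rank ties with the standard tie
correction, a constant feature scoring `H = 0`). Walking the ranking from
the top, each unassigned feature seeds a cluster that absorbs all unassigned
features sharing at least 25% of their variance with the seed
(squared Pearson correlation ≥ `r2_threshold`); membership is judged against
the seed only, matching the top-down procedure, and link groups are absorbed
atomically. Correlated features are deliberately selected *together* — the
goal is a complete picture of relevant structure, not a minimal predictive
subset.

Ranking, clustering and the filter test run on a fresh balanced training
split of the fold by default (`ranking_data = "training"`); the fold's full
non-holdout data is available as an option. Four selections of equal feature
budget are then formed:

1. **Filter** — every cluster whose best member reaches `p < 0.01`. If none
   does, a fallback picks the prefix length of the ranking (from the grid
   1, 2, 3, 5, 8, 13, 21, 34, 55, ties toward fewer features) that maximizes
   inner 5-fold cross-validated accuracy. The filter's feature count defines
   `target_size` for the other three methods.
2. **Wrapper** — stepwise inclusion over the search space of the top
   `2 x target_size` ranked features: per iteration, the change in
   validation accuracy from adding each candidate cluster is averaged over
   4 fresh splits; improving clusters are admitted best-first up to 25% of
   the budget; when the selection first exceeds 75% of the budget, every
   cluster is tested once (largest first) and dropped if removal helps.
3. **Random** — clusters drawn uniformly to the same budget. High accuracy
   here signals an easy problem where many features are informative.
4. **Pseudorandom** — a uniform draw restricted to clusters untouched by
   filter and wrapper, probing whether the *unselected* remainder still
   carries category information.

Clusters are admitted whole, so a selection may overshoot the budget by the
last cluster's size; random and pseudorandom selections use the same rule so
cardinalities stay comparable.

Each selection, plus a full model over all features, is trained on the
fold's class-balanced non-holdout data (linear soft-margin SVM, `C = 1`,
features standardized by training mean/SD, one-vs-one for more than two
classes) and scored on the holdout fold. The default SVM backend is the
package's dual coordinate-descent solver — the pipeline trains tens of
thousands of models per run — with e1071/libsvm available as
`classifier = "libsvm"`; the test suite checks that the two backends agree.

## Significance: permutation null and the regression-to-the-mean control

For each fold and each method's selection, 25 additional models are trained
and tested under shuffled category labels: the labels of the fold's training
and holdout examples are permuted jointly, and the model is scored against
the permuted holdout labels. (Scoring chance models against the *true*
holdout labels is not an option: on strongly clustered data a chance model
aligns with the cluster boundary at random polarity, the null becomes
bimodal at 0 and 1, and its maximum saturates.) The pooled
`k x 25 x 4 = 1000` chance accuracies form the null distribution.

Each method's fold-mean holdout accuracy gets a permutation probability
`p = (b + 1) / (B + 1)`, where `b` counts null values at or above it.

Individual features are judged in two stages:

1. **Candidate collection.** A feature qualifies only if it appeared in at
   least one evaluated model whose accuracy exceeds the 99th percentile of
   the null — the percentile compensates for running four selection methods.
2. **Contracted criterion.** Features are not all tested equally often, and
   a mean of many accuracies regresses toward the mean. For a feature used
   `m` times, a control distribution of 1000 *averages of m* resampled null
   values is built, and the feature is flagged only if its mean associated
   accuracy exceeds that control's **maximum**. A feature used once must
   beat the raw null maximum (an effective level of at most 1/1000); a
   consistently re-selected feature faces the appropriately narrower
   criterion for means. Feature accounting covers the four selection
   methods' evaluated models; the full model is a reference only.

Method-level and feature-level inference are deliberately separate: a
selection method can fail to reach significance while individual features
are still flagged through the models that carried them.

`find_feature_combinations()` addresses interactions after the fact: every
pair of flagged features is retrained in isolation, and pairs whose combined
cross-validated accuracy exceeds the mean of all tested pairs by more than
two standard deviations are reported. Pairs are tested in isolation rather
than in the context of all flagged features — the isolated version answers
"do these two features interact?" without conditioning on a particular
surrounding model.

## The mock-data benchmark

`generate_mock_dataset()` builds the package's ground-truth validation
problem: 400 features, 250 examples per class, each feature drawn once as
`n` standard-normal values and assigned to *both* classes in independently
shuffled orders. This exact whole-set null construction means unmanipulated
features have identical class value multisets — whole-set rank statistics
are exactly zero — while any *subset* (a training split) shows ordinary
sampling variation. A random subset of features (25, 50 or 100) then
receives a constant shift of class 1, linearly spaced from 0.5 down to 0.25
SD (the same endpoints at every count; the standard normal makes shifts
directly interpretable as SD units).

Two consequences of the construction are worth knowing when reading
benchmark output. First, unmanipulated features are *anti*-predictive across
the fold boundary: whatever class difference a training sample shows, the
complementary holdout difference has the opposite sign, so models built on
null features score *below* 0.5 on holdout — false alarms are suppressed far
more strongly than under independent sampling. Second, when many features
are manipulated (the 100-of-400 condition), even random selections contain
enough signal to produce accurate models, and every null feature riding in
such a model can pass the contracted criterion; the feature-level false-alarm
rate of the screening procedure therefore *rises* with the number of truly
relevant features. The null-calibration property (flagging nothing when
nothing is manipulated) is the designed guarantee and is what the test suite
asserts over 20 exact-null runs.

The t-test baseline (`ttest_select()`) runs two-sample t-tests per fold on
the fold's balanced training split, uncorrected, at 0.05/0.01/0.001. How
per-fold significance patterns aggregate into one detected set is not
uniquely defined; the package exposes five rules (`fold_mean`, `majority`,
`any`, `all`, `whole`) and uses `fold_mean` — each fold suggests its set and
hit/false-alarm counts are averaged over folds — as the benchmark default,
which in simulation sits closest to the detection rates such a selector
achieves under these conditions. The `whole` rule is exactly
false-alarm-free here (whole-set t statistics of unmanipulated features are
identically zero) but detects nearly everything; the `all` rule is far too
conservative on the training basis.

Benchmark problem sizes in the shipped tests are scaled to desk runtimes:
3 iterations per condition for the full screening pipeline and 15 for the
t-test baselines (the generator defaults document 30); the acceptance script
uses 4 and 30. Means at these scales carry visibly wider standard errors,
which the tests account for.

## The synthetic localized-difference image set

`synthetic_face_set()` generates the package's image-level validation
problem: two categories of face-like images (oval, two eye blobs) that
differ only in a lower-central "mouth" region — a thin line versus a filled
ellipse. Images are generated as **matched pairs**: the i-th image of each
category shares its noise field, position jitter, amplitude and brightness
draw, so outside the mouth region the categories are exactly identical.
This is the image analogue of the mock data's exact-null construction, and
it is what makes a concentration test meaningful at this sample size: under
independent sampling, 100-odd images of several hundred noise cells always
contain a few cells whose sampled class difference is real *in this sample*,
and the screen (correctly) reports them. Passing the concentration check
therefore shows that the pipeline localizes a controlled difference; it does
not show that screens of freely sampled natural images contain no
sample-idiosyncratic features — they generally will, which is precisely why
the method reports them for inspection.

The default conditions (80 images per category, 60 x 60 pixels, pixel noise
SD 0.16) put holdout decoding near 0.75 — the hard-but-decodable regime
typical of natural-image category pairs — where the two-stage feature
criterion has its intended behavior: consistently selected mouth cells pass
their contracted control, while cells that appear once or twice by chance
would need to beat (nearly) the raw null maximum.

## Numerical and degenerate-input conventions

* Kruskal–Wallis: mid-rank ties, tie-corrected; constant features score 0
  with `p = 1` rather than `NaN`.
* Permutation p-values use the add-one convention, never exactly zero.
* Constant features get unit scale in standardization (they contribute
  nothing to the SVM).
* Non-square images are cropped centrally to the largest square before the
  FFT so the band geometry stays isotropic; HOG crops bottom/right remainder
  pixels smaller than one cell.
* Wrapper ties (equal average gain) break toward the higher-ranked cluster;
  "improving" means strictly positive averaged gain.
* The wrapper's pruning pass runs exactly once, at the first crossing of the
  75% trigger, in descending cluster-size order.
* An empty selection is scored at chance (1 / number of classes).
* The pseudorandom pool can be smaller than the budget; the selection then
  shrinks with a warning rather than failing the run.

## Known limitations

* The per-feature criterion is calibrated against *chance*, not against
  "relevance given the other selected features": in regimes where most
  features are informative, features co-selected with strong ones inherit
  high associated accuracies, and feature-level false alarms rise (see the
  benchmark section). Interpret flagged sets from very easy problems
  accordingly — the random-selection accuracy is the diagnostic to watch.
* Holdout accuracy is granular for small holdout sets (`1/n` steps), which
  makes the null maximum coarse; with very few examples per fold,
  `small_data_mode` gives better-behaved estimates.
* Deep-learning classifiers are out of scope by design: the features, not
  the classifier, are the object of interest, and learned features would
  defeat interpretability.
* Viola–Jones-style object localization is not included; spatially specific
  feature spaces assume the object of interest is reasonably centered, so
  crop or align images first.
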