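---
title: "Interpretable breast-thermography diagnosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable breast-thermography diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modeling idea

Malignant breast tissue is metabolically active and highly vascularized, which
raises the local skin temperature by a few degrees Celsius. An infrared camera
measures the skin temperature field directly, so a thermogram of both breasts
carries a diagnostic signal: a localized hot-spot on one side, or an unusual
left/right asymmetry. Deep networks classify such images well but are opaque;
clinicians need to know *why* an image was called sick.

`thermotan` implements a fully interpretable diagnostic chain around a
tree-augmented naive Bayes (TAN) network:

1. **Temperature grids.** Thermograms arrive as spreadsheet exports: one
   temperature in degrees Celsius per pixel, blank cells where background was
   removed. `read_temperature_grid()` and `write_temperature_grid()` handle
   this format; everything downstream consumes the `thermogram` container
   (values + validity mask).
2. **Segmentation.** `threshold_segment()` masks out every cell strictly
   below a threshold (default 29 degC), separating the body from the cooler
   ambient background.
3. **CNN.** A small LeNet-style network (`cnn_build()`, `cnn_train()`)
   classifies the bilateral composite image. It is a desk-scale model —
   two conv(3x3, ReLU)/maxpool(2x2) blocks, a ReLU dense layer, and a
   two-unit softmax head — trained with Adam on categorical cross-entropy.
4. **Explanation.** A LIME-style perturbation explainer
   (`segment_superpixels()`, `explain_instance()`) switches contiguous image
   segments on and off, queries the CNN, and fits a locally weighted ridge
   surrogate whose coefficients rank the segments. `critical_roi()` carries
   the top-k positive segments back to grid coordinates: the *critical
   region of interest*.
5. **Thermal factors.** `extract_factors()` computes a panel of 18 factor
   columns from the (affected, healthy) breast pair: extreme temperatures,
   range, mean, median, population SD and variance, deviations of the
   affected maximum from its own mean and from the healthy side's maximum,
   minimum and mean, difference of means, the pixel distance D between the
   hottest and coldest cells, and the hot-area counts A, B, C with their
   ratios A/B and C/B (threshold `mean + 0.5 (max - mean)`).
6. **Diagnostic network.** `tan_fit()` learns a naive Bayes or TAN
   classifier over the discretized factors and the medical-record variables
   (age, age at last menstrual period). Model A uses factors + records;
   Model B adds the CNN's predicted label as one more node.
7. **Evaluation.** BayesiaLab-style confusion reports
   (occurrences/reliability/precision and their overall/mean summaries),
   mutual-information node rankings with the G-test, Gini/ROC/lift/
   calibration indices, and stratified K-fold cross-validation.

The premise is that if the network's cross-validated accuracy approaches the
CNN's, its structure and conditional probability tables *are* the
explanation of the diagnosis.

## The TAN model

With class $Y$ (diagnosis, 0/1) and discrete features $X_1,\dots,X_p$, the
network factorizes the joint distribution as

$$P(Y, X_1,\dots,X_p) \;=\; P(Y)\,\prod_{i=1}^{p} P\!\left(X_i \mid Y,\,
X_{\pi(i)}\right),$$

where $\pi(i)$ is the (at most one) feature parent of $X_i$. Naive Bayes is
the special case with no feature parents. The feature tree is learned by
scoring every pair with the class-conditional mutual information
$I(X_i; X_j \mid Y)$ (maximum-likelihood plug-in, in bits), taking a
maximum-weight spanning tree (Kruskal; ties broken by the lexicographic
variable-name pair), and orienting it outward from the alphabetically first
feature. The root choice does not change the represented distribution; it is
fixed purely for determinism. CPTs are estimated with Laplace smoothing
(`alpha = 1` by default), so states defined by the discretization but unseen
in a training fold keep positive probability.

`posterior()` performs exact inference: for each class state, unobserved
features are marginalized by sum-product message passing over the feature
tree (linear in $p$), then the class axis is normalized. The test suite pins
this against a brute-force enumeration of the full joint for up to six
ternary features. `simulate()` draws records ancestrally and underlies the
structure-recovery tests; `predict()` applies a stored discretization scheme
to raw tables.

### Discretization

Continuous factors are cut into three states by default (equal-frequency,
with each cut at the midpoint between the two order statistics straddling
the quantile boundary); three states match the two degrees of freedom per
continuous node in the reference analyses. Integer-valued variables with at
most 80 distinct values — ages, pixel counts, binary flags — are kept
discrete as-is. Edges always come from the training split only; at predict
time, discrete-as-is variables map unseen values to the nearest stored
state, and constant variables are dropped with a warning.

### The node-influence report

`mi_report()` mirrors the "influence on target" table of the reference
workflow. For each node: plug-in mutual information with the diagnosis (in
bits); normalized MI ($\mathrm{MI}/\log_2 k_Y$); relative MI
($\mathrm{MI}/H(Y)$); relative significance ($\mathrm{MI}/\max
\mathrm{MI}$); the G-statistic, which for plug-in estimates obeys the
algebraic identity $G = 2N \ln(2)\,\mathrm{MI}$; degrees of freedom
$(r-1)(c-1)$ over observed states; and the upper-tail chi-square p-value.
Because the identity is exact for the maximum-likelihood estimator, no bias
correction is applied to MI — that is what makes the printed G values
reproducible from the printed MI values.

## Evaluation conventions

Confusion tables are reported with rows = predicted state and columns =
true state. *Reliability* row-normalizes (how trustworthy each emitted
prediction is), *precision* column-normalizes (how well each true state is
recovered). Overall precision is the trace over N; mean precision averages
the diagonal precision entries; overall reliability weights the diagonal
reliability entries by the true-class proportions (the weighting that
uniquely reproduces both reference models' printed summaries from their
printed counts); mean reliability averages them. Row totals are always
derived from the counts, never from labels.

The ranking indices satisfy, by construction and identically on every
input: `roc_index` = AUC in percent (midrank tie handling),
`gini_index = roc_index - 50`, `relative_gini = 2 * gini_index`. The lift
index is the area under the cumulative-gains curve divided by the 0.5 area
of a random ranking, and the relative lift expresses that area as a
percentage of the way from random to the ideal ranking; both follow these
documented definitions and are not claimed to match any proprietary
normalization. The calibration index is $100\,(1 - \overline{|p - \hat f|})$
over ten equal-count score bins.

`kfold()` stratifies folds by class (counts per fold within one of each
other), trains on each complement, and evaluates the pooled out-of-fold
predictions.

## The synthetic cohort

No patient data ships with the package; `generate_cohort()` simulates the
study population the pipeline assumes:

* class counts default to 211 healthy / 153 sick (364 patients);
* each breast is an elliptical body region at a per-patient baseline
  temperature (mean 31.5, SD 0.8 degC) plus a smooth low-frequency field of
  amplitude 0.3 degC, over a 22 degC ambient background that segmentation
  must remove;
* sick cases receive an additive isotropic Gaussian hot-spot on the affected
  side (peak 2-4 degC, spatial sigma 2-4 px, both uniform), the simplest
  model of local tumour-associated hyperthermia; the peak cell is recorded
  in the grid metadata as ground truth for explainer tests;
* i.i.d. Gaussian pixel noise (SD 0.25 degC) on body cells;
* ages are truncated-normal with mean 57.0 and SD 10 years, ages at last
  menstrual period with mean 48.1 and SD 5 years, both rounded — the means
  anchor to the cohort the diagnostic network is designed for, the SDs and
  truncation bounds are declared assumptions, drawn independently of the
  class.

What the generator deliberately does **not** model: vascular patterns,
bioheat (Pennes) physics, camera optics, pose variation, or any dependence
of the medical-record variables on the diagnosis. Passing tests on this
cohort therefore show that the pipeline recovers a planted
localized-hyperthermia signal under noise; they do not certify performance
on real thermograms, where the class signal is weaker and the record
variables carry information.

A "no-tumor symmetry bound" is part of the generator's contract: with zero
noise, the left/right difference of body maxima for a healthy patient is at
most `2 * smooth_amp`; for a sick patient the affected-minus-healthy maximum
difference equals the drawn hot-spot delta within that same bound.

## Numerical and design choices

* **Temperature window.** Grids become network input by the fixed linear
  map of [`t_low`, `t_high`] = [22, 40] degC onto [0, 1] (clipped, masked
  cells 0) rather than per-image min-max scaling: absolute temperature is
  itself diagnostic, and per-image scaling would erase the hot-spot's
  absolute elevation.
* **Input normalization in the CNN.** Two centering steps are part of the
  fitted model: each image's mean level is removed (the per-patient
  baseline body temperature is a nuisance; diagnosis rides on within-image
  contrast), then the per-pixel training mean is subtracted (removing the
  large common component that otherwise dominates early gradients and can
  kill the ReLU stack at practical learning rates). Both are stored with
  the model and applied identically at predict time.
* **Native-aspect input.** The default CNN input matches the aspect ratio
  of the bilateral composite (e.g. 32x64 for two 32x32 breasts). Squeezing
  the composite into a square input halves the hot-spot's width and
  measurably degrades both training and the explainer's peak-pixel
  recovery; with the native aspect the nearest-neighbour resize is the
  identity and explanation masks map back to grid cells one-to-one.
* **Optimizer schedule.** Adam at learning rate 3e-3 with batch size 8 for
  10 epochs. On cohorts of tens of images the limiting factor is the number
  of parameter updates, not data passes; larger batches at these sizes give
  too few updates, much larger rates can silence the ReLU stack.
* **Off-segment fill in the explainer.** `explain_instance()` defaults to
  the per-channel image mean, the canonical LIME choice for photographs.
  For segmented thermograms the pipeline overrides this with a constant
  fill of 0 (`fill = 0` in `run_config()`): after segmentation and scaling,
  0 *is* the background, so switching a segment off reads as "tissue
  removed". The mean fill instead paints gray blocks over the background,
  which the network rightly treats as signal; in the package's own
  measurements peak-pixel recovery drops from ~84% to ~24-40% with mean
  fill.
* **Explainer settings.** 16 target superpixels (regular contiguous
  blocks), 150 perturbation samples, exponential kernel of width 0.25 over
  cosine distance, ridge penalty 1.0 with unpenalized intercept, top-3
  segments for the critical ROI, ties broken by lower segment id. If no
  segment weight exceeds `weight_floor = 0.05` — the typical outcome for
  healthy cases, where no single region drives the prediction — factors
  fall back to the whole affected breast.
* **Affected/healthy convention.** For sick patients the recorded affected
  side takes the affected role; for tumour-free patients the left breast is
  treated as affected and the right as healthy, so the bilateral difference
  factors are defined for everyone. The healthy side's statistics are
  always computed on the whole healthy breast (the critical ROI exists only
  where the CNN found signal).
* **Factor conventions.** Population (not sample) variance; median as the
  midpoint of the central order statistics; ties at the maximum or minimum
  resolved to the first cell in row-major order (fixing D
  deterministically; a constant ROI has D = 0 and A = C = 0); "near the
  maximum" for A operationalized as the 8-connected above-threshold
  component containing the maximum cell, which guarantees A <= C.
  Connected-component labeling is done in-package because the available
  image-analysis labeling routine is 4-connected.
* **Coordinates.** Row-major, row 1 = image top, column 1 = image left,
  throughout.
* **Leakage guards.** In cross-validated runs, the CNN that scores or
  explains a patient never saw that patient (per-fold training);
  discretization edges and CPTs for a fold are fitted without that fold's
  rows; Model B's CNN node uses out-of-fold predictions by default. A
  `resubstitution = TRUE` switch reproduces the optimistic variant in which
  one CNN sees all images, for fidelity experiments only.

## Problem sizes used by the tests and the acceptance script

The shipped tests exercise the full pipeline at desk scale, the package's
own choice of simulation size: an "easy" cohort of 70 patients (40 healthy,
30 sick) with 24x24-pixel breasts, hot-spot deltas of 2.5-4 degC and noise
0.25 degC; 50 additional seeded sick cases for explainer-recovery
measurement; a 364-patient cohort (the design class balance) for the
shuffled-label null; 20-seed repetitions for the paired Model A versus
Model B comparison and for the TAN-versus-NB likelihood ordering; and
10,000 records for the prior checks. Under these conditions the
cross-validated overall precision of both models is typically in the
85-95% range, Model B at or above Model A on most seeds, and the
whole-image CNN around 90% out-of-fold.

## Known limitations

* The synthetic hot-spot is a single additive Gaussian; multifocal disease,
  diffuse hyperthermia and inflammatory patterns are out of scope.
* The block superpixels are axis-aligned rectangles; content-adaptive
  segments would follow anatomy better but would make the perturbation unit
  itself stochastic.
* The lift and calibration indices follow the package's documented
  definitions; their absolute values are not comparable to proprietary
  implementations of the same names.
* Real spreadsheet exports vary; the reader supports the comma-separated
  and first-sheet XLSX conventions described above, not proprietary
  radiometric formats.
* With tens of patients per fold, CPTs for many-state discrete variables
  (such as age) are heavily smoothed; at these sizes the record variables
  act mostly as noise, by construction of the generator.
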