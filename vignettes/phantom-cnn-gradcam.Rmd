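---
title: "Classifying brain contrast maps with a compact CNN and explaining the decision with Grad-CAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain contrast maps with a compact CNN and explaining the decision with Grad-CAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocam)
```

## The problem

Developmental dyslexia is a neurodevelopmental reading disorder. Task-fMRI
studies of reading contrast the activation evoked by word stimuli against a
fixation baseline; group differences between dyslexic (DYS) and typical (TYP)
readers concentrate in a reproducible set of frontal, temporoparietal and
occipitotemporal regions. `neurocam` implements a complete small-cohort
analysis of such data: a convolutional classifier that separates the two
groups from whole-brain contrast volumes, and a visual-explanation stage that
asks *which voxels* drove each classification and aggregates the answer into
per-region cluster tables.

The classifier input is one 3D contrast map per subject (the subject-level
average of word-condition activation after first-level modelling), on a common
template grid — canonically 60 × 73 × 60 voxels at 3 mm. Because cohorts of
this kind are small (tens of subjects) and usually not redistributable, the
package ships a phantom module that simulates the whole study: geometry,
per-subject volumes with a controlled group effect, and cohort demographics.
Everything downstream is written against that interface, so the pipeline runs
identically on real NIfTI data.

## The phantom: what it emulates and what it does not

`make_brain_geometry()` builds an ellipsoidal brain mask and partitions it
into spatially contiguous parcels by nearest-seed growth — a stand-in for an
anatomical parcellation with named regions. `simulate_subject()` generates

$$ y(v) \;=\; \mu \;+\; a\,\sigma\,[v \in \text{target parcels, group
elevated}] \;+\; \varepsilon(v), \qquad \varepsilon = G_\varsigma *
\eta,\;\; \eta(v) \sim N(0, \sigma^2), $$

i.e. a constant baseline, an additive group effect of amplitude $a$ in units
of the noise SD restricted to designated parcels, and Gaussian-smoothed
voxel noise (smoothing sigma 1 voxel by default, a reduced-scale analogue of
the 6 mm FWHM smoothing used in template-space preprocessing; out-of-mask
voxels are exactly zero). Only the noise is smoothed, so the injected
contrast between target and non-target parcels equals $a\sigma$ exactly —
the Monte-Carlo tests rely on that identity. The simulated effect is
deliberately the *simplest* structure that lets recovery be verified:
constant within parcels, no spatial gradient, no subject-level amplitude
variability, no correlation between effect size and demographics. Passing
tests therefore demonstrate that the machinery recovers a localised additive
group difference; they do not demonstrate robustness to the richer structure
of real fMRI contrasts (inter-subject anatomical variability, distance-
dependent noise correlation, motion artefacts, site effects).

`simulate_cohort()` draws demographics per group from truncated normal
distributions whose default means and SDs are the cohort summary values the
package targets (e.g. reading speed 84.71 ± 31.89 words/min for typical
readers vs 13.07 ± 7.68 for dyslexic readers; 16 subjects per group). Ages
are clipped to 7–13 years, IQ to 60–150, rates and times to their natural
ranges, so no degenerate draws occur; the truncation shifts the realised
mean of strongly-truncated variables (dyslexic reading speed by about +0.7
words/min), which the tests check against the closed-form truncated-normal
mean rather than the nominal one. The baseline and noise scale of the
volumes are free choices (defaults 0 and 1): the numeric scale of averaged
word-activation inputs is not standardised, and every volume is z-scored
within the mask before it reaches a model anyway.

One global seed drives everything; per-subject seeds are derived as seed +
subject index so cohorts are reproducible subject-by-subject.

## Slice-as-channel packing and augmentation

A 2D CNN consumes the 3D volume by treating the slices along one axis as
input channels (`pack_slices_as_channels()`, default axial/z), exactly as an
RGB image has three colour channels. This keeps the parameter count an order
of magnitude below a genuine 3D convolution while still seeing the whole
brain. Two augmentations expand the training set: i.i.d. Gaussian voxel
noise (robustness to acquisition noise) and a single random intensity offset
per copy (robustness to global contrast shifts). Both touch in-mask voxels
only. Defaults: 10 augmented copies per training subject, both sigmas 0.1 ×
the in-mask intensity SD (the augmentation literature for fMRI states no
canonical magnitude; 10% preserves class structure while visibly perturbing
the input). Volumes are z-scored within the mask *before* augmentation, so
the offset augmentation is not silently undone by normalisation. Validation
and test subjects are never augmented and are always evaluated on their
original volumes — held-out accuracy is subject-level by construction. (The
evaluation unit behind published sample-level accuracies on data of this
kind is often ambiguous; pinning it to subjects is the conservative choice.)

The 80/10/10 split uses floor sizes with a minimum of one subject in any
part with positive fraction, remainder to train (32 subjects → 26/3/3), and
stratifies by group by default.

## The classifier

`build_modified_lenet5()` pins a LeNet-5-derived architecture with four
modernisations: batch normalisation in each convolutional block, ReLU
instead of tanh, max instead of average pooling, and dropout (rate 0.5) on
the fully connected layer. The pinned geometry is three blocks of
5 × 5 valid convolution (stride 1, filters 16/32/64 doubling per block) each
followed by batch-norm → ReLU → 2 × 2/2 max pool, then flatten →
dense(64) → dropout → dense(2) → softmax. For the canonical 60 × 73 input
with 60 slice channels this counts 170,450 parameters — the "~175 K" scale
that distinguishes this family from VGG-class networks. Exact kernel sizes
and fully connected width are a reconstruction: they are constrained by the
hyperparameter grammar (kernels ≤ 5, filters starting at 16 and doubling)
and by that parameter-count target, not printed anywhere.

Pooling uses floor semantics, with one deliberate refinement: a pooling
window is clipped at the border when the input side is smaller than the
kernel, so pooling a length-1 side is the identity rather than an error.
Without the clip the third block would be unreachable for 32 × 32 inputs,
the volume size the desk-scale experiments run at.

`to_3d()` swaps 2D convolutions for isotropic 3D ones (k × k → k × k × k)
and makes the input a single-channel 4D array. The conversion always has
strictly more parameters than its 2D source (650,210 for the pinned model
at 60 × 73 × 60 × 1 — the multi-million counts reported for such
conversions depend on the unprinted details of the converted architecture,
so the package asserts the ordering and logs the count rather than a fixed
number).

Training is plain Adam on the 2-class cross-entropy (default lr 0.001,
batch 16 — the one hyperparameter value that *is* fixed in the grammar —
epochs from the grammar grid, no early stopping by default). The engine is
the package's own: im2col convolution via precomputed gather indices and a
compiled scatter kernel, batch-norm with population statistics per batch and
an exponential-moving-average (momentum 0.9) eval mode, He-uniform
initialisation, inverted dropout. Everything is deterministic given the
seed: initialisation, shuffling and dropout masks derive from it, and
argmax ties break toward the first class. Batch-norm epsilon is 1e-5;
softmax subtracts the column max before exponentiation.

The SVM baseline (`train_svm_baseline()`) operates on flattened in-mask
voxels, standardised per voxel by training statistics, with a linear kernel
and the cost chosen from {0.01, 0.1, 1, 10, 100} by validation accuracy
(ties to the smaller C — the less complex model). The SVM sees original
volumes only; whether augmented copies should reach a margin classifier is
ambiguous, and leaving them out keeps the baseline conventional.

## Architecture search

`evolve()` runs grammar-based genetic programming over the hyperparameter
space: a genome holds the number of conv blocks, per-block kernel and
stride, learning rate, dropout rate, epoch count and FC width, each drawn
from its grammar option set; `genome_to_model()` maps genomes
deterministically onto model specs (filters follow the 16-doubling rule).
The published description names GGP but not its operators or population
settings, so the package uses conventional GA machinery sized for
desk-scale runs: tournament selection of size 3, uniform crossover with
probability 0.9, per-gene mutation at rate 0.1, elitism 1, default
population 10 and 5 generations. Fitness is validation accuracy of the
trained genome; each distinct genome is evaluated once (cache), failures
score zero, and fitness ties prefer smaller models. The grammar's dropout
option "1" cannot be a literal probability (it would zero the layer); it is
capped to 0.99 with a warning. The number of conv blocks (1–4 by default)
is likewise a search-space bound the hyperparameter table leaves open.

## Visual explanation

`gradcam()` implements gradient-weighted class activation mapping from
scratch on the package's own engine: forward pass, one-hot gradient of the
*pre-softmax* class score (standard practice; the raw category score, not
the probability), backpropagated to the rectified feature maps $A^k$ of the
chosen convolutional block (default: the final one). The per-filter weights
are spatial means, $\alpha_k = \frac{1}{Z}\sum_u \partial y^c / \partial
A^k_u$, and the map is $\mathrm{ReLU}(\sum_k \alpha_k A^k)$ at conv
resolution, bilinearly upsampled (half-pixel centres, align-corners off) to
the input plane. `guided_backprop()` modifies the backward pass at every
rectifier: the signal is zeroed where the forward activation was
non-positive *or* the incoming backward signal is non-positive.
`guided_gradcam()` multiplies the upsampled map — broadcast across the
channel axis — pointwise with the guided saliency. Because channels are
brain slices, the product resolves relevance along all three axes and
unpacks to a 3D relevance volume; the plain Grad-CAM map alone carries no
slice information, which is why the region tables are built from the guided
product (the channel-broadcast plain map remains exportable for
comparison).

Correctness is enforced by oracle tests: backward gradients and
$\alpha_k$ against central finite differences (the FD check targets the
final conv block — finite differences are invalid across max-pool tie
points), a closed-form single-filter architecture where the map must equal
the rectified feature map, and scale-covariance (scaling the class logit
scales $\alpha_k$ and leaves the normalised map unchanged).

## Group maps and region tables

Per-subject saliency volumes are min-max normalised and averaged over the
*correctly classified* subjects of a class (explanations of misclassified
subjects explain the wrong decision; `use_all = TRUE` overrides).
`threshold_map()` keeps in-mask voxels at or above the q-th in-mask
percentile (default q = 90; published tables of this kind report clusters
of roughly 64–201 voxels against a whole-brain mask, which this threshold
reproduces at scale, and no canonical threshold exists to inherit).
`connected_clusters()` labels 26-connected components, discards those below
`min_size` (default 20 voxels) and orders labels by descending size;
`region_table()` then counts each cluster's voxels per parcellation region,
reports the highest-saliency voxel as the peak in mm (RAS affine, 0-based
voxel indices, left = negative x) and labels the cluster by the region at
its peak. Voxels a cluster occupies outside the parcellation are reported
under an explicit "unlabeled" row, and each cluster's region counts sum to
its size by construction (tested). White matter, if wanted, is simply an
additional parcellation label.

`ttest_from_summary()` closes the loop on cohort tables: an
independent-samples t-test recomputed from printed means/SDs/sizes
(pooled-variance by default, Welch optional). With 16 subjects per group
the packaged demographic parameters give p < 0.001 for age, reading speed
and in-scanner task accuracy. For response time (2039.2 ± 423.56 vs
2981.06 ± 954.82 ms) the same computation gives p ≈ 0.001 — nominally
significant even though such tables sometimes mark it otherwise; the
package reports the computed value.

## Problem sizes, determinism and the reference experiment

`run_phantom_experiment()` is the single-call reference protocol: 100
subjects per group at 32 × 32 × 16 voxels with 10 parcels, amplitude 3 ×
noise SD in 4 parcels, stratified 80/10/10 split, the pinned network
trained for 25 epochs with ×10 augmentation, subject-level test accuracy on
the 20 held-out subjects. The reduced grid keeps a full run in the
minutes range on one CPU core while preserving the qualitative regime — a
strong, spatially localised group effect that a compact CNN should drive to
high accuracy (and does; the linear SVM also separates this phantom, and the
paired-seed comparison checks ordering, with ties counted for the CNN). The
test suite runs the same protocol plus three multi-seed batteries at
lighter settings: 10 paired CNN/SVM seeds (20 subjects per group, 8 epochs,
no augmentation), 20 localisation seeds (single injected parcel, amplitude
4, 12 epochs, qualifying a seed only when test accuracy reaches 90%), and
20 null seeds (amplitude 0, where every classifier must stay within
50 ± 15% — the leakage check). Multi-seed batteries shorten training because
their conclusions — rank ordering, localisation, chance-level behaviour —
stabilise long before convergence, whereas the headline accuracy uses the
full 25-epoch protocol.

All randomness flows from integer seeds through one derivation rule, and
every operation restores the caller's RNG state, so any result in the
package — including the full pipeline (`run_pipeline()`), which logs each
stage's seed and the config hash as JSON lines — is bit-reproducible from
its config. Single-threaded execution is the default and the only mode
used by the shipped experiments.

## Known limitations

* The phantom's effect model is additive and piecewise-constant; no claim
  is made about sensitivity to subtler, distributed group differences.
* The pinned architecture is a constrained reconstruction, not a published
  layer table; its 3D conversion is likewise pinned by rule (isotropic
  kernels), so its parameter count should be read as "this conversion", not
  "the conversion".
* Guided backpropagation is defined here only for ReLU networks, which is
  the only activation the architecture grammar produces.
* The 2D Grad-CAM map is channel-blind; all slice-resolved statements rest
  on the guided product.
* No registration, resampling or surface projection: volumes are assumed to
  share one grid, and region names come from the parcellation provided.
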