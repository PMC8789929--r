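---
title: "Deeply supervised 3D segmentation of hippocampus subfields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deeply supervised 3D segmentation of hippocampus subfields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippunet)
```

## The problem

Hippocampus subfields (CA1, CA2/3, CA4/dentate gyrus, the strata, the
subiculum) are small, thin, curved structures whose segmentation from MRI
is both clinically relevant and notoriously data-poor: manually labelled
volumes number in the tens, not thousands. `hippunet` implements a
complete, CPU-testable toolkit for this setting: a family of
region-overlap training objectives, a deeply supervised 3D encoder-decoder
with coarse-to-fine output feedback, prediction with sample-specific
normalization statistics, the matching augmentation suite, Dice-based
K-fold evaluation, and a synthetic phantom generator so that every stage
of the pipeline can be exercised end to end without access to any MRI
repository.

## Overlap losses

For a predicted probability field $p_{ci}$ (class $c$, voxel $i$) and a
one-hot reference $t_{ci}$ with class volumes $V_c = \sum_i t_{ci}$, the
package provides:

* **Dice loss (DL)** — the per-class mean of the soft Dice ratio,
  $1 - \frac{2}{NC}\sum_c \frac{\sum_i p_{ci}t_{ci}}{\sum_i p_{ci}+t_{ci}}$.
* **Generalized Dice loss (GDL)** — classes pooled with quadratic
  inverse-volume weights $w_c = 1/V_c^2$.
* **Jaccard loss (JL)** — the per-class mean of the soft
  intersection-over-union loss.
* **Generalized Jaccard loss (GJL)** — the Jaccard ratio pooled across
  classes with *linear* inverse-volume weights $w_c = 1/V_c$:
  $1 - \frac{\sum_c w_c \sum_i p_{ci}t_{ci}}
  {\sum_c w_c \left(\sum_i p_{ci}+t_{ci}-\sum_i p_{ci}t_{ci}\right)}$.
  The linear weighting counteracts label-size imbalance less aggressively
  than the quadratic one, which in practice avoids the instability that
  makes quadratically weighted pooling fragile when a class is nearly
  absent, while still preventing large structures from dominating the
  objective. GJL is the package's default training objective.
* **Categorical cross-entropy (CCE)** — the voxel-mean log loss, with
  probabilities clipped at $10^{-7}$ before the logarithm. It is
  implemented unweighted.

Three numerical conventions, all configurable, deserve a note:

* **Smoothing.** A constant $\varepsilon = 10^{-5}$ is added to every
  denominator. This keeps absent classes finite without moving any
  reported value by more than $\sim 10^{-4}$.
* **Absent classes.** A class with $V_c = 0$ receives weight 0 in the
  pooled losses and is dropped from the per-class means (with a warning
  from `class_weights()`). Undefined $1/0$ weights must never become NaN
  losses mid-training.
* **The pooled-ratio Jaccard variant.** A formulation that first pools
  the Jaccard ratio over classes and then multiplies by $1/NC$ cannot
  reach zero at a perfect prediction — its floor is $1 - 1/NC$, which the
  test suite asserts symbolically. The default `jaccard_loss()` is
  therefore the per-class mean, structurally consistent with the Dice
  loss; the pooled-ratio form remains available via `literal = TRUE`
  (and `jl_literal` in the training config) for comparison.

Every loss has a closed-form gradient (`loss_gradient()`), validated
against central finite differences at $10^{-4}$ relative tolerance; the
gradients are what the training loop consumes.

## The network

`network_spec()` describes a 3D U-Net variant with, by default, 4
resolution levels spanning 0.5 mm to 4 mm, 64 filters at the finest level
doubling at each coarser level (64/128/256/512) and halving again on the
way up, and three convolution blocks per level. A block is batch
normalization, a 3×3×3 "same" convolution, then ReLU — except the very
first block, which convolves the raw two-channel (T1w/T2w) input directly.
Dropout (rate 0.5) follows each encoder level's block stack; 2× max-pooling
descends; parameter-free nearest-neighbour upsampling ascends, with the
encoder shortcut concatenated at each decoder level.

With deep supervision on, the three finest decoder levels each end in a
1×1×1 convolution and a per-voxel softmax, producing segmentations at
full, half and quarter resolution whose losses are combined with weights
0.1 (low), 0.2 (medium), 0.7 (high). Architectures with fewer than three
heads renormalize the finest weights to sum to one.

**Output feedback.** The coarser heads do not merely add auxiliary losses:
each coarse segmentation also informs the next finer output. The default
wiring adds the upsampled coarser head logits to the finer head logits.
Adding logits multiplies the corresponding probabilities, so the coarse
segmentation acts as a spatial prior that the finer level refines — and
the coupling costs no parameters. The alternative wiring, concatenating
the upsampled coarse class probabilities as extra input channels of the
next decoder level, is available as `feedback = "concat"`. The additive
form is the default because it is the reconstruction under which the
package's parameter accounting reproduces the reference total exactly
(below); at phantom scale we observed no systematic accuracy difference
between the two wirings.

**Parameter accounting.** `parameter_audit()` enumerates every
parameterised layer; `count_parameters()` sums it. Normalization layers
carry four per-channel quantities — trainable scale and shift, plus
running mean and variance. The default count includes all four, matching
the parameter totals that deep-learning toolkits print in their model
summaries; `include_stats = FALSE` gives the strictly trainable subset.
Under the default architecture (four levels, 64 base filters, three
blocks, 1×1×1 heads with bias, parameter-free upsampling and additive
feedback, four output classes) the audit sums to exactly **35,085,580**:
35,061,120 convolution kernel weights, 4,224 convolution biases, 1,804
head parameters, and 18,432 normalization parameters. This figure was
calibrated by exhaustively enumerating the principled combinations of
upsampling operator, head kernel size, feedback wiring, normalization
placement and counting convention; the configuration above is the unique
exact reconstruction in that family and is frozen as the default. Notably,
no variant with channel-concatenated feedback reproduces the total under
any counting convention, which is why the additive wiring is the default
rather than concatenation.

With `deep_supervision = FALSE` the same constructor yields the classic
single-output 3D U-Net used as the ablation comparator.

## Training

`train_network()` runs Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, the optimizer's customary defaults) with batch size
one for up to 200 epochs by default. Ground truth for the coarse heads is
produced by majority-vote downsampling of the label map per coarse voxel
(ties break toward the smaller label), which keeps every supervision
target a valid hard label field: no label is invented or lost while a
structure remains thicker than the coarse voxel. All randomness —
initialization, shuffling, dropout, augmentation — derives from the
config seed, so a fixed seed reproduces the loss history bit for bit in
this single-threaded implementation. The checkpoint kept is the one with
the lowest validation loss (`checkpoint = "best"`); the final state is
also returned. A non-finite loss aborts immediately, naming the step and
sample.

The forward and backward passes are implemented in the package itself
(with RcppArmadillo kernels for the 3×3×3 convolutions, pooling and
upsampling), since the network architecture and its gradients are the
core subject matter; the backward pass is verified against central
differences through every layer type and both feedback wirings.

### Augmentation

Three augmentations mirror the training protocol for bilateral,
contrast-rich structures:

* **Flip pooling** (`flip_pool()`): left crops are mirrored along the
  left-right axis so all crops are right-oriented, doubling the training
  set (25 bilateral subjects yield 50 crops; 5 yield 10).
* **Random smooth/sharpen** (`smooth_sharpen()`): with equal probability a
  Gaussian blur (σ drawn from 0.3-1.2 voxels) or an unsharp mask (amount
  0.2-1.0), identical for both channels, emulating acquisition-quality
  variation. The ranges are package defaults, chosen to span visibly
  lower- to higher-quality images without destroying subfield contrast,
  and are exposed in `augment_config()`.
* **mixup** (`mixup()`): convex combinations of image pairs and their
  soft label fields with $\lambda \sim \mathrm{Beta}(0.3, 0.3)$.

Each augmentation applies independently with probability 0.5 per sample
(a package default, exposed in the config). Mixup partners are drawn
within the training set of the current fold. Spatial (elastic/affine)
augmentation is deliberately out of scope.

## Prediction: stored versus sample statistics

With batch size one, the running statistics a normalization layer
accumulates during training track a momentum average that can sit far
from any individual sample's statistics — and at test time the mismatch
degrades segmentations, especially under intensity drift between training
and test data. `predict_volume(..., mode = "ttbn")` therefore normalizes
every layer with the statistics of the presented sample, computed per
call, exactly as a training-mode forward pass would — but with dropout
disabled and the stored statistics left untouched. The interpretation of
"training-mode prediction" as *batch-statistics on, stochastic layers
off* is a deliberate choice: dropout at test time would randomize
segmentations, and the technique's motivation concerns normalization
statistics only. Prediction in either mode never mutates the model.

The test suite probes the mechanism from three sides: repeated calls are
bit-identical and stateless; when the stored statistics are set equal to
the sample's, the two modes coincide exactly; and on phantoms degraded by
a global intensity scale and shift after normalization (×1.5, +0.5), the
sample-statistics mode achieves mean Dice at least as high as the stored-
statistics mode across ten seeded replicates — in our runs the margin is
large (≈0.96 vs ≈0.77).

## Evaluation

`dice_coefficient()` implements $2|A \cap B|/(|A|+|B|)$ with the standard
degenerate conventions (both masks empty: 1; exactly one empty: 0).
`dice_report()` reports per-structure Dice for labels $1..NC-1$, their
unweighted mean, and the Dice of the union of all non-background labels
(the whole-structure overlap). `make_folds()` builds a deterministic
K-fold plan: seeded shuffle, contiguous partition, and the last
$\max(2, \mathrm{round}(n_\mathrm{train}/8))$ shuffled training ids held
out for validation — a rule that yields 40 training images (5 validation)
and 10 test images per fold for 50 samples at $K = 5$, and 8 (2) / 2 for
10 samples. `run_crossval()` trains one model per fold and pools
per-structure mean ± sd; `compare_architectures()` runs several specs on
identical folds for ablation tables.

## The phantom generator

`phantom_config()`/`generate_phantom()` produce the package's test
surface: a curved tube (an arc-swept circular cross-section, a "banana")
partitioned into 3-5 nested laminar shells, emulating the layered
geometry of hippocampal subfields. Each label receives a distinct mean
intensity per channel, with opposed contrast orderings across the two
channels (T1-like: darker core to brighter rim; T2-like: the reverse), a
smooth multiplicative bias field (seeded random linear gradient, ±20%
by default), and additive Gaussian noise (sd 0.1 on a unit intensity
scale — a mid-range contrast-to-noise regime for structural MRI).
Rician noise is deliberately omitted — at these SNRs Gaussian noise is an
accepted approximation, and the generator exposes the noise model should
that change. The default grid is 48×32×48 voxels at a nominal 0.5 mm
spacing — large enough to carry 3-5 shell layers of ≥2.5 voxels
thickness, small enough for CPU-scale training, and divisible through
3-4 resolution levels. Shell volumes admit a closed-form estimate
(Pappus' theorem for the arc-swept annuli plus spherical end caps)
against which the voxelized volumes agree within 15%. Bilateral mode
emits exact mirror pairs, which makes flip pooling testable to bit
equality. The geometry uses laminar shells only — angular sectors were
considered and dropped, as nesting alone exercises every consumer of the
labels.

What the phantoms do **not** emulate: anatomical shape variability,
partial-volume mixing at interfaces, Rician noise statistics,
registration error, or inter-protocol label ambiguity. Passing tests
therefore demonstrate that the pipeline's machinery — losses, gradients,
architecture, augmentation, statistics handling, evaluation — is correct
and learnable at desk scale, not that real-data accuracy figures are
reproduced; reproducing those requires the original repositories and
GPU-scale training, which are out of scope by design.

## End-to-end study conditions

The expensive checks run at fixed, package-default conditions: a tiny
network (3 levels, 8 base filters) trained with GJL for 300 optimizer
steps on 20 default phantoms reaches mean held-out per-structure Dice
≥ 0.80 on 5 fresh phantoms (≈0.82 in our runs); the same trained model
anchors the sample-statistics comparison above. These problem sizes were
chosen as the smallest at which learning is unambiguous; a single such
training run takes a few minutes on one CPU core and is shared across
the dependent checks within a test session.

## External stages

Denoising, bias-field correction and affine template registration are
established external tools, not reimplemented; `run_external_steps()`
orchestrates configured command templates in canonical order with
provenance, and warns when a configuration lists them out of order.
Super-resolution likewise remains an external hook. Volumes travel as
NIfTI via RNifti, with crop origins folded into the stored affine so
crops remain invertible. Label maps are only ever moved with
nearest-neighbour/majority logic, never smooth kernels.

## Known limitations

* Pure-R plus Rcpp training is CPU-bound: the full-size default network
  is practical for parameter accounting and architecture audits, not for
  training; training-scale work uses reduced specs.
* The nearest-neighbour upsampling and additive feedback reflect the
  calibrated default reconstruction; transposed-convolution upsampling is
  not currently offered.
* `batch_size` is accepted but the loop processes one volume per step —
  the reference protocol; larger batches would change normalization
  statistics semantics and are untested.
* The phantom generator's simplifications listed above bound what the
  end-to-end tests can claim about real MRI.
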