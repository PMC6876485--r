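---
title: "Two-stage lymph node detection with multi-view convolutional false-positive reduction"
author: "nodecad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage lymph node detection with multi-view convolutional false-positive reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pelvic MR Lymphography (MRL) uses an iron-oxide (USPIO) contrast agent to
make lymph nodes assessable on MRI, but reading an MRL study means finding
every lymph node — healthy or diseased — in a large 3D volume, which takes
expert readers up to 80 minutes. A computer-aided detection (CAD) system
that proposes all node locations for review can cut that time, provided its
false-positive rate is tolerable. The dominant failure mode is the
blob/tube ambiguity: a blood vessel crossing an image plane looks exactly
like a node in 2D, and only 3D context resolves it.

`nodecad` implements such a CAD pipeline in two stages:

1. **Candidate detection.** Per-voxel features (normalized channel
   intensities, multi-scale Hessian shape measures, positional maps) feed a
   GentleBoost classifier of 200 regression stumps, producing a per-voxel
   node likelihood in [0, 1]. Candidates are local maxima of this map under
   a spherical window of 10 mm diameter — the maximum size of non-enlarged
   lymph nodes — with plateau merging by 26-connected component analysis
   (each plateau is reduced to the member voxel nearest its center of
   gravity).
2. **False-positive reduction.** Around each candidate, 65 × 65 patches
   (0.8 mm pitch, spanning the 52 mm cube that encloses the candidate) are
   sampled on 1, 3 or 9 of the symmetry planes of that cube, and a
   multi-view convolutional network — one conv(5×5,24)–pool–conv(5×5,48)–
   pool–conv(5×5,96) branch per view, branches concatenated into FC-512 and
   a 2-way softmax, no weight sharing between branches — rescores the
   candidate with a node probability.

Both stages are evaluated jointly by free-response ROC (FROC) analysis:
sensitivity over all annotated nodes versus false positives per node (or
per image), summarized as the partial area under the curve (pAUC) between
0.25 and 32 FP/node, with patient-level bootstrap confidence bands and a
one-sided paired bootstrap test (Bonferroni-corrected for multiple
comparisons) between systems.

Because no patient data ship with the package, a synthetic phantom
generator provides the study material: dual-channel 0.8 mm isotropic
volumes with ellipsoidal bright nodes (3–10 mm), curved bright tubes,
thin sheets, and Gaussian noise, plus exact node label maps.

## Conventions and parameters that matter

**World coordinates.** Voxel index `i` (1-based in R) sits at
`(i - 0.5) * spacing` mm. Every module uses this convention; candidate
positions, patch sampling grids and node centers of gravity are all
expressed in it.

**Stage-1 voxel training set.** Positive rows come only from nodes of at
least 0.1 ml (≈195 voxels at 0.8 mm) and only within 4 mm of the node's
center of gravity; this excludes boundary voxels whose labels are
unreliable. Negatives are drawn uniformly from background, in equal number
(balanced classes). Both rules follow the reference protocol.

**Hessian shape features.** The reference system names blobness,
vesselness and sheetness but not their formulas, so the package adopts the
standard Frangi eigenvalue-ratio construction: with
`|λ1| ≤ |λ2| ≤ |λ3|`, the ratios `RA = |λ2|/|λ3|` and
`RB = |λ1|/sqrt(|λ2 λ3|)` and the structureness `S` (Frobenius norm)
combine into measures in [0, 1] that respond to bright spheres, tubes and
sheets respectively (α = β = 0.5; the structureness cutoff `c` adapts per
volume and scale to half the maximum Frobenius norm). Scales default to
{1.6, 2.4, 3.2} mm to bracket 3–10 mm nodes; responses aggregate across
scales by maximum. Shape features are computed on the T1-like channel by
default (configurable), with bright-structure polarity assumed.

One consequence worth knowing: per-volume intensity normalization plus the
per-volume-adaptive cutoff make stage 1 invariant to the global intensity
scale. A volume containing *nothing* is normalized until its noise looks
like weak structure, so featureless inputs still yield low-grade
candidates. On real data the same normalization is applied, and the
second stage exists precisely to dismiss such non-node candidates.

**Positional features.** The reference system used atlas registration of
pelvic anatomy; phantoms have no anatomy to register, so position is
encoded directly as three normalized coordinate maps plus one signed
Euclidean distance map (mm, negative inside) per optional landmark mask.
This preserves the *kind* of information (where in the volume a voxel
sits) without the out-of-scope registration machinery.

**Boost likelihood link.** The additive stump score `F` is mapped to
[0, 1] by `1/(1 + exp(−2F))`, the standard calibration for additive
logistic boosting; an empty model scores 0.5 everywhere. Stump thresholds
are searched at midpoints between consecutive distinct sorted feature
values, and ties break toward the lowest feature index — fitting is fully
deterministic given the row order.

**Candidate floor.** Without a likelihood floor, the all-background
plateau is itself a (huge) local-maximum component and would emit one
spurious candidate per volume; the floor defaults to 0.01 and is
configurable. Plateau equality is exact floating-point equality: plateaus
arise from identical computation paths, and any tolerance would merge
genuinely distinct maxima.

**Patch geometry.** All views sample with the in-plane step fixed at the
0.8 mm voxel pitch, so oblique patches span 52 × 52 mm inscribed in the
enclosing cube rather than stretching to the cube diagonal; this keeps the
physical scale identical across views, and 65 samples × 0.8 mm reproduces
the stated cube edge exactly. Samples outside the volume are zero-padded —
zero is the mean of the normalized background, so border candidates get
plausible, well-scaled patches. Patches are taken from the normalized
T1-like channel (the sequence used for node localization in the reference
protocol; configurable).

**Network and training.** The network follows the reference architecture
table exactly (65→61→30→26→13→9 per view; FC-512; 2-way softmax; ReLU
throughout; no padding; no weight sharing). Training is plain SGD with
learning rate 1e-4, Nesterov momentum 0.9, categorical cross-entropy plus
an L2 penalty of 5e-4 on weight matrices (not biases), 20% inverted
dropout on the hidden FC layer, minibatches of 32 with exactly 16 node and
16 non-node patch sets sampled with replacement, 200 minibatches per
epoch, at most 200 epochs, and early stopping when validation accuracy
(threshold 0.5, computed on the full validation set at each epoch's end)
has not improved for more than 20 epochs; the best-validation weights are
returned. Weight initialization is He-uniform with zero biases,
seed-controlled. Where the reference training protocol leaves a choice
open (per-batch sampling with replacement versus epoch-wise shuffling;
which layers receive dropout), the package chooses balanced
with-replacement sampling and dropout on the hidden FC activations, and
records both choices here.

The network itself is implemented in the package (single-precision
im2col + BLAS matrix products with analytic backpropagation); its
gradients are verified against finite differences in the test suite.

**Evaluation.** A candidate whose voxel lies inside a node's segmentation
is a hit; the hit criterion is not stated in the reference, and this is
standard FROC practice. At any threshold a node counts as detected if at
least one of its candidates reaches the threshold; additional candidates
inside an already-counted node are ignored (neither TP nor FP), which
prevents double counting. The pAUC integrates sensitivity (as a fraction)
against FP/node on a linear axis by the trapezoid rule between 0.25 and
32, anchored at the (0, 0) operating point, linearly interpolated at the
bounds, and step-extended beyond the last operating point — the maximum
attainable value is 31.75. The bootstrap resamples patients with
replacement; both systems are recomputed on the same resampled patients in
every replicate, so the pAUC comparison is a paired one-sided test with
the `(count + 1)/(n + 1)` small-sample correction, Bonferroni-multiplied
across comparisons. Cross-validation folds are assigned greedily at the
patient level — patients sorted by annotated-node count, each joining the
currently lightest fold — which balances node counts across folds to
within one patient's worth.

## The phantom generator: what it emulates, and what it does not

Each phantom is a pair of co-registered 64³ volumes at 0.8 mm (51.2 mm
field of view) emulating a T1-weighted ("VIBE"-like) and a T2*-weighted
("MEDIC"-like) acquisition, the two sequences of the reference MRL
protocol. Defaults: 4 ellipsoidal nodes with diameters uniform in 3–10 mm
(axis ratios 0.75–1, random orientation), 3 vessels swept along polylines
with mild random curvature (radius 1–2.5 mm), 1 thin sheet (1.6 mm), a
background level of 100 with additive node/vessel/sheet contrasts of
80/60/40 (T1-like) and 50/70/40 (T2*-like), a 0.4 mm partial-volume blur,
and Gaussian noise with SD 10. Nodes never overlap each other or the other
structures; vessels curve enough to intersect sampling planes both along
and across their axis, reproducing the tubular-versus-nodular ambiguity
that drives stage-1 false positives. An option makes nodes hypointense in
the T2*-like channel (the USPIO-uptake appearance of healthy nodes); it is
off by default since stage 1 consumes intensities of both channels either
way.

The generator does **not** simulate MR physics: no bias fields, no
USPIO uptake kinetics, no pelvic anatomy, no inter-patient anatomical
variability, no annotation error. Consequently, passing phantom tests
demonstrates that the pipeline's machinery is correct and that the
multi-view stage can exploit 3D context to dismiss tubular false
positives; it does not demonstrate clinical-grade performance, and the
absolute pAUC values on phantoms are (much) higher than anything
attainable on patient data.

A note on the placement margin: structures keep a configurable margin
(default 6 mm) from the grid boundary — enough to contain each structure
fully, but much less than a patch half-width (26 mm). Patches near borders
are therefore partially zero-padded by design; requiring a full
patch-width margin would make desk-scale grids impractically large.

## The reference phantom study

`phantomStudyConfig()` fixes the package's own study conditions: 20
evaluation phantoms plus 4 separate phantoms used only to train stage 1
(the reference study cross-validated the first stage as well, but with 240
patients; at desk scale a small dedicated training set avoids refitting
features five times while keeping the evaluation phantoms untouched by
stage-1 training), stratified patient-level 5-fold cross-validation of the
3-view network (3 folds train, 1 validates, 1 tests; test-fold
probabilities pooled), and 1000 bootstrap replicates.

The CNN schedule in this configuration is shortened to 5 epochs × 10
minibatches at learning rate 1e-3: with tens of phantoms, the blob/tube
discrimination task saturates validation accuracy within a few hundred
balanced minibatches, and the larger step compensates for the
proportionally fewer updates. The reference protocol values (1e-4,
200 × 200, patience 20) remain the package defaults in
`pipelineConfig()` and `trainConfig()`.

With these conditions the experiment reproduces the direction of the
reference finding: the 3-view-CNN-rescored system attains a higher pooled
cross-validated pAUC than the stage-1 candidate detector, and fewer false
positives per image at 80% sensitivity, with the one-sided paired
bootstrap test significant. `scripts/acceptance.R` reruns the whole study
from scratch and writes the numbers; the test suite asserts the direction.

## Numerical choices and degenerate inputs

* Gaussian and derivative-of-Gaussian kernels are sampled at ±3σ and
  sum-normalized; Hessian responses are scale-normalized by σ².
* Symmetric 3×3 eigenvalues use the trigonometric closed form (stable for
  smooth fields); eigenvalues sort by absolute value.
* A constant volume cannot be normalized (σ = 0) and raises an error; a
  zero volume yields identically zero shape maps (the adaptive cutoff
  would otherwise divide by zero).
* The distance transform is the exact Felzenszwalb–Huttenlocher algorithm
  with "absent" parabolas encoded as a large finite constant.
* Pooling ties take the first element (deterministic); boosting stops
  early if observation weights degenerate to the point that no valid split
  remains, returning the stumps fitted so far.
* Fold assignment, batch sampling, dropout, bootstrap resampling and all
  phantom geometry draw from R's RNG under seeds fanned out from one
  global seed by fixed offsets, so a single integer reproduces a full run
  (the CNN additionally computes in single precision, deterministically on
  a given BLAS).

## Known limitations

* Phantom realism, as above: no anatomy, no MR physics, no annotation
  noise. Absolute performance numbers do not transfer to patients.
* The scale-invariance caveat: structure-free volumes still produce
  low-grade candidates (see the normalization note).
* The 9-view configuration is supported and tested, but the reference
  study's second-order question (9 views versus 3) is not re-examined at
  phantom scale, where both saturate.
* `partialAUC` interprets the FROC between operating points linearly
  (trapezoid); systems evaluated at very few distinct scores are
  accordingly interpolated, not stepped.
* The raw-FROC table reader auto-detects comma/semicolon/tab/whitespace
  dialects and percent-versus-fraction sensitivities, but expects the
  first two numeric columns to be (FP rate, sensitivity).
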