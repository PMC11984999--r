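---
title: "Harmonizing mammograms for federated BIRADS classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing mammograms for federated BIRADS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fedmammo)
```

## The problem

Hospitals that want to co-train a BIRADS classifier on mammograms cannot
pool their images: the data stays on premises and only model weights are
exchanged (federated learning, FedAvg). That setting is brittle in a way
centralized training is not. Scanners at different sites emit different
raw intensity ranges, opposite photometric conventions (`MONOCHROME1`
stores the breast *dark*), different pixel spacings and lateralities, and
site-specific artifacts — printed laterality/view labels, surgical clips,
implants. Pooled training averages these nuisances away; federated
training amplifies them, because each client overfits its own convention
and the merged model serves the worst-harmonized site poorly.

`fedmammo` implements the full counter-measure pipeline as testable
components:

1. **Metadata-driven preprocessing** (`preprocess()`): DICOM rescale,
   inversion decision, percentile windowing onto a common scale,
   laterality alignment, spacing-aware resize.
2. **Breast Area Detection (BAD)**: bootstrap masks by K-means
   (`kmeans_mask()`), automated selection (`quality_filter()`), fake-label
   augmentation (`augment_with_fake_labels()`), a small UNet
   (`train_unet()` / `predict_mask()`), and mask-guided cleaning
   (`clean_and_crop()`).
3. **Patient-wise cohort management** (`filter_cohort()`,
   `patientwise_split()`, `assemble_federation()`).
4. **A compact CNN classifier** (`build_model()`, `train_centralized()`,
   `evaluate_f1()`).
5. **An in-process FedAvg simulator** (`run_federated()`,
   `rounds_epochs_sweep()`, `harmonization_ablation()`).
6. **A phantom generator** (`generate_phantom()`, `generate_cohort()`)
   that stands in for clinical data, with analytic ground truth.

## The phantom generator

Every downstream stage is validated on synthetic phantoms because the
clinical cohorts the pipeline was designed around are not distributable.
A phantom is a half-elliptical "breast" attached to the left or right
image border, textured by smoothed multiplicative noise, so the
ground-truth mask is known analytically. Per-hospital heterogeneity is
controlled by `hospital_profile()`:

* `intensity_range` — raw stored-value range of the detector. The default
  demo federation uses disjoint ranges (0–1023 vs 2000–4095), an
  exaggerated but structurally faithful version of inter-site intensity
  shift.
* `photometric` — `MONOCHROME1` stores the presentation-inverted image,
  exactly as such scanners do; the phantom's stored breast is darker than
  its background.
* `label_prob`, `clip_prob`, `implant_prob`, `mis_scan_prob` — artifact
  rates. Clinical sources do not characterize artifact statistics, so
  these are free parameters, not estimates; defaults (0.2–0.6 for labels,
  0.1–0.25 for clips, 0.05 for patient-level implant / mis-scan flags)
  were chosen once so that a modest cohort contains several of each
  artifact. Labels are bright rectangles with glyph-like texture placed
  entirely in open background (with a small clearance halo around the
  breast, as real corner labels sit in free background); clips are 2–5
  small near-white disks inside the breast; an implant is one large
  bright disk.

The BIRADS class signal is deterministic given the class: class $b$
carries $2(b-1)$ lesions of radius 4.5–6% of the image side with additive
brightness $0.12 + 0.06(b-1)$. Lesion burden is therefore non-decreasing
in $b$, which is what makes classifier parameter recovery meaningful.
What the phantoms deliberately do **not** emulate: anatomy (pectoral
muscle, ducts, skin line), realistic lesion morphology, scanner noise
spectra, or label text semantics. Passing tests demonstrate that the
pipeline's *mechanics* (geometry, metadata handling, leakage control,
federation dynamics) are correct — not that the classifier would reach
clinical accuracy on real mammograms.

All randomness flows from explicit integer seeds through a splittable
hash (`derive_seed()`); no stage touches the global RNG state outside a
seeded scope, so every artifact is bit-reproducible.

## Preprocessing model

The harmonization steps run in a fixed order: rescale → inversion →
windowing → laterality flip → spacing-aware resize.

* **Rescale**: `output = slope * stored + intercept`, the standard DICOM
  linear map.
* **Inversion**: triggered if the Pixel Intensity Relationship Sign is
  +1, or the Photometric Interpretation is `MONOCHROME1`, or the
  Presentation LUT Shape is `INVERSE`. Each pixel is subtracted from the
  *image maximum* (not the bit-depth maximum) — a deliberate fidelity
  choice; it guarantees a zero minimum and preserves rank order.
* **Windowing**: intensities are clamped to the [0.5, 99.5] percentile
  window and the window is mapped to [0, 1]. The percentile clamp removes
  hot/dead pixels; the mapping is the step that actually aligns
  hospital-specific detector ranges onto one scale (without it, a
  0–1023-range site occupies a quarter of the intensity axis of a
  0–4095-range site after shared min/max normalization, and the ablation
  below shows the federated model then fails both sites). Windowing runs
  after inversion and before the flip/resize. Set `clip = NULL` to skip
  it.
* **Laterality**: images with Image Laterality `R` are flipped so the
  breast is always attached to the left border. A missing laterality is
  an error, not a default — flipping is bias-critical. Other optional
  attributes default to the non-inverting values.
* **Resize**: anisotropic pixel spacing is first resampled to isotropic
  at the coarser spacing (preserving physical aspect ratio), then scaled
  to the target (512×512 by default). Images use bilinear interpolation,
  masks nearest-neighbour so they stay binary.

The output record's metadata is rewritten to the post-harmonization
convention (slope 1, intercept 0, `MONOCHROME2`, `IDENTITY`, sign −1,
laterality L, isotropic spacing), making `preprocess()` idempotent on its
own output — exactly so with `clip = NULL`, and to within re-windowing of
interpolated tails (< 2% of the range) with the default window.

## Breast Area Detection

Real mask supervision does not exist, so BAD bootstraps it:

1. **K-means masks** with $k = 2$ on pixel intensities. The field's
   sources leave $k$ unstated; $k = 2$ matches the bimodal
   breast-vs-background structure of a mammogram, and the downstream
   filter catches failures. `stats::kmeans` (Hartigan–Wong) is run with
   three seeded starts — 1-D intensity clustering at $k = 2$ is
   insensitive to initialization given restarts. The brightest cluster is
   kept, reduced to its largest connected component, holes filled:
   printed labels are bright but form separate components and drop out
   here.
2. **Automated selection** replaces the visual inspection a human would
   perform: accept iff mask area fraction ∈ [0.08, 0.75], the mask
   touches exactly one vertical border, and solidity (area / convex hull
   area) ≥ 0.85. Thresholds are tunable arguments; they are a stand-in
   for judgment, not a calibrated procedure.
3. **Fake-label augmentation** turns each accepted mammogram into 5
   variants — the original plus four copies each carrying one bright
   rectangle (side 5–20% of the image, intensity at the 99th percentile
   of breast pixels, placed by rejection sampling entirely outside the
   mask). The variant's mask equals the original mask, which is what
   teaches the UNet that labels are non-breast. Background-only placement
   was chosen because real laterality/view labels lie in free background.

The segmenter is a compact UNet: `depth` pooling levels (2 at desk scale,
configurable) with two 3×3 convolutions per level, base width 8 doubling
per level, nearest-neighbour upsampling with skip concatenation. The loss
is soft Dice + binary cross-entropy — a standard pairing that is robust
to the foreground/background imbalance of full-frame masks. Training
uses Adam at 1e-3, per-image min-max scaling, and keeps the
lowest-validation-loss checkpoint. Following the 1000/300/remainder
protocol, `split_auld()` assigns *source images* (not samples) to sets so
all five variants stay together — otherwise near-duplicates of training
images would leak into validation.

Inference thresholds the sigmoid map at 0.5, keeps the largest component
and fills holes; `clean_and_crop()` zeroes everything outside the mask,
crops to the bounding box plus a 4-pixel margin and resizes to 256×256,
the classifier's input geometry. Empty predictions raise an error telling
the caller to fall back to the uncleaned image (the pipeline does).

## Cohort management

`filter_cohort()` drops BIRADS 0 and 6 images (noisy labels) and all
images of patients flagged with implants or incorrect scans — exclusion
operates on patients, as clinical review does. `patientwise_split()`
partitions *patients* 70/20/10 with largest-remainder rounding (ties
broken in train > val > test order; a set left empty by rounding takes
one patient from the largest set, so any cohort of ≥ 3 patients splits).
Patients are assigned in seeded-shuffled order grouped by BIRADS, which
spreads classes across sets — best-effort stratification that stabilizes
tiny synthetic cohorts and costs nothing when classes are balanced.
Whether to stratify was an open choice; it never changes the exact set
sizes. `assemble_federation()` gives every training hospital its
train+val sets as one client and keeps every hospital's test set separate
(test-only hospitals contribute their whole cohort as a test set), so
performance is always reported per data provider.

## Classifier

The BIRADS model is a deliberately small CNN: 3×3 conv + ReLU + 2×2
max-pool blocks (widths 8/16/32), global average pooling, and a linear
head — ~6k parameters, far below the 2M communication budget a federated
round can afford. GAP makes the parameter count independent of input
resolution, so the same architecture runs at 256×256 (the pipeline
geometry) and at 64×64 (desk-scale experiments).

Normalization follows the train-set-only min/max protocol:
`compute_norm_stats()` accepts only the training partition, and values
outside the training range (possible under hospital shift) clamp to
[0, 1] rather than extrapolate. The reference training recipe
(cross-entropy, Adam, batch 10, 100 epochs, learning rate 1e-8) is kept
as `train_config()`'s default for fidelity; 1e-8 is impractically small
at desk scale, so examples and tests override `lr` to 1e-3. Evaluation
reports macro-averaged F1 over the classes present in the truth labels —
the unweighted mean is the right summary under the strong class imbalance
typical of BIRADS distributions — plus a full confusion matrix per test
set.

## FedAvg simulation

`run_federated()` is a synchronous in-process simulator: each round
broadcasts the global weights, every client trains `local_epochs` passes
over its data, and `fedavg_merge()` averages parameters — by sample count
(canonical FedAvg) by default, uniformly on request; the underlying
description of the merge is ambiguous between the two, so both are
exposed. Two design choices matter for reproducibility:

* **Client optimizer state persists across rounds.** The merge operates
  on weights only, and each client keeps its Adam moments. Consequence: a
  single-client federation is *bit-identical* to centralized training
  with the same seed and the same total epochs — the equivalence the test
  suite asserts. Data order is reshuffled every local epoch with a
  global-epoch-indexed seed shared by both code paths.
* **The merge is computed in anchored form**
  $p_1 + \sum_{k>1} w_k (p_k - p_1)$, algebraically the weighted mean but
  exact when all clients coincide — merging $K$ copies of a model returns
  that model bit for bit.

Normalization statistics in the federation are computed per client and
merged to a global min/max before round 1 (`federated_norm_stats()`) —
the "exchange normalization values" mitigation; per-client-only
normalization is available for ablations.

`rounds_epochs_sweep()` compares (rounds, local-epochs) schedules with a
common initial model — the reference protocol is (100, 1), (50, 2),
(20, 5), all 100 total epochs — and warns when combinations differ in
total epochs, since they are then not comparable.

## The harmonization ablation

`harmonization_ablation()` reproduces the central qualitative finding at
desk scale: on a deliberately heterogeneous two-hospital federation
(disjoint detector intensity ranges, labels and clips present), it
trains condition **A** (minimal preprocessing: raw
stored pixels resized to the model input) and condition **B** (full
harmonization: `preprocess()` + breast-mask cleaning) with identical
splits, shared normalization and identical FL schedules, and reports
per-hospital F1, the worst-hospital F1 and the inter-hospital spread.
The expectation is directional — B's worst hospital at least matches
A's, with a smaller spread; the magnitude of the published improvement is
not reproducible without the original hospital data. Inside the ablation,
condition B's masks come from the quality-filtered K-means bootstrap
(falling back to the full-image mask when rejected) rather than a freshly
trained UNet: the ablation isolates the harmonization effect, the mask
source is pluggable via `mask_fun`, and the end-to-end demo exercises the
trained-UNet path.

Three aspects of the ablation cohort are deliberate, because the
comparison only means something in the *asymmetric-collapse* regime —
minimal-preprocessing FL serving one hospital and failing the other:

* **One photometric convention, disjoint ranges.** If one hospital's raw
  images are additionally presentation-inverted, the minimal condition
  collapses for *both* hospitals, and a near-chance federation trivially
  has a small spread. Inverted-presentation handling is exercised by the
  preprocessing tests and the end-to-end demo instead.
* **Equal artifact rates across hospitals.** Unequal label/clip rates are
  a residual domain gap that mask-cleaning cannot fully close, so the
  harmonized condition's hospitals would drift apart under long training
  for reasons unrelated to intensity harmonization. With equal rates the
  harmonized hospitals are identically distributed, and the spread
  criterion isolates exactly the intensity-range axis.
* **An imbalanced federation (20/80).** With equal client sizes,
  sample-weighted FedAvg under minimal preprocessing often stalls on both
  clients at once; with a clear majority hospital the merge reliably
  learns the majority and collapses on the minority — the phenomenon
  harmonization is meant to repair. Data providers of equal size are the
  exception in practice anyway.

Per-hospital F1 is tail-averaged over the last 10 rounds (round-to-round
jitter on small test sets otherwise dominates) and evaluated on each
hospital's val + test patients — FL clients train on the train split
only, so validation patients remain held out and roughly triple the
minority hospital's evaluation set.

## Numerical choices and degenerate inputs

* Empty ∩ empty masks have Dice = IoU = 1 (perfect-agreement
  convention), making the metrics total; the identity
  IoU = Dice / (2 − Dice) is used as a cross-check in tests.
* K-means ties are broken by lowest cluster index; a constant image is an
  error (no cluster separation), as is a rescale slope of 0 and an
  empty array for inversion.
* Non-finite training losses abort with the epoch named rather than
  silently diverging.
* Conv weights use He initialization; convolutions are im2col + GEMM in
  compiled code with zero padding; pooling is 2×2 max with argmax
  backward. Input sides must be divisible by `2^depth` (UNet) or
  `2^n_blocks` (classifier).
* Arrays are row-major in DICOM pixel data, column-major internally;
  origin top-left; masks are logical matrices aligned with their image.

## Problem sizes

The test-suite and acceptance runs use sizes chosen as honest desk-scale
study conditions: 200 phantoms at 128×128 (150/20/30) and 5 epochs for
UNet recovery; a 300-patient, 64×64 cohort for classifier recovery (50
epochs) and for the ablation (40 rounds × 2 epochs per condition); tiny
16×16 federations for the exact-bookkeeping and equivalence checks; the
full 512×512 → 256×256 geometry is asserted directly. The UNet converges
on phantoms within 1–2 epochs; extra epochs are margin, not tuning.

## Known limitations

* The DICOM codec reads and writes explicit-VR little-endian single-frame
  files with the attribute set the pipeline consumes; it is not a general
  DICOM implementation (no sequences, no compressed transfer syntaxes, no
  VOI LUT pipelines).
* The simulator is synchronous and in-process: network latency, stragglers,
  secure aggregation and client failure are out of scope.
* Phantom realism bounds what the tests can claim (see above); the
  pipeline's clinical performance must be established on real data.
* The UNet and CNN run on a purpose-built dense conv engine; it is exact
  (gradient-checked) but single-threaded and desk-scale by design.
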