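---
title: "Texture-based grading of tissue-section images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based grading of tissue-section images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texgrade)
```

## The problem

At low magnification (×10), a breast-cancer tissue section reveals its
*architecture* rather than individual nuclei: alveolar (gland-like)
structures, stromal texture, areas of necrosis and inflammation, and the
overall density of cells. Histological grading (I–III) at this scale is a
pattern-recognition task on texture, and `texgrade` implements a complete
pipeline for it:

1. **Feature extraction** — 30 texture descriptors per 512×512 grayscale
   region of interest (ROI): 4 first-order statistics, 16 co-occurrence
   (Haralick) descriptors, and 10 run-length (Galloway) descriptors.
2. **Feature reduction** — a per-feature one-way ANOVA significance filter
   at p < 0.001.
3. **Model selection** — exhaustive search over all feature subsets up to a
   size cap, scored by leave-one-out (LOO) accuracy.
4. **Classification** — kNN (k = 3), a probabilistic neural network (PNN),
   or an RBF support vector machine, behind one train/predict contract.
5. **Validation** — LOO on the full dataset, and external cross-validation
   (ECV): repeated stratified 2/3 design / 1/3 evaluation splits in which
   *all* filtering and subset-selection decisions are made inside the
   design fold.

Because the clinical images such a study uses are generally not
distributable, the package also contains a first-class synthetic generator
that emulates the three grade morphologies, so that every downstream stage
is testable end to end.

## The feature set

**First order.** Population mean, standard deviation, skewness
$m_3/m_2^{3/2}$ and Fisher excess kurtosis $m_4/m_2^2 - 3$ of the raw
intensities. A zero-variance image returns skewness = kurtosis = 0 by
convention.

**Co-occurrence (GLCM).** The image is quantized to $G = 32$ levels and the
normalized, symmetrized joint histogram $P(i,j)$ of level pairs at distance
1 is formed for each direction $\theta \in \{0°, 45°, 90°, 135°\}$. Eight
descriptors are computed per direction on 0-based level indices: energy
$\sum P^2$, contrast $\sum (i-j)^2 P$, correlation, variance, inverse
difference moment, entropy ($\log_2$, with $0\log 0 = 0$), and sum average
/ sum entropy over the diagonal-sum distribution $p_{x+y}$. Each descriptor
is reported **averaged** (`a`) and **ranged** (`r`, max − min) over the four
directions: 8 × 2 = 16 features. Degenerate correlation (zero marginal
variance) is defined as 0.

**Run length (RLM).** The image is quantized to $G = 16$ levels; maximal
constant-level runs are counted along every scan line of each direction
(diagonal scans include the length-1 corner lines). With $n(i,j)$ the count
of level-$i$ runs of length $j$ and $N_r = \sum n(i,j)$:

$$\mathrm{SRE} = \tfrac{1}{N_r}\sum \tfrac{n(i,j)}{j^2},\quad
  \mathrm{LRE} = \tfrac{1}{N_r}\sum n(i,j)\,j^2,\quad
  \mathrm{GLNU} = \tfrac{1}{N_r}\sum_i \Big(\sum_j n(i,j)\Big)^2,$$
$$\mathrm{RLNU} = \tfrac{1}{N_r}\sum_j \Big(\sum_i n(i,j)\Big)^2,\quad
  \mathrm{RP} = N_r / N_{\mathrm{pixels}},$$

each again as `a` and `r`: 5 × 2 = 10 features. SRE lies in (0, 1] and
equals 1 exactly when every run has length 1; the package's test suite
verifies all descriptors against an independent brute-force enumeration.

### Quantization convention

Levels are assigned per image by linear min–max binning,
`level = min(G - 1, floor((v - min) * G / (max - min)))`, constant images
mapping wholly to level 0. The denominator `max - min` (rather than
`max - min + 1`) makes the binning *exactly* invariant under positive
affine intensity rescaling — a property the test suite locks — while still
splitting the full 8-bit range into equal 16-intensity bins at G = 16.
$G = 32$ for the co-occurrence channel and $G = 16$ for runs are common
practice for 8-bit 512² images; both are exposed in `feature_config()`.

### Which 16 co-occurrence features?

Descriptor sets in the literature vary. This package fixes the 16
second-order features as the 8 classic Haralick descriptors × {average,
range}, mirroring exactly the `a`/`r` aggregation that the run-length
family uses (SREa, RLNUr, …). That choice yields 16 by construction and
keeps one uniform aggregation rule across both matrix families.

## Classifiers

All three back ends see z-score-standardized features; the mean and
standard deviation are always estimated from the training fold only, and
queries are transformed with those frozen statistics. kNN and PNN are
scale-sensitive, the literature rarely reports whether standardization was
applied, so it is applied uniformly here and the no-leakage contract is
tested explicitly.

* **kNN** (default k = 3): majority vote among the k nearest training
  vectors in Euclidean distance. Every tie is deterministic: distance ties
  resolve by training-set order, vote ties by the class of the single
  nearest neighbour among the tied classes.
* **PNN**: per class $c$, the Parzen score
  $g_c(x) = \tfrac{1}{n_c}\sum_{i \in c} \exp(-\lVert x - x_i\rVert^2 / 2\sigma^2)$,
  predicting the argmax. Score ties — including complete kernel underflow
  as $\sigma \to 0$, in which case PNN provably reduces to 1-NN — fall back
  to the class of the nearest training sample.
* **SVM**: soft-margin RBF machine (one-vs-one multiclass) via
  \pkg{e1071}/libsvm, with fixed defaults C = 10 and
  $\gamma = 1/(d \cdot \mathrm{var})$ of the standardized training matrix.
  No per-fold kernel tuning is done by default: reproducibility is
  preferred over benchmark-chasing, and both parameters are exposed.

### The PNN spread

No single kernel width suits subsets of different dimensionality, so the
spread is parameterized as a multiplier of the **root-mean-square pairwise
distance** of the standardized training data. The RMS scale (rather than
the arithmetic mean distance) was chosen because it admits an exact
closed-form leave-one-out update: with per-fold standardization the fold
mean cancels in every pairwise difference, and both the fold distances and
the fold RMS scale can be reconstructed from per-feature sums — which makes
the package's C++ LOO scorer *bit-exact* with respect to the naive
fit/predict loop (an equivalence the test suite asserts on random data).
`spread = "auto"` selects the multiplier from the grid 0.05, 0.10, …, 1.00
by LOO accuracy on the training data, smallest multiplier on ties. Inside
`exhaustive_search()` the grid is resolved **once per training fold** (on
the full candidate set) and then applied to every subset; re-running the
grid inside each of ~10⁵ subsets would multiply the search cost twenty-fold
while making subset scores incomparable across different spreads.

## Selection and validation protocol

The filter retains features whose one-way ANOVA across the three grades has
p < 0.001. "MANOVA" in this literature is ambiguous; the operative reading
that yields a retained-feature *list* is per-feature testing, so that is
what gates features here, while a dataset-level Wilks'-lambda MANOVA is
computed and reported for reference (`wilks_p`). Zero-variance features get
p = 1 and a warning; zero within-class variance with between-class signal
is the degenerate F → ∞ limit and yields p = 0.

`exhaustive_search()` enumerates every subset of size 1..`max_subset_size`
(default 5 — published best subsets in this problem have 2–4 features, and
the cap keeps the combinatorics at desk scale). Ties break toward higher
accuracy, then smaller subsets, then lexicographic feature names, making
the search deterministic and invariant to candidate ordering. Once a size
achieves a perfect LOO score the remaining sizes are skipped — under the
strict-improvement tie-break no larger subset can win, so the shortcut is
exact. With the SVM back end the candidate list is truncated to the top 8
features by filter p-value, because libsvm must be refit n times per subset
and an exhaustive enumeration over ~10⁵ subsets is computationally
infeasible with any realistic budget; kNN and PNN use the closed-form LOO
path and search the full candidate set.

ECV draws `floor(n_c / 3)` test samples per class — with class sizes
(20, 20, 25) that is a (6, 6, 8) test fold, the only scheme consistent with
per-class accuracies quantized to multiples of 1/6 and 1/8 — and repeats
over `n_trials = 10` seeded splits. Summaries report mean ± *sample*
(n − 1) standard deviation; the package's regression tests lock both the
n − 1 convention and half-up one-decimal rounding (a column mean of 86.25
must report 86.3, where IEEE half-even rounding would print 86.2).

Within the reported LOO evaluation the feature subset is *fixed* (selection
happens before it); within ECV, selection is redone per trial inside the
design fold, and a leakage audit in the test suite re-derives every trial's
subset from a physical copy of the design fold alone.

## The synthetic generator

`generate_roi()` draws, back to front: Gaussian background noise (stroma),
bright smooth ellipses (alveolar structures), mottled mid-gray patches
(necrosis/inflammation), and small dark disks (nuclei), then rounds and
clamps to 8 bits. Defaults per grade:

| parameter | I | II | III |
|---|---|---|---|
| alveoli (count, radius px) | 150, 8–20 | 60, 8–18 | 10, 8–16 |
| nuclei (per 10⁴ px², radius px) | 3, 2–4 | 8, 2–4 | 16, 2–4 |
| necrosis patches (count, radius px) | 0 | 4, 35–65 | 8, 50–90 |
| intensities (bg/alv/necr/nucl) | 180/200/140/60 | same | same |
| background noise sd | 5 | 5 | 5 |

The palette keeps hematoxylin-like dark nuclei on pale stroma with pale,
low-contrast alveoli. The counts make the morphological orderings strict by
construction — nuclei I < II < III, alveoli I > II > III, necrosis
0 = I < II ≤ III — and were calibrated once so that the three ordinal
feature trends hold in the per-grade *medians* of the default 65-ROI
dataset for every master seed 1–5:

* **SREa increases with grade** — growing cellularity and mottled necrosis
  shorten runs;
* **GLNUa decreases with grade** — grade I's runs concentrate in the few
  gray levels of stroma and same-level alveoli, while higher grades split
  run mass across the distinct levels of necrosis and nuclei;
* **RLNUa increases with grade** — fine-grained texture concentrates runs
  at short lengths while also multiplying them.

The background noise level is deliberately *shared* across grades: GLNU is
the total run count times the concentration of runs over levels, and an
early design with grade-specific noise levels confounded the two factors.

`generate_dataset()` reproduces the study geometry — 13 sections (4/4/5 per
grade, one patient each) × 5 ROIs = 65 ROIs of 512², 20/20/25 per grade —
with all 5 ROIs of a section sharing its grade and `source_id`, enabling
grouped (per-patient) splits as a future extension. Per-ROI seeds derive
deterministically from one master seed; identical seeds give bit-identical
images.

**What passing tests do and do not show.** The generator produces
stationary object-plus-noise textures with exact class structure and no
staining variation, focus blur, tiling artifacts, or patient-level
covariate shift. The classes are much better separated than real grades,
so the pipeline's near-perfect synthetic ECV accuracy validates the
*protocol machinery* (no leakage, correct aggregation, deterministic
selection), not clinical performance. Conversely, feature-level
correctness is established independently of the generator, against
brute-force oracles on enumerable images.

## Numerical choices and degenerate inputs

* RGB inputs convert by Rec. 601 luminance with round-half-up — bit-exact
  across platforms; conversion is idempotent.
* Intensities above 8 bits are rejected with an instruction to rescale
  explicitly, rather than silently renormalized.
* Constant images: quantize to level 0, GLCM energy 1 / entropy 0 /
  correlation 0, one run per scan line.
* All seeds are plain 32-bit integers; every random step (generator,
  splits) is seeded explicitly, and RNG state is restored after use.
* Problem sizes used by the shipped validation runs: the in-package checks
  run the full 65 × 512² design over five master seeds with 10 ECV trials
  each; unit tests exercise the same code paths on smaller ROIs (48–128 px,
  with object counts scaled by area) where the study scale adds nothing.

## Known limitations

* The exact identity of the 16 co-occurrence descriptors and the
  quantization depths used in the motivating literature are unstated there;
  the choices here are documented assumptions, exposed as configuration.
* ECV splits at ROI level, so ROIs of one section can straddle design and
  evaluation folds; a grouped per-patient mode is the natural sensitivity
  analysis and the manifest already carries the grouping.
* Rotation invariance of the classifiers holds only up to per-feature
  standardization (which is applied uniformly); translation and per-feature
  affine invariance are exact and tested.
* The SVM search cap (top-8 candidates by p-value) is a computational
  necessity, not part of the evaluated contract for kNN/PNN.
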