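---
title: "Committee uncertainty sampling for slice-level tumor grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee uncertainty sampling for slice-level tumor grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbcselect)
```

## The model and its assumptions

`qbcselect` implements single-round, query-by-committee active learning for
binary classification of tumor-bearing MRI slices (HGG = 1, LGG = 0). The
procedure assumes a training pool of N slices of which a fraction
(default 30%) is already labeled, and works in four steps:

1. **Committee construction.** The same base classifier is trained M times
   on the labeled seed, varying only the learning rate (defaults 0.001,
   0.0005, 0.0001, so M = 3). Members therefore share the data and all
   other hyperparameters; their disagreement reflects optimization-path
   sensitivity, not data heterogeneity.
2. **Forward-only scoring.** Each member predicts class probabilities for
   every sample in the pool. No labels are read at this stage, so the
   scored pool may be entirely unlabeled.
3. **Uncertainty score.** Per sample, the score is the sum of all member
   entropies plus the Kullback–Leibler divergence over all ordered member
   pairs. Entropy captures each member's own uncertainty;
   the pairwise divergence captures disagreement between members.
4. **Selection.** The pool is ranked by descending score; the top
   `exclude_top` and bottom `exclude_bottom` fractions (10% each by
   default) are discarded, and a budget (default 30% *of the full pool*)
   is sampled uniformly from the remainder. Only the selected subset is
   used for the final training; the labeled seed enters only the cost
   accounting.

The rationale for discarding both extremes: the most disagreed-about
samples tend to be outliers (mislabeled or atypical acquisitions) whose
labels would be spent on noise, while the most agreed-about samples are
redundant and add no training value. The annotation cost of the
procedure is the union of the seed and the selected subset, which for a
30% seed and 30% budget lies between 30% and 60% of the pool —
equivalently a saving between 40% and 70% (mean 55%) relative to
labeling everything.

## Design choices in the score

Several details of the score are underdetermined by its verbal
definition; the package fixes them as follows.

* **Logarithm base: natural (nats).** The only downstream use of scores
  is ranking, and a change of base rescales every score by the same
  positive constant, leaving the ranking unchanged. A property test
  asserts this on random profiles.
* **"Pairwise" KL: all ordered pairs.** The divergence is asymmetric, but
  the committee's disagreement should not depend on member order, so both
  directions of every unordered pair are summed. This realizes the
  symmetrized divergence exactly and makes `kl_sum` invariant under member
  permutation. (Summing unordered pairs once would halve every `kl_sum`,
  which is rank-neutral for this symmetric form; the ordered-pair
  convention was chosen as the self-contained one.)
* **Zero-probability handling.** All probabilities are clipped to
  `[1e-12, 1]` before logs and ratios, without renormalization. Saturated
  classifier outputs then give a large finite divergence
  (about 27.6 nats per direction) instead of `Inf`, and the perturbation
  to non-degenerate scores is below 3e-11 — negligible against every
  tolerance in use.
* **Tie-breaking: ascending sample id, radix order.** Ties in the score
  are broken deterministically so that selection is reproducible across
  platforms and locales.
* **No weighting** between the entropy and divergence terms: the score is
  their plain sum. Entropies lie in [0, log C] per member while the
  divergence is unbounded, so strong disagreement dominates the top of the
  ranking by construction.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `learning_rates` | 0.001, 0.0005, 0.0001 | one committee member per rate |
| `max_epochs` | 30 | training passes per member |
| `batch_size` | 16 | SGD mini-batch size |
| `momentum` | 0.8 | SGD momentum |
| `l2_penalty` | 1e-4 | L2 regularization strength |
| `exclude_top`, `exclude_bottom` | 0.10, 0.10 | discarded ranking extremes |
| `budget` | 0.30 | selected fraction of the full pool |
| `k_hgg`, `k_lgg` | 20, 20 | slices extracted per patient (10/30 for the balanced variant) |
| `target_size` | 224 | slice side length after resizing (pixels) |

Percentile ranges on the ranking use the 0-based half-open convention
`[floor(lo·N), floor(hi·N))`, so adjacent ranges such as 10–40% and
40–70% compose without overlap, and `exclude_extremes(a, b)` equals
`select_range(a, 1 − b)`. Budget fractions convert to counts by round
half up, which reproduces the usual printed correspondence tables
exactly (e.g. 30% of a 4,060-slice pool is 1,218 samples).

## The reference classifier

The committee contract demands only `fit(data, config)` and
`predict_proba(data)` with reproducibility given a seed. The packaged
reference member is a multinomial logistic model over flattened,
channel-concatenated pixels, trained by mini-batch SGD with momentum and
L2 penalty exactly as configured. Member m of a committee receives seed
`config$seed + m − 1`, so members differ in initialization and shuffling
as well as learning rate but remain individually reproducible; passing
`vary_seeds = FALSE` makes equal-rate members bitwise identical, which
collapses every downstream `kl_sum` to zero (a cross-module consistency
check in the test suite). When a validation set is supplied to `fit()`,
the parameters from the epoch with the highest validation AUC are kept
(checkpoint selection); otherwise training runs to `max_epochs`. A deep
CNN fine-tuned from pretrained weights can be dropped in through the same
contract; nothing in the scoring or selection layers assumes linearity.

## The slice pipeline

Volumetric records hold four co-registered modalities (T1, T1C, T2,
FLAIR) and a voxel-wise segmentation with labels {0, 1, 2, 4}; any
non-zero voxel counts as tumor. Axial planes are the third array axis,
indexed 0-based in manifests. Per patient, `k` tumor-bearing planes are
sampled without replacement; each slice stacks the T1, T1C and T2
channels (FLAIR is carried in the container but never emitted — the
three-channel choice is a config option with this triple as default),
min–max normalizes each channel to [0, 1] and resizes it bilinearly
(240 → 224 in the canonical geometry). Min–max normalization is the
least parametric standardization that makes extraction invariant to
per-channel intensity scaling; bilinear interpolation is the common
default for resizing into classifier input sizes. Patients with fewer
than `k` tumor planes are an error in strict mode and a warning (all
available planes taken) in permissive mode.

Splits are assigned at patient level to prevent leakage of a patient's
slices across cohorts. Per-split class counts follow largest-remainder
apportionment of each class across the splits, which reproduces the
canonical 203/66/66 patient split of a 259 HGG + 76 LGG cohort as
157+46 / 51+15 / 51+15. Selection, by contrast, operates at slice level:
the ranked list is slice-level and no patient-level constraint is imposed
on the selected subset.

## What the synthetic generators emulate — and what they do not

**Phantom cohorts** stand in for preprocessed volumetric scans: Gaussian
background intensity per modality, an ellipsoidal lesion with nested
shells labeled 1 (necrotic core), 4 (enhancing tumor) and 2 (edema), a
grade-dependent lesion intensity shift (HGG lesions brighter, with extra
post-contrast enhancement of the enhancing shell in T1C), and a lesion
guaranteed to span at least `min_tumor_planes` axial planes. They exercise
every pipeline contract — shape checks, label sets, tumor-plane detection,
count identities, splits — but are not anatomically realistic: no bias
fields, no partial-volume effects, no skull, no registration error.

**Planted-structure slice tasks** emulate the informativeness structure of
a training pool. A unit-norm direction u separates the two class means by
`class_sep` (so `class_sep` is the d′ of the underlying problem; 0 gives
chance-level held-out accuracy, 5 gives near-perfect). Three
subpopulations are planted: *normal* samples (class mean + unit noise),
*duplicates* (near-copies of the class prototype, sd 0.05 noise —
maximally typical, redundant), and *outliers* (0.25× class signal drowned
in sd-3 noise, with flipped labels — misleading). All planted structure is
confined to the training split; validation and test stay clean so
held-out AUC measures generalization. Defaults are n = 400 samples,
16×16×3 images, `class_sep` 4, 10% outliers, 10% duplicates, 70/15/15
splits.

An earlier iteration of the duplicate mechanism added a large random
per-class offset to the duplicate prototype; that offset itself became a
direction of committee disagreement and inverted the intended ordering.
The lesson is recorded here deliberately: with linear members, *any*
high-variance direction shared by a subpopulation can attract divergence.
The final mechanism keeps duplicates on the class prototype itself.

Consequences for interpretation: passing tests on these tasks show that
the scoring concentrates committee disagreement on label-noise outliers
and that budgeted selection from the trimmed ranking matches or beats
random sampling *under this generative model*. They do not show that the
same margins appear on real MRI, where outliers are rarer and less
separable from hard informative cases, and where deep-feature committees
behave differently from linear ones.

## Evaluation conventions

AUC is computed by the Mann–Whitney midrank formulation (ties credited
0.5), verified in tests against brute-force pair enumeration and pROC.
Repeated experiments report the mean of n runs (run r uses seed
`base_seed + r − 1`) with a symmetric 95% interval
`mean ± 1.96 · sd/√n` — the normal approximation, which is the common
reporting convention at n = 10; a Student-t interval is available via
`ci_method = "t"` since the two cannot be distinguished from published
interval endpoints alone. Evaluation is slice-level: scores and labels
per slice, no patient-level aggregation.

The two sweep harnesses mirror the standard experiment designs:
`range_sweep` trains on equal-width windows of the ranking (constant
sample count) to locate where training value lives, and `size_sweep`
compares uncertainty sampling (budget from the trimmed ranking) against
random sampling (budget from the full pool) at budgets 10%–80% in 10%
steps, both arms at identical cardinality per budget, plus a full-pool
baseline.

## Problem sizes used by the test suite

The suite and acceptance script run entirely on synthetic data at sizes
chosen to make the statistics stable on a single CPU: count identities on
a full 335-patient phantom cohort at 12×12×34 voxels (the balanced build
extracts 30 slices per LGG patient, so phantoms guarantee 30 tumor
planes); planted-structure recovery at n = 400 over 10 seeds; and the
uncertainty-vs-random sweep on an 800-sample pool aggregated over 24
sweep seeds with 3 runs per point. The sweep aggregation size was set
from variance estimates of the per-seed arm difference (seed-level sd up
to 0.035 at the 10% budget against mean gains of +0.003 to +0.03): at
these sizes the per-fraction aggregate reliably reflects the underlying
ordering rather than selection noise.

## Known limitations

* Single-round selection only: no iterative re-training/re-scoring loops,
  and no batch-diversity constraints within the selected subset.
* The score has no density or representativeness term beyond what extreme
  exclusion provides; a cluster of identical outliers would all rank high
  together.
* Committee members differ only by learning rate (and seed); richer
  committees (architectures, bootstraps) satisfy the same contract but
  are not generated by `build_committee`.
* The annotation-cost bounds treat the seed fraction as sunk cost; if the
  seed were chosen by the method itself the accounting would differ.
* Serialization targets small, plain-text containers (CSV/TSV/JSON,
  NIfTI for volumes); very large slice datasets would need a binary
  container instead.
```{r session}
sessionInfo()
```
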