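# qbcselect

Query-by-committee active learning for MRI slice classification.

## The problem

Training a slice-level classifier to grade gliomas (high-grade, HGG, vs.
low-grade, LGG) from multi-modality brain MRI needs thousands of labeled 2D
slices, and expert annotation is the bottleneck. `qbcselect` implements an
annotation-efficient alternative: label only a small seed of the training
pool, let a *committee* of classifiers trained on that seed score every
remaining sample by how much the committee is uncertain and disagrees about
it, and then spend the labeling budget only on the informative middle of
the ranked list. The package is aimed at medical-imaging researchers who
want the selection machinery independent of any particular network: any
model exposing `fit()` / `predict_proba()` can sit on the committee, and a
seeded SGD multinomial logistic reference classifier is included so the
whole pipeline runs at desk scale.

## The statistic at the core

Each committee member m outputs a class distribution p_m for a sample. The
sample's informativeness score is

    score = Σ_m H(p_m)  +  Σ_{m ≠ m'} D(p_m ‖ p_m')

where H(p) = −Σ_i p_i log p_i is the predictive entropy and
D(p‖q) = Σ_i p_i log(p_i/q_i) is the Kullback–Leibler divergence, summed
over all ordered member pairs (both directions of every pair, realizing the
symmetric divergence). Scores are in nats; the ranking is invariant to the
log base. Samples are sorted by descending score; the top decile (likely
outliers) and bottom decile (uninformative, near-duplicate samples) are
discarded, and a budget of 30% of the full pool is sampled uniformly from
the remainder. With a 30% labeled seed and a 30% budget, between 40% and
70% of the annotation cost is saved (mean 55%), depending on how much the
two subsets overlap.

Around the scoring core the package provides: committee construction by
varying the learning rate (0.001 / 0.0005 / 0.0001 by default), the
volumetric-to-slice pipeline (tumor-plane detection from `{0,1,2,4}`
segmentation maps, T1/T1C/T2 channel stacking, min–max normalization,
bilinear resizing, patient-level stratified splits), annotation-cost
accounting, ROC-AUC evaluation over repeated seeded runs, range and
sample-size sweep harnesses, and synthetic generators (phantom volumetric
cohorts and planted-structure slice tasks) that make everything testable
without any external dataset.

## Worked example

Score a 400-sample planted-structure task, select 30%, and compare the
selected subset against training on the full pool:

```r
library(qbcselect)

task  <- make_slice_task(slice_task_spec(n = 400, seed = 42))
train <- subset_dataset(task, split = "train")

seed_ids  <- random_baseline(dataset_manifest(train)$sample_id, 0.30, seed = 42)
committee <- build_committee(subset_dataset(train, ids = seed_ids),
                             config = training_config(seed = 42))
ranked <- score_dataset(predict_profiles(committee, train))
head(as.data.frame(ranked), 3)
#>   sample_id entropy_sum   kl_sum    score rank
#> 1     s0046   0.9326613 5.164465 6.097126    1
#> 2     s0035   1.3180751 4.329066 5.647141    2
#> 3     s0238   1.0859338 3.943179 5.029113    3

plan <- selection_plan(exclude_top = 0.10, exclude_bottom = 0.10,
                       budget = 0.30, seed = 42)
selected <- apply_selection_plan(ranked, plan)
annotation_cost(0.30, 0.30, initially_labeled_ids = seed_ids,
                selected_ids = selected, pool_size = nrow(ranked))
#> <cost_report> seed-labeled 30%, budget 30% of pool
#>   labeling needed: 30% - 60% of the pool
#>   annotation saving: 40% - 70% (mean 55%)
#>   realized: 47.9% needed (52.1% saved)

run_experiment(selected, task, config = training_config(seed = 42),
               n_runs = 10, base_seed = 7)
#> AUC 0.9707 (95% CI 0.9631 - 0.9783, n = 10)
run_experiment(dataset_manifest(train)$sample_id, task,
               config = training_config(seed = 42), n_runs = 10, base_seed = 7)
#> AUC 0.9821 (95% CI 0.9775 - 0.9868, n = 10)
```

The top-ranked samples are dominated by `kl_sum` — the committee actively
disagrees about them (these are the planted outliers). Training on the
selected 30% reaches a mean test AUC of 0.971 against 0.982 for the full
pool, while cutting the realized annotation need to 47.9% of the pool.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/qbcselect` (`simulate`, `slices`, `committee`, `score`, `select`,
`evaluate`, `sweep`), each stage reading the previous stage's plain-text
outputs.

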