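# shapdyn

Temporal feature-attribution dynamics for pre-death patient states.

## What this package is for

Routine laboratory panels trace a dying patient's internal state over the
final months of life, but irregular sampling and large between-patient
variation make those dynamics hard to see directly. `shapdyn` is for
researchers studying decedent cohorts who want to (a) quantify *when* each
laboratory parameter starts mattering for mortality, and (b) stratify
patients by the *pattern* of parameters driving their terminal course —
rather than by raw laboratory values, which mix outcome-relevant signal
with inert inter-individual variation.

The core construction: put all patients on a days-before-death axis
(death = day 0), resample each patient's events with a 5-day moving
average, and train one gradient-boosted tree classifier per horizon
*n* ∈ {1, …, 90} that separates the state *n* days before death
(positive) from the same cohort's state 168 days before death (negative)
— a self-referenced, exactly 1:1-balanced design. Each model is explained
with exact per-feature Shapley attributions φᵢⱼ in log-odds space
(base + Σⱼ φᵢⱼ = margin, enforced to 1e-6 per row; computed in double
precision by a C++ TreeSHAP engine in `src/`). For correctly predicted
positives, feature *j* at horizon *n* is summarized by its max-scaled
mean attribution

&nbsp;&nbsp;&nbsp;&nbsp;sⱼ(n) = mⱼ(n) / maxₖ |mₖ(n)|,&nbsp;&nbsp; mⱼ(n) = meanᵢ φᵢⱼ(n),

whose trajectory over horizons shows each parameter's importance rising,
falling, or switching on late. Day-1 attribution vectors then drive
hierarchical patient stratification (Ward linkage, Euclidean distance,
silhouette-selected k with the elbow curve reported), with a standardized
raw-value clustering arm for comparison, and 2-D embeddings (UMAP, t-SNE,
PCA) of time-stacked states in both spaces.

Because no real cohort ships with the package, a synthetic
decedent-cohort generator (`cohort_spec()`, `terminal_drift_params()`,
`generate_cohort()`) plants latent subtypes with known drift drivers —
including a late-onset driver and two-sided derangement features — and
returns the ground truth, so every claim the package makes is testable.
See the vignette (`vignettes/patient-state-dynamics.Rmd`) for the model,
the generator's assumptions, and design rationale.

## A worked example

```r
library(shapdyn)

cohort <- generate_cohort(cohort_spec(n_patients = 300, seed = 1),
                          missing_rates = terminal_drift_missing_rates())
states <- resample_cohort(cohort$events, window_days = 5, max_day = 168)
family <- train_model_family(states, horizons = c(1, 15, 30, 45, 60, 75, 90),
                             folds = 5, seed = 1)
family$metrics
#>   horizon n_patients n_rows mean_auroc   sd_auroc
#> 1       1        291    582  0.9780703 0.01253782
#> 2      15        282    564  0.9383124 0.01578146
#> 3      30        278    556  0.8298682 0.01294317
#> 4      45        279    558  0.6828902 0.03757435
#> 5      60        275    550  0.5854545 0.02857832
#> 6      75        281    562  0.5991302 0.02311442
#> 7      90        277    554  0.5346590 0.02201367
```

Patient-level 5-fold cross-validated AUROC decays from 0.978 one day
before death towards chance at 90 days: the planted drift signal fades
with distance from death, as it should.

```r
panels <- lapply(names(family$models), function(h)
  attribute_panel(family$models[[h]], family$datasets[[h]], family$splits[[h]]))
behaviors <- behavior_matrix(lapply(panels, select_correct_positives))
rank_and_proportions(behaviors, horizon = 1, k = 5)$top
#>   rank feature scaled_mean
#> 1    1     bun   1.0000000
#> 2    2      mg   0.4124253
#> 3    3      ua   0.3851146
#> 4    4       k   0.3782655
#> 5    5     pho   0.3763214
```

One day before death, the late-onset driver (BUN, flat until 30 days out
by construction) tops the ranking with scaled mean attribution 1.0; at
horizon 60 it ranks near the bottom — the importance-switches-on-late
pattern the behavior matrix is designed to expose.

```r
day1 <- select_correct_positives(
  attribute_panel(family$models[["1"]], family$datasets[["1"]], use = "all"))
subtypes <- cluster_and_select_k(day1, k_range = 2:8)
table(subtypes$labels)
#>  1  2  3
#> 98 98 86
mclust::adjustedRandIndex(
  subtypes$labels,
  cohort$truth$subtype[match(names(subtypes$labels), cohort$truth$patient_id)])
#> [1] 0.717
```

Silhouette selection picks k = 3 and the attribution-space clusters
recover the three planted subtypes (ARI 0.72 at this small cohort size;
~0.9 at the reference size of 500). The same clustering on standardized
raw day-1 values stays near ARI 0.2 — the package's headline contrast.

`run_pipeline(pipeline_config(...), "out/")` runs all stages as one
reproducible unit, writing CSV artifacts and a JSON manifest with config
hash and artifact checksums.

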