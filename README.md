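# eosclust

Automated, data-driven phenotype clustering for **early onset scoliosis
(EOS)** — progressive spinal deformity with onset before age 10. Consensus
classification assigns EOS patients to subgroups by preset Cobb-angle and
kyphosis bands; `eosclust` instead stratifies each etiology (congenital,
idiopathic, neuromuscular, syndromic) by **fuzzy C-means clustering** of six
pre-operative clinical indices:

age (years), major curve Cobb angle (°), kyphosis (°), vertebral levels in
the major curve, levels in kyphosis, and the **deformity index** — the ratio
Cobb/kyphosis (> 1 means the coronal deformity dominates the sagittal one).

The package is aimed at spine-deformity researchers who want reproducible,
membership-based subgrouping of registry-style patient tables, plus a
simulator for method validation when registry data are unavailable.

## The method

Indices are z-scored, then fuzzy C-means (fuzzifier *m* = 2, Euclidean
distance) minimizes

```
J_m(U, V) = Σᵢ Σⱼ uᵢⱼᵐ ‖xᵢ − vⱼ‖²,   Σⱼ uᵢⱼ = 1,
```

by alternating the membership update `uᵢⱼ = 1 / Σₗ (dᵢⱼ/dᵢₗ)^(2/(m−1))` and
the weighted-mean centroid update, from 10 seeded random starts. Per
etiology:

1. **Cluster count** — models are fitted for k = 2…6 and the k maximizing
   the *average membership* (mean over subjects of their maximum
   membership) is selected; ties go to the smaller k.
2. **Outliers** — subjects whose maximum membership is strictly below 0.6
   are flagged and excluded from summaries (the model is not refitted).
3. **Canonical labels** — clusters are renumbered in ascending order of
   mean raw Cobb angle, so cluster 1 is always the mildest coronal
   deformity.
4. **Statistics** — one-way ANOVA per index across clusters, Tukey HSD for
   all pairwise contrasts (reporting α = 0.01).
5. **Scoring** — new patients are assigned by evaluating memberships
   against the frozen centroids, never by refitting.

Because no public EOS registry exists, the package ships a seeded
truncated-Gaussian mixture generator (`generate_cohort()`,
`default_cohort_specs()`) that produces four synthetic etiology cohorts
with three well-separated components each, plus injected uniform-range
outliers and ground-truth labels for recovery tests.

## Worked example

```r
library(eosclust)

specs   <- default_cohort_specs(n_subjects = 250, outlier_fraction = 0.05,
                                seed = 2023)
records <- do.call(rbind, lapply(specs, generate_cohort))   # 1000 patients
analysis <- run_act(records, act_config(seed = 2023))
summary(analysis)
#>        etiology best_k avg_membership n_eligible n_outliers n_included
#> 1    congenital      3      0.8802217        250         14        236
#> 2    idiopathic      3      0.9267481        250          9        241
#> 3 neuromuscular      3      0.9269660        250         11        239
#> 4     syndromic      3      0.9186566        250         12        238
```

Three clusters per etiology maximize the average membership; 9–14 subjects
per cohort fall below the 0.6 membership floor and are set aside as
outliers. Per-etiology detail, in canonical ascending-Cobb order:

```r
r <- analysis$results$neuromuscular
r
#> neuromuscular: k = 3 clusters (avg membership 0.927)
#>   subjects: 250 eligible, 0 excluded (missing), 11 outliers (< 0.60), 239 included
#>   cluster sizes: 84, 84, 71

round(r$summary_table[, 1:8], 2)
#>   cluster  n age_mean age_sd cobb_major_mean cobb_major_sd kyphosis_mean kyphosis_sd
#> 1       1 84     2.00   0.51           38.22          4.69         67.80        5.02
#> 2       2 84     5.59   0.58           69.45          5.27         41.93        4.75
#> 3       3 71     8.93   0.72          107.73          5.41         62.45        5.46
```

Cluster 1 is the young, kyphosis-dominant phenotype (mean kyphosis 68°
against Cobb 38°, deformity index < 1); cluster 3 the oldest, most severe
coronal deformity. All six indices separate the clusters (every ANOVA
p < 10⁻⁹⁰ here; `r$anova`, `r$tukey` hold the full tables), and
`plot(r)` draws the kyphosis-versus-Cobb scatter colored by cluster with
outliers as grey crosses.

Scoring a new patient against the frozen model:

```r
new_patient <- data.frame(subject_id = "new-01", etiology = "neuromuscular",
                          age_years = 5.5, cobb_major_deg = 72,
                          kyphosis_deg = 41, levels_cobb = 8,
                          levels_kyphosis = 5)
score_patients(r$model, new_patient)
#>   subject_id cluster max_membership outlier membership_1 membership_2 membership_3
#> 1     new-01       2       0.996945   FALSE   0.00149102     0.996945   0.00156396
```

The patient lands in cluster 2 with 99.7% membership — a confident
assignment, not an outlier. `write_act_results(analysis, "results/")`
exports per-etiology JSON models, summary/statistics/scatter CSVs and the
resolved config; reruns are byte-identical. A thin command-line wrapper
(`inst/scripts/act-eos.R`) exposes `run`, `simulate` and `score`
subcommands over the same functions.

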