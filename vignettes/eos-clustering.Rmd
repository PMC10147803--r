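---
title: "Fuzzy C-means phenotype clustering for early onset scoliosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy C-means phenotype clustering for early onset scoliosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eosclust)
```

## The clinical problem

Early onset scoliosis (EOS) is a progressive spinal deformity with onset
before age 10, spanning four etiologies — congenital, idiopathic,
neuromuscular, and syndromic — with very heterogeneous presentations.
Consensus classification groups patients by preset cut-offs on Cobb angle
and kyphosis bands, which yields many sparsely populated subgroups and no
data-driven basis for the band boundaries. `eosclust` implements an
automated alternative: within each etiology, patients are soft-clustered on
six pre-operative clinical indices, the number of clusters is chosen by a
membership criterion, and low-confidence patients are set aside as outliers
rather than forced into a subgroup.

The six indices, in the fixed column order used throughout the package, are:

| feature           | units   | meaning                                        |
|-------------------|---------|------------------------------------------------|
| `age`             | years   | age at presentation (EOS: under 10)            |
| `cobb_major`      | degrees | major curve (Cobb) angle, coronal plane        |
| `kyphosis`        | degrees | thoracic kyphosis, sagittal plane              |
| `levels_cobb`     | count   | vertebral levels in the major curve            |
| `levels_kyphosis` | count   | vertebral levels in kyphosis                   |
| `deformity_index` | ratio   | `cobb_major / kyphosis`; > 1 means the coronal deformity dominates |

The deformity index is always computed, never measured or simulated
directly. Kyphosis values below a configurable floor (default 1 degree,
covering hypokyphotic and lordotic patients recorded as zero or negative)
are floored in the denominator only; the raw kyphosis value is kept as a
feature, so the sagittal information is preserved while the ratio stays
finite and positive.

## The model

Fuzzy C-means (FCM) represents a partition of $n$ subjects into $k$
clusters by a row-stochastic membership matrix $U = (u_{ij})$ and centroids
$v_1, \dots, v_k$, minimizing the fuzzified within-cluster scatter

$$ J_m(U, V) = \sum_{i=1}^{n} \sum_{j=1}^{k} u_{ij}^m \, \lVert x_i - v_j \rVert^2, \qquad m > 1, $$

by alternating the two stationarity conditions

$$ u_{ij} = \Big( \sum_{l=1}^{k} (d_{ij}/d_{il})^{2/(m-1)} \Big)^{-1}, \qquad
   v_j = \frac{\sum_i u_{ij}^m x_i}{\sum_i u_{ij}^m}, $$

with Euclidean distance $d_{ij} = \lVert x_i - v_j \rVert$. Each half-step
can only decrease $J_m$, which the implementation asserts (the objective
trace is stored in every fit and tested to be non-increasing). A point at
numerically zero distance from one or more centroids takes membership split
equally across the coincident centroids and zero elsewhere; a cluster whose
total weight collapses is re-seated on the point with the worst current
maximum membership (both events are logged).

**Standardization.** The six indices mix years, degrees, counts and a
ratio. Euclidean distance on raw values would be dominated by the
degree-valued features (tens of degrees of spread) over age (years) and
level counts. Each column is therefore z-scored with the sample standard
deviation (divisor $n-1$) before clustering; the per-column center and
scale are stored in the fit so that centroids are reported in original
units and new patients are mapped into the same space when scored.
Constant columns map to zero with the scale recorded as 1 (and a warning).
Standardizing an already standardized matrix is a no-op.

**Both kyphosis and the deformity index enter the feature set** although
they are functionally related; the six-index list is the method's contract,
and the ratio carries the coronal-versus-sagittal contrast that neither
angle carries alone.

## Choosing the number of clusters

For each candidate $k$ (default 2–6) the model is fitted with an identical
seed and configuration, and scored by the **average membership**: the mean
over subjects of their maximum membership. A crisp partition scores 1; a
totally uninformative one scores $1/k$. The $k$ with the highest score
wins; ties break to the smaller $k$ (parsimony). The per-subject maximum is
the only per-subject scalar that works both as a confidence measure here
and as the outlier score below, which is why the package aggregates row
maxima rather than, say, per-cluster means.

Two properties of this criterion are worth knowing. First, on structureless
data (a single Gaussian cloud) all centroids collapse to the grand mean and
every score lands exactly at the uniform baseline $1/k$, so the criterion
degrades gracefully: `select_k()` picks $k = 2$ and emits a
"weak cluster structure" message whenever the best score is within 0.1 of
$1/\hat{k}$. $k = 1$ is deliberately not a candidate; the message is the
structureless-data signal. Second, with $m = 2$ in six dimensions the
criterion rewards the true component count only when components are well
separated relative to their within-component spread; moderately overlapping
components are absorbed into fewer, broader clusters. The synthetic
defaults below are designed on the separated side of that trade-off.

## Outliers and canonical labels

A subject whose maximum membership is **strictly below 0.6** does not
belong convincingly to any cluster and is flagged as an outlier (a subject
at exactly 0.6 is retained). Flagged subjects are excluded from summary
tables and statistics, but by default the model is **not refitted** without
them: assignments are frozen at fit time, which keeps the procedure
deterministic and keeps every non-outlier's label independent of the
exclusion step. A config switch (`refit_after_exclusion`) refits the
winning $k$ on the retained subjects for users who prefer the alternative
reading; the outlier flags themselves are never revised by the refit.
Raising the floor can only flag more subjects — the rule is monotone, and
tested as such.

After fitting, cluster labels are relabeled so that **cluster 1 has the
lowest mean raw Cobb angle and cluster $k$ the highest**, computed over
non-outlier members (argmax assignment); centroid rows and membership
columns are permuted consistently. The convention makes tables and scatter
plots comparable across etiologies: label 1 is always the mildest coronal
deformity. Exact ties keep the lower original index first and are logged.
Relabeling is idempotent.

## Statistical comparison

Within each etiology, every index is compared across the fitted clusters
with a one-way ANOVA, and all pairwise cluster contrasts with Tukey's HSD
(studentized-range adjustment; Tukey–Kramer harmonic form for unequal
cluster sizes), both via the standard `stats` machinery (`lm`/`anova`,
`TukeyHSD`). The reporting significance level defaults to 0.01 and is
configurable. Outlier-flagged subjects are excluded from all statistics,
matching their exclusion from cluster membership. Degenerate inputs are
handled explicitly: a cluster with fewer than two retained members is an
error naming the cluster, and zero within-group variance with differing
means reports $p = 0$ with a warning rather than `NaN`.

No correction is applied across the six indices; Tukey's adjustment acts
within an index, across pairs.

## The synthetic cohort generator

Registry EOS data are not publicly available, so the package ships a
generator that emulates the *statistical structure* the analysis assumes: a
per-etiology finite Gaussian mixture over the five measured indices, with
valid-range truncation (age clipped to 0.25–10 years, angles to 10–150
degrees, level counts rounded to integers in 1–17) and a configurable
fraction of injected outliers drawn uniformly over those full ranges. The
deformity index is computed from the sampled angles, exactly as for real
data. Components use diagonal covariance by default because per-cluster
index correlations are not something the summary-level literature
constrains; a full-covariance hook exists for stress tests. Level counts
are rounded truncated normals (not Poisson), keeping their spread
interpretable and bounded.

The shipped default specs (`inst/extdata/default_cohort_specs.json`, a
versioned config file rather than code) give each etiology three components
ordered by ascending mean Cobb angle, 250 subjects and 5% injected outliers
per cohort. Their qualitative pattern mirrors what is clinically expected
of the four etiologies: neuromuscular and syndromic cohorts each contain
exactly one kyphosis-dominant component (mean kyphosis above mean Cobb,
expected deformity index below 1), while every congenital and idiopathic
component keeps Cobb at or above kyphosis — including an idiopathic
severe-kyphotic component whose deformity index still exceeds 1. The
magnitudes are plausible synthetic design points chosen within clinical
ranges (age 0.5–10 years, Cobb 15–140°, kyphosis 5–120°, levels 3–14), not
estimates of any real cohort.

Two design notes on the default geometry. The components are deliberately
**well separated** (within-component SDs of 0.5 years, 4–5 degrees, 0.8
levels against between-component mean gaps of several within-SDs in every
feature): the membership criterion only recovers the generative component
count in that regime, and the defaults are the package's reference
conditions for its own recovery and outlier-recall tests. Two features
limit how sharp the separation can be made: the deformity index inherits
ratio noise (large when kyphosis is small), and level counts carry
irreducible rounding noise. What passing tests on these cohorts shows is
that the pipeline recovers planted, well-separated structure and flags
range-uniform outliers; it does **not** show that real registry cohorts
contain three well-separated clusters per etiology, that real measurement
error behaves like diagonal Gaussian noise, or that real outliers are
range-uniform.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | fuzzifier; 2 gives inverse-square-distance memberships, larger is fuzzier |
| `k_range` | 2–6 | candidate cluster counts (6 caps well above the expected optimum of 3) |
| `n_starts` | 10 | random restarts per fit; best final objective wins |
| `tol` | 1e-6 | convergence on the largest membership change |
| `max_iter` | 300 | iteration cap per start |
| `membership_floor` | 0.6 | strict outlier bound on the maximum membership |
| `alpha` | 0.01 | reporting significance for ANOVA/Tukey |
| `deformity_floor` | 1 degree | kyphosis floor in the deformity-index denominator |
| `seed` | — | drives all randomness; identical (input, config) reruns are byte-identical |

Initialization draws each start's membership matrix from a symmetric
Dirichlet(1) (row-normalized exponentials), seeded; `fcm()` also accepts
explicit initial centroids, which is how the near-crisp limit ($m = 1.05$)
is checked against a plain Lloyd k-means oracle in the tests.

## A worked run

```{r}
specs <- default_cohort_specs(n_subjects = 250, outlier_fraction = 0.05,
                              seed = 2023)
records <- do.call(rbind, lapply(specs, generate_cohort))
analysis <- run_act(records, act_config(seed = 2023))
summary(analysis)
```

```{r}
r <- analysis$results$neuromuscular
print(r)
round(r$summary_table[, 1:8], 2)
```

```{r, fig.width = 6, fig.height = 5}
plot(r)
```

Scoring a new patient against the frozen neuromuscular model (what a
clinician-facing front end would do per patient):

```{r}
new_patient <- data.frame(subject_id = "new-01", etiology = "neuromuscular",
                          age_years = 5.5, cobb_major_deg = 72,
                          kyphosis_deg = 41, levels_cobb = 8,
                          levels_kyphosis = 5)
score_patients(r$model, new_patient)
```

## Problem sizes and runtime

The reference analyses in the tests and the acceptance script use four
etiologies at $n = 250$ (selection over $k = 2..6$, 10 starts each),
50-replicate recovery and outlier-recall studies, and a 2000-replicate null
calibration of the ANOVA type-I error. The full suite runs in a few minutes
on a single CPU; individual fits take milliseconds, so cohorts one or two
orders of magnitude larger are practical.

## Known limitations

- The average-membership criterion never proposes $k = 1$; on structureless
  data it returns $k = 2$ at the $1/k$ baseline with a weak-structure
  message, and downstream summaries should not be over-read in that case.
- With $m = 2$, overlapping components merge: the criterion is a
  separation detector, not a density-model selector. If overlapping
  subgroups are expected, compare against an information-criterion-based
  mixture model.
- The deformity index is noisy for small kyphosis values; the 1-degree
  floor bounds it but hypokyphotic patients will show wide index spread.
- Outlier recall is quoted against range-uniform injected outliers;
  adversarially placed outliers near a centroid are undetectable by any
  membership rule.
- Per-index ANOVAs are descriptive of cluster separation, not a joint test;
  no across-index multiplicity correction is applied.
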