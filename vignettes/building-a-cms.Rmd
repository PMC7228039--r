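---
title: "Building composite measure schemes for severity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building composite measure schemes for severity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmskit)
```

## The problem

Grading the burden experienced by laboratory animals — for harm–benefit
analysis, model prioritization, or validating refinement measures — is
usually done with coarse, subjective scales. A composite measure scheme
(CMS) replaces this with a data-driven construction: from a battery of
behavioral and biochemical parameters measured across several disease
models and treatment groups, select the few parameters whose association
with the experimental condition is *stable under resampling*, combine them
into a single standardized score per animal, and partition that score into
ordinal severity levels with quantified uncertainty on the level
boundaries.

`cmskit` implements the full construction and the application of a frozen
scheme to new animals. The stages are:

1. **Filter** — drop parameters with more than 20% missing cells (strictly
   greater; exactly 20% survives), then drop user-declared exclusions.
2. **Preprocess** — Box-Cox-normalize, center and scale each retained
   parameter to mean 0, SD 1.
3. **Select** — run a PCA on 100 random 80% subsamples; per run, tally the
   four parameters with the largest absolute loadings on the
   group-separating component; keep the most frequent parameters.
4. **Score** — sum the selected, directionality-aligned z-values per
   animal. Low composite = higher severity.
5. **Cluster** — run k-means (k = 3) on 100 random 80% subsamples of the
   scores, convert each run's cluster boundaries to thresholds, and
   aggregate them into mean thresholds with 95% percentile confidence
   borders; assign each animal a severity level from the thresholds.

## Worked example on the synthetic tutorial battery

No public dataset accompanies the scheme, so the package ships a
generator that emulates the statistical structure the pipeline assumes
(see "What the generator does and does not emulate" below).

```{r pipeline, eval = FALSE}
dir <- tempfile()
paths <- simulate_reference_fixture(dir, seed = 1)
res <- run_pipeline(paths$battery, paths$spec, file.path(dir, "out"),
                    seed = 1, n_runs = 100)
print(res$selection)
print(res$severity$thresholds)
```

The bundle written to `out/` contains every intermediate artifact
(filtered table, preprocessing manifest, selection report, scores, severity
report, per-group level distributions) plus a manifest with MD5 digests, so
a run can be replayed and verified.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `max_missing_fraction` | 0.20 | A parameter is removed iff its missing fraction is *strictly greater*. Computed over the pooled table, not per model, because the scheme is built on combined data. |
| `boxcox` | on | Profile-likelihood Box-Cox per parameter before scaling; behavioral read-outs are often right-skewed. Turn off to reproduce a plain z-score pipeline. |
| `train_fraction` | 0.80 | Standard resampling fraction; the 20% complement exists to probe sampling variability, not for supervised validation. |
| `n_runs` | 100 | Resampling runs for both selection and clustering. |
| `top_k` | 4 | Parameters tallied per PCA run. |
| `n_selected` | 4 | Size of the final parameter set. |
| `component` | `"auto"` | Group-separating component: the one (among the first three) maximizing the one-way between-group F of its scores. A fixed index reproduces a manual choice. |
| `k` | 3 | Severity levels; three suffice for a meaningful severity scale, more elaborate gradings use larger k. |
| `n_init` | 10 | k-means++ restarts per clustering run. |

Directionality is declared per parameter in the spec file: `+1` means a
low raw value indicates higher severity (burrowing, social interaction,
saccharin preference…), `-1` the reverse (immobility time, stress
hormones…). The composite negates `-1` parameters so that a low composite
always means higher severity.

## Design choices where the method is genuinely open

**Preprocessing order.** Box-Cox is applied to the raw (offset-shifted)
values *first*, then centering/scaling. Applying a power transform after
standardization would be undefined for the negative half of every column;
transform-then-standardize achieves the same intent (normalize, then put
parameters on a common dimensionless scale) and is well defined. Columns
with non-positive values receive an offset of `1 - min` before the
transform. The fitted λ, offset, mean and SD per parameter are stored in
the preprocessing manifest so any score is reproducible bit-for-bit on new
animals.

**Missing cells in retained parameters.** Cells still missing after the
20% filter are imputed with the column mean *on the scaled scale* (i.e.
0). This is neutral both under the composite summation and under the PCA
covariance; imputed cells are recorded in a mask, excluded from the
`n_contributing` count, and an animal missing more than half of the
selected parameters is flagged `unreliable` rather than dropped.

**Ranking parameters within a PCA run.** Parameters are ranked by
*absolute loading* on the chosen component — the only per-parameter
quantity a PCA offers; eigenvalues are per-component. Loading signs are
pinned by the convention that each component's largest-magnitude loading
is positive, which removes eigen-solver sign ambiguity and makes run
records comparable.

**Choosing the component.** The first component frequently tracks overall
disease phenotype (e.g. open-field locomotion in epileptic animals with
high seizure frequency) rather than burden, so severity selection should
not default to it. In `auto` mode the component with the largest
between-group F statistic among the first three is used, and all audited
F statistics are kept in the run record; a run whose best F is below the
0.05 critical value is flagged as ambiguous. The tally uses the single
chosen component per run; a joint PC1+PC2 tally was considered and
rejected as the default because it mixes phenotype-driven and
burden-driven loadings.

**Selection ties.** Ties in frequency at the selection boundary break by
higher mean absolute loading across runs, then input column order —
deterministic and auditable.

**Threshold definition.** The per-run threshold between adjacent clusters
is the midpoint of the two scores flanking the boundary (the "outer
values"): symmetric, scale-free, and it reduces to a single number per
boundary. Aggregation across runs uses the mean and distribution-free
percentile (2.5th/97.5th, linear interpolation) confidence borders rather
than a normal approximation.

**Training-only clustering.** Each clustering run fits k-means on the 80%
training scores only and assigns *all* animals through that run's
thresholds, so every animal has a membership in every run and per-group
distributions have a run-to-run SD. A `use_full_data` flag fits the full
population each run instead.

**Boundary convention.** A score exactly on a threshold is assigned to the
less severe side — conservative against over-reporting severity. Severity
level k is the cluster with the lowest centroid (lowest composite =
worst), so levels read 1 = best to k = worst.

## Numerical choices

- SDs use the n−1 denominator throughout.
- The Box-Cox λ is fitted by a coarse grid scan on [−5, 5] followed by
  `optimize()` refinement to 1e-4; transforms that collapse a column to
  numerically constant values are barred from winning the scan.
- `kmeans_1d` runs k-means++/Lloyd with `n_init` restarts, then certifies
  the result against the exact dynamic-programming optimum over contiguous
  partitions of the sorted scores (for 1-D data the optimal k-means
  partition is contiguous). The DP guarantees the global within-cluster
  sum-of-squares optimum even on the rare restart sets that all stall in a
  local optimum; with k = 3 this costs microseconds at typical n.
- A single master seed fans out to independent per-stage, per-run streams
  (hash of stage name and run index), so adding runs to one stage never
  perturbs another, and identical inputs, configuration and seed reproduce
  every artifact byte-for-byte.

## What the generator does and does not emulate

`simulate_battery()` draws per-animal latent multivariate normals under a
Gaussian copula (target Spearman structure converted through
`2 sin(πρ/6)`), applies standardized group shifts (Cohen's d, signed by
each parameter's severity direction) to the informative parameters, maps
to raw units through marginal means/SDs, and injects missingness
completely at random. The default battery has 13 parameters across 3
models × 3 groups (~200 animals), 4 informative parameters at d = 1.5,
Spearman 0.5 between the burrowing- and social-interaction-like
parameters and −0.65 between the two locomotion-like parameters — settings
chosen to resemble a realistic rodent battery, clearly simulation
parameters rather than reproductions of any study.

It does **not** emulate: informative missingness (dropout correlated with
severity), batch or subproject effects, heavy-tailed or discrete
marginals, ceiling/floor effects (e.g. preference percentages truncated at
100), or session-to-session correlation of repeated tests. Passing the
planted-truth tests therefore demonstrates that the machinery recovers
known structure under the model's assumptions — not that any particular
real battery satisfies those assumptions.

## Validation problem sizes

The test suite validates each stage against independent oracles at sizes
chosen for fast, deterministic runs: the exhaustive contiguous-partition
oracle at n ≤ 12 and k ∈ {2,3,4} (hundreds of random cases), λ-recovery on
log-normal samples of n = 500, planted-parameter recovery on the ~200
animal battery with 100 PCA runs, and planted-stratum recovery on 3 × 60
scores with 100 clustering runs. Worth noting: with strata at means −4, 0,
+2 and SD 0.8, the Bayes-optimal boundaries (the midpoints) give a maximum
expected assignment agreement of about 92.5%; no threshold rule on the
composite can exceed that ceiling, and the observed agreement of the
clustering stage sits just below it, exactly as theory predicts.

## Limitations

- Severity levels are *relative*, data-driven grades for comparing models,
  groups and interventions. They cannot be directly translated to the
  severity categories of EU Directive 2010/63 without further processing
  and considerations.
- The scheme assumes the selected parameters share a monotone relation
  with burden, encoded by the declared directionality; the tool makes no
  domain judgement about which parameters are suitable (e.g. disease
  phenotype measures must be excluded by the user).
- Equal weights in the composite are a deliberate simplicity choice; a
  loading-weighted variant exists behind `weights=` in `build_composite()`
  for exploration only.
- With overlapping severity distributions, k-means boundaries converge to
  the within-cluster-SS optimum, which is slightly offset from the Bayes
  midpoint between strata; the bootstrap CI quantifies sampling noise
  around the former, not the latter.
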