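# persinet

Single-subject gray-matter **similarity networks** by reference-group
perturbation, with the full lifespan analysis stack around them.

## The problem

Structural covariance — the correlation of regional gray matter volumes
across people — defines a brain network, but only at the group level: one
subject has one volume per region and no covariance of their own. The
perturbation approach recovers an individual network anyway:

1. Build a **reference network** `R_ref` from a young group (age < 30):
   partial Pearson correlations `r_ij` of regional volumes over reference
   subjects, controlling for total intracranial volume (ICV).
2. Add one subject to the reference group and recompute the partial
   correlations, giving the **perturbed network** `P`.
3. The subject's network is the z-scored difference,
   `Z = zscore(P − R_ref)` (off-diagonal entries; zero diagonal).

persinet implements this construction and everything the resulting
networks feed into, for three modalities (similarity, anatomical/
tractography, functional/correlation connectomes):

* preprocessing (diagonal zeroing, negative clipping, proportional density
  thresholding at 30% with 10%/50% robustness settings, rescaling to [0, 1]);
* the four global measures — Onnela weighted clustering `C`,
  characteristic path length `L`, global efficiency `E_glob`, Louvain
  modularity `Q`;
* lifespan trajectories via penalized cubic smoothing splines, with
  bootstrap confidence bands on the first derivative and detection of the
  **inflection age** at which age-related change begins;
* **age prediction** with an edge-attention graph neural network
  (edge MLP → node aggregation → node MLP → softmax edge attention →
  global embedding; MAE/Adam, 200 epochs, batch 64, lr 0.005), single- and
  multi-modality, plus an 8-16-16-8 MLP baseline on raw volumes, under
  repeated 10-fold cross-validation with 80/10/10 splits;
* linear **age-bias correction**
  `corrected = predicted + (Ω − (αΩ + β))` and phenotype-failure analysis
  (which subject characteristics correlate with corrected error);
* per-outcome **PLS regression** of cognition with CV-selected latent
  variables and Variable-Importance-in-Projection (VIP > 1) significance;
* **cytoarchitectonic** analyses over seven groups (five cortical types +
  insula + cingulate): intra-group efficiency on induced subgraphs,
  intra-group edge-count–age correlations, group volume trajectories.

A fully parameterized synthetic cohort generator (`synthetic_truth()`,
`simulate_cohort()`) plants known onsets (similarity 32 < anatomical 43 <
functional 62 years), network–cognition links and phenotype effects, so
every stage is tested by parameter recovery without access-controlled
imaging data.

## Worked example

```r
library(persinet)

truth  <- synthetic_truth(n_subjects = 150, n_regions = 40, seed = 42)
truth
#> Synthetic cohort truth (seed 42 )
#>   subjects: 150  regions: 40  communities: 6
#>   planted onsets (years): volume/similarity 32 | anatomical 43 | functional 62

cohort <- simulate_cohort(truth)
ref    <- build_reference(cohort$volumes, cutoff = 30)
ref
#> Young-reference similarity network
#>   regions: 40  reference subjects: 23  (age < 30 )

nets    <- batch_individual_networks(cohort$volumes, ref)
metrics <- cohort_metrics(nets, modality = "similarity", density = 0.30,
                          n_restarts = 5, seed = 1)
head(metrics, 3)
#> # A tibble: 3 × 7
#>   subject_id modality   density     C     L E_glob      Q
#>   <chr>      <chr>        <dbl> <dbl> <dbl>  <dbl>  <dbl>
#> 1 S0001      similarity     0.3 0.109  6.57  0.119 0.0128
#> 2 S0002      similarity     0.3 0.137  5.22  0.147 0.0182
#> 3 S0003      similarity     0.3 0.163  4.84  0.140 0.0772

infl <- inflection_age(nets$age, metrics$Q, B = 200, seed = 7,
                       metric = "Q", modality = "similarity")
infl[, c("inflection_age", "ci_low", "ci_high", "direction")]
#>   inflection_age       ci_low      ci_high direction
#> 1       32.51022 -0.006050692 -0.003016946        -1
```

The detected inflection age (32.5 years, derivative CI excluding zero,
declining) recovers the planted similarity onset of 32 years: modularity of
the perturbation networks starts dropping as soon as the planted atrophy
process begins. `modality_ordering()` runs the same detection for all
modalities and metrics; `autoplot()` methods visualize trajectories,
derivative bands, true-vs-predicted age, and VIP profiles; `tidy()` /
`glance()` return tibbles from every fitted object.

A command-line interface over the same functions ships in
`inst/cli/persinet.R` (subcommands `simulate`, `build-similarity`,
`preprocess`, `metrics`, `trajectories`, `train-age`, `predict-age`,
`bias-correct`, `pls-cognition`, `cytoarch`); every run writes a JSON
manifest with config, seed, versions and input hashes.

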