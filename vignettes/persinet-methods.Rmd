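---
title: "Perturbation-based individual similarity networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-based individual similarity networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Structural covariance networks — correlations of regional gray matter
volume computed **across** subjects — are group-level objects: a single
subject has one volume per region and therefore no correlation structure of
their own. persinet implements the perturbation strategy for recovering a
single-subject network: build a reference covariance network from a young
group, add one subject to that group, recompute, and treat the (z-scored)
difference as that subject's individual similarity network. Downstream, the
package analyses these networks alongside anatomical (tractography-derived)
and functional (correlation-derived) connectomes: weighted graph measures,
lifespan trajectories with onset detection, age prediction with an
edge-attention graph neural network, age-bias-corrected failure analysis,
PLS models of cognition with VIP scoring, and cytoarchitectonic intra-group
analyses.

# Individual network construction

The reference network is the matrix of partial Pearson correlations of
regional volumes over reference subjects (age strictly below the cutoff,
default 30 years), controlling for total intracranial volume (ICV).
Partial correlations are computed by residualization: each region's volumes
are regressed (with intercept) on ICV and the residuals correlated. The
closed-form identity
\((r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}\)
is used only as an independent test oracle.

For a non-reference subject, the perturbed matrix `P` is recomputed over
the `n_ref + 1` subjects — the subject's ICV joins the covariate vector —
and the difference `D = P - R_ref` is z-scored. Two points the method
leaves open were fixed as follows:

* **z-scoring is per subject**, over the off-diagonal upper-triangle
  entries of that subject's own `D` (sample sd, n−1 denominator). This is
  the only reading that keeps single-subject construction self-contained:
  cohort-level z-scoring would make a subject's network depend on who else
  was scanned.
* Reference subjects receive no individual network; a leave-one-out
  variant is deliberately out of scope.

Near-constant regions (zero residual variance) are a hard error, not a
silently regularized case.

# Preprocessing and graph measures

All connectivity matrices pass through one chain: zero the diagonal, set
negative weights to zero (correlation-valued and similarity matrices),
retain the largest `floor(density * n(n-1)/2)` upper-triangle weights, and
divide by the largest survivor so weights lie in [0, 1]. The default
density is 0.30, with 0.10 and 0.50 as the standard robustness settings.
Ties at the threshold are broken by (row, col) lexicographic order, which
makes thresholded edge sets deterministic and nested across densities.

Four global measures are computed per network:

* **Clustering coefficient C** — Onnela's geometric-mean-of-triangle-weights
  form, the convention of the standard brain-connectivity toolboxes; nodes
  of degree < 2 contribute zero.
* **Characteristic path length L** and **global efficiency E_glob** — edge
  length is the reciprocal weight (the method family's usual choice; the
  analysis does not prescribe one); `E_glob` averages inverse shortest-path
  distances over all ordered pairs with disconnected pairs contributing 0,
  `L` averages distances over reachable pairs only, with disconnection
  flagged.
* **Modularity Q** — Louvain at resolution 1 on the weights, 10 restarts
  with consecutive seeds, keeping the partition with maximal weighted
  Newman–Girvan modularity. Louvain is a heuristic: Q is
  permutation-invariant in practice only when the optimum is well
  separated, which the tests respect.

# Lifespan trajectories and onset detection

Metric-versus-age trajectories are modeled with penalized cubic smoothing
splines (`stats::smooth.spline`), evaluated with their analytic first
derivative on a half-year age grid. Smoothing is chosen by GCV but capped
at 8 equivalent degrees of freedom — unconstrained GCV occasionally returns
very wiggly fits whose derivative bands are useless for onset detection.
When several modalities are compared, one smoothing parameter per metric
(the median of the per-modality GCV choices) is frozen across modalities so
the degree of smoothing is constant across analyses; pooling raw values
across modalities before GCV would let between-modality offsets dominate.

Onset ("inflection age") detection is two-stage:

1. **Detection.** Subjects are resampled with replacement `B` times
   (default 1000), the spline refitted with the frozen smoothing, and the
   pointwise percentile 95% CI of the derivative formed on the grid. A
   change is declared only where the CI excludes zero for at least four
   consecutive grid points (two years) — single-grid-point excursions are
   ignored.
2. **Localization.** The reported onset is the breakpoint whose
   spline-smoothed unit-hinge derivative template best matches the fitted
   derivative, by least squares weighted inversely to the bootstrap
   variance at each grid age. The naive "earliest age at which the CI
   excludes zero" systematically anticipates an abrupt onset by most of a
   smoothing bandwidth (the spline smears the kink leftwards) and its
   crossing age carries high sampling variance; template matching removes
   the smearing bias exactly for hinge-shaped changes and pools the whole
   curve, which in simulations roughly halves the onset's sampling sd. The
   derivative CI is reported at the first significant grid age at or after
   the onset, so a reported onset always carries a CI that excludes zero.

The detection rule is the package's own: the underlying method literature
reports onset ages and derivative CIs without stating a rule, so persinet
documents one and tests it by parameter recovery (a planted breakpoint at
45 years, n = 600, noise sd equal to 30% of the total planted decline, is
recovered within ±3 years in ≥ 90% of seeds).

# The synthetic cohort

Every analysis is testable without access-controlled imaging data through
`synthetic_truth()` / `simulate_cohort()`. Defaults define the study
conditions and are not tuned per analysis:

* 632 subjects (the scale of the cohort the method family was developed
  on); ages uniform on 18–88 — uniform rather than an empirical age
  distribution so the spline support is even across the range; 60 regions
  at test scale (246 for full-scale emulation), partitioned into 6
  communities, the first 3 "affected" by aging.
* **Volumes.** Region baselines 5–15 (arbitrary units), an allometric ICV
  term `(icv / mean icv)^0.7`, community factors with loadings ≈ 1 and
  noise sd 0.6 giving within-community correlations ≈ 0.5–0.8, and a
  WMH-like vascular burden increasing with age. The gray-matter age effect
  is modeled as an age-increasing **prevalence of a fixed atrophy
  pattern**: after the volume onset (32 y) each subject expresses, with
  probability growing at 0.02/year, a 30% volume reduction in the affected
  communities. A deterministic per-year decline and a loading shrink are
  available as parameters but default to zero: one added subject perturbs
  the reference correlations quadratically in their own offset, so a
  deterministic ramp produces a population response whose apparent onset is
  late and whose direction on normalized network measures flips with the
  random reference draw; a growing prevalence of a fixed pattern gives the
  population mean a linear post-onset trend with a recoverable onset, and
  is a reasonable caricature of accumulating subclinical pathology.
* **Anatomical connectomes.** A modular template (within-community weights
  0.5–0.8, between 0.05–0.25) with within-affected-community weights
  declining 0.6%/year after 43 y, plus symmetric edge noise (sd 0.03),
  clipped at zero. The decline is restricted to affected communities
  because a globally uniform multiplicative decline cancels exactly under
  the max-rescaling preprocessing step.
* **Functional connectomes.** Region time series (length 200) = community
  signal + global signal scaled by a coupling that declines 1.5%/year
  after 62 y + noise; the output is the Pearson correlation matrix. In the
  noise-free, long-series limit the cross-community correlation is
  `kappa^2 / (1 + kappa^2)`, used as a closed-form oracle.
* **Cognition.** `score = 100 - 0.3 max(0, age - 40) + 12 Q + N(0, 0.6)`,
  with `Q` the subject's similarity-network modularity; the effect size was
  fixed once, at design time, so the implied partial correlation given age
  is ≈ 0.3 at the observed scale of `Q`. Pure-noise phenotypes are included
  as negative controls.

What the generator does **not** emulate: MRI physics, realistic FA values,
test–retest noise, heavy-tailed noise, or an empirical age distribution.
Passing tests therefore demonstrate that the implementation recovers what
was planted under this statistical caricature — not that the pipeline's
conclusions transfer to any particular real cohort.

Planted-onset ordering (32 < 43 < 62) is recovered end-to-end through the
**modularity** trajectories of the three modalities: an expressed atrophy
pattern concentrates a similarity network's strongest edges into one block
and reliably lowers Q in every seed, whereas the weighted global efficiency
of a z-scored, proportionally thresholded, max-rescaled network turned out
to respond to the same perturbation with a seed-dependent sign — the
normalization chain removes almost all magnitude information, leaving two
competing topological effects of similar size. Modularity is therefore the
readout used for the ordering recovery experiment (n = 450 subjects,
B = 120, Louvain restarts 3 — sizes chosen to keep the experiment's
runtime proportionate while leaving the recovery rate at ≥ 18/20 seeds).

# Age prediction

The edge-attention GNN follows the committed reading of the architecture
schematic: an edge MLP (widths 16 and 8, latent 16) encodes each edge's
channel vector; incident edge states are aggregated (mean by default — a
symmetric function, making predictions invariant to node relabeling) into
node features and updated by a node MLP; each edge's latent state is
concatenated with its endpoints' node states and scored by a linear
attention layer; a softmax across the graph's edges yields weights whose
weighted sum of edge states is the global embedding, decoded linearly
(sigmoid for classification). Thresholded edges are excluded from message
passing rather than passed as zeros. Attention operates on the hidden edge
states, and the per-edge attention weights — which sum to one per graph —
are the edge-importance readout.

Training uses Adam on mean absolute error (binary cross-entropy for
classification), 200 epochs, batch 64, learning rate 0.005. The forward
and reverse passes are written directly in R (with a small shared dense
network engine also used by the 8-16-16-8 MLP-on-volumes baseline);
training is exactly reproducible given the configuration seed. Ages are
centred and scaled internally on the training set and predictions mapped
back to years; with a bounded-gradient loss and a zero-centred
initialization, regressing raw ages (~50 ± 20) would otherwise spend most
of the training budget moving the output bias.

Cross-validation: per repetition a fresh 10-fold split (repetition `r`
seeds both the fold assignment and the weight initialization with
`seed + r`); within each fold iteration one fold tests, the next validates,
the remaining eight train (80/10/10). The validation fold selects the
epoch: validation loss is evaluated after every epoch and the
best-validation parameters are restored — with a bounded-gradient MAE loss
the output amplitude converges slowly, and epoch selection guards the
test predictions against both under- and over-trained snapshots. The full protocol is 100 repetitions;
exploratory defaults are smaller because a fresh network is trained for
every fold. Edge importance is the mean attention weight over test-set
subjects and repetitions; nodal importance sums incident edge importances;
`top_regions()` takes the top 20% (k = round(0.2 n), ties broken by region
index); overlap between equal-size region sets is `100 |A ∩ B| / |A|`.

# Bias correction and phenotype failure

The age bias model is OLS of predicted on chronological age,
`Y = alpha * Omega + beta`. The applied correction is

    corrected = predicted + (Omega - (alpha * Omega + beta))

— the standard linear brain-age-gap adjustment, and the unique form that
zeroes the OLS slope of the corrected error on age on the fitting set
(an algebraic consequence of least-squares orthogonality; the tests verify
it to 1e-8). It is idempotent under refitting and preserves prediction
rank order at any fixed age. The bias model is fitted per repetition on
that repetition's out-of-fold predictions. Corrected errors are then
associated with covariates: Pearson correlation for continuous covariates,
a two-sample t-test for sex, complete cases per covariate, covariates with
fewer than 10 complete cases skipped with a warning. Raw p values are the
primary report (matching the reporting convention of the analysis family);
a Benjamini–Hochberg column is appended for transparency.

# PLS and VIP

One single-response PLS model per cognitive outcome, on standardized
predictors (sex coded 0/1 and standardized like the rest) and outcome.
NIPALS is implemented directly because the VIP statistic needs the
per-component weights, scores and response loadings exactly:

    VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a ),
    SS_a = q_a^2 t_a' t_a

so that `sum_j VIP_j^2 = p` and VIP > 1 marks an above-average
contribution. The installed mixOmics implementation serves as an
independent cross-check in the test suite, never as the implementation.
The number of latent variables is the argmin of 10-fold RMSECV over
`1..min(p, 10)`; complete cases per outcome, outcomes with fewer than 30
complete cases skipped. One caveat the synthetic recovery experiment makes
visible: when cognition depends on age and a network metric, any other
metric strongly tracking age (e.g. anatomical modularity) can also exceed
VIP = 1 — VIP flags contribution to prediction, not causal specificity.

# Cytoarchitecture

Regions map to at most seven groups (five classical cortical types plus
insula and cingulate); subcortical regions carry no label and are excluded
with a message. The shipped synthetic atlas assigns groups cyclically —
it is a placeholder documented as carrying no neuroanatomical meaning, and
a real mapping is supplied by the user as an atlas column. Intra-group
efficiency is computed on each group's **induced subgraph** (masking edges
while keeping all nodes would let shortest paths leak through removed
nodes), averaged over groups, with < 2-node groups skipped. Edge counts
within groups are correlated with age per group; group volume trajectories
reuse the spline machinery with the whole-brain GCV smoothing frozen
across groups.

# Numerical and scale choices

* Matrices are stored dense with region-id headers; 246 × 246 is tiny.
* `smooth.spline` becomes numerically unstable for extreme penalty values;
  the OLS-limit behaviour is exercised in tests at a large-but-stable
  penalty.
* Test and acceptance experiments run at reduced scale chosen once —
  breakpoint recovery n = 600 and B = 200; ordering recovery n = 450,
  Q-readout, B = 120; GNN overfit check 60 graphs of 30 nodes with batch 8
  (more optimizer steps per epoch at the same 200-epoch budget); the
  reproduction script's cross-validated age model runs on anatomical
  connectomes (110 subjects, 30 regions, 100 epochs at batch 4, matching
  the optimizer-step count of the full protocol) — the modality whose
  generator encodes age continuously, whereas the synthetic similarity
  signal is a binary pattern with a correspondingly low information
  ceiling for continuous age regression; VIP end-to-end n = 200 with 40
  regions. The whole suite completes on one CPU in tens of minutes while
  each recovery stays comfortably above its pass threshold.
* The CLI (`inst/cli/persinet.R`) is a thin wrapper over the exported
  functions; every run writes a JSON manifest (config, seed, package and R
  versions, input hashes).

# Known limitations

* The similarity construction's weighted global efficiency is nearly
  invariant to single-block covariance perturbations (see above); onset
  analyses of similarity networks should lean on modularity/clustering or
  corroborate efficiency results across densities.
* Louvain is a heuristic; Q values are only as stable as the restart
  budget.
* The GNN engine is plain R: suitable for hundreds of subjects and a few
  hundred regions, not for GPU-scale sweeps; no hyperparameter search is
  provided.
* Bootstrap CIs are percentile (not BCa); subjects are the resampling
  unit.
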