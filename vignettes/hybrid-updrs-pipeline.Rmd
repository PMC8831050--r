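---
title: "Cluster-ensemble SVR for UPDRS telemonitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-ensemble SVR for UPDRS telemonitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(UPDRSens)
```

# The problem and the method

Remote telemonitoring of Parkinson's disease records frequent voice
samples per patient and summarizes each recording as a vector of voice
measures (jitter-, shimmer-, entropy-like quantities). Clinical severity
is scored on the Unified Parkinson's Disease Rating Scale: the motor
section (Motor-UPDRS, 0–108) and the full scale (Total-UPDRS, 0–176).
Predicting both scores from the voice measures replaces some in-clinic
assessments.

A single regression model fitted to all patients mixes heterogeneous
subpopulations: groups of patients differ both in where their voice
features lie and in how features map to severity. The pipeline in this
package addresses that heterogeneity explicitly:

1. **Imputation.** Missing feature cells are predicted by iterated
   truncated SVD on the normalized feature block.
2. **Base clusterings.** Expectation-maximization Gaussian mixtures at
   several component counts and self-organizing maps at several lattice
   sizes each partition the recordings.
3. **Consensus.** The resulting cluster ensemble is fused into one
   partition by one of three consensus functions: Hungarian-aligned
   majority voting, CSPA (reclustering the co-association similarity),
   or HGPA (balanced minimal hyperedge cut).
4. **Decorrelation.** Within each consensus cluster, PCA removes the
   multicollinearity of the voice measures.
5. **Prediction.** Per cluster and per target, a bagged ensemble of
   eight RBF-kernel support vector regressors is trained, with
   hyperparameters chosen by exhaustive 5-fold grid search.

Evaluation uses RMSE, MAE, Willmott's index of agreement (IA), the
Pearson correlation of predictions and observations (PA), and adjusted
R².

# Model components and their parameters

## Support vector regression

The ε-insensitive dual is solved by SMO (through libsvm). The kernel is
the γ²-denominator radial basis form

$$K(x, y) = \exp\!\left(-\frac{\lVert x - y\rVert^2}{\gamma^2}\right),$$

so γ is a length scale in feature units. The tuning grids are
γ ∈ [0.01, 0.1] in steps of 0.005 (19 values), ε ∈ [0.0001, 0.002] in
steps of 0.0001 (20 values), and C ∈ [3, 4.1] in steps of 0.005
(221 values); `svrGrids("fast")` keeps every 4th value per axis
(5 × 5 × 56 cells) for desk-scale runs. Note the implied operating
regime: with γ at most 0.1, the kernel only resolves structure when
pairwise feature distances are of order 0.1 — i.e. small-magnitude,
variance-concentrated features, which is what voice-measure panels look
like and what the synthetic generator produces. Grid-search ties are
broken toward smaller C, then larger ε, then smaller γ (the weakest
model among equals). Bagged ensembles use eight members on
with-replacement resamples of the training rows; the ensemble
prediction is the unweighted member mean.

Tuning is per cluster and per target: the groups differ precisely in
the shape and scale of their target functions, so a shared parameter
set would reintroduce the compromise that clustering removes. Inside
the experiment harness the tuning folds are grouped by subject, like
the outer splits — repeated recordings of one subject otherwise sit on
both sides of a tuning fold and bias the selection toward bandwidths
that memorize subject identity.

## EM mixtures and the SOM

EM uses diagonal-covariance Gaussians by default (full covariance by
flag), kmeans++-style seeding, five restarts keeping the best final
likelihood, a variance floor of 1e-6 times each feature's overall
variance, and convergence when the log-likelihood changes by less than
1e-6. The per-iteration log-likelihood trace is stored and must be
nondecreasing — the class validity enforces the fundamental EM
guarantee on every fitted object.

The SOM trains online: per presented sample the best-matching node and
its lattice neighbors move toward the sample; learning rate (from 0.5)
and Gaussian neighborhood radius (from half the larger lattice
dimension) decay exponentially to 0.01 across epochs (default 200 for
standalone fits; the experiment harness uses 50, its desk-scale
choice). Empty nodes remain as empty clusters; the consensus functions
drop them when building hyperedges.

## Consensus functions

*Majority voting* aligns every partition to the first by maximum-overlap
assignment (Hungarian method on the contingency table) and takes each
row's modal aligned label, ties resolved by the earliest partition in
ensemble order. Clusters are enumerated in a canonical content order
(by smallest member row) before the assignment so that equal-overlap
ties resolve identically whatever the arbitrary label names — without
this, label-permutation invariance fails on tie cases.

*CSPA* builds the co-association matrix (the fraction of ensemble
partitions co-clustering each row pair) and recuts it at the target
cluster count by average-linkage agglomeration on 1 − similarity. The
published description calls for a graph partitioner here; similarity
reclustering by deterministic agglomeration honors the same contract
with no external binary and no randomness.

*HGPA* poses consensus as a balanced minimum hyperedge cut: each
cluster of each partition is a hyperedge, and the vertex set is split
into `targetK` parts of size within `(1 ± tolerance)·n/targetK`,
minimizing the number of hyperedges spanning more than one part. The
solver is multi-restart (default 20) greedy vertex-move refinement with
Fiduccia–Mattheyses-style gain bookkeeping, plus two additions that the
plain scheme needs in this setting. First, consensus hyperedges are few
and large, so single-vertex moves almost never change the cut from a
random start — every gain is zero and refinement stalls; moves that
keep the cut equal but increase the total per-edge majority mass (the
sum over edges of the largest within-part count) are therefore
accepted, which strictly increases a bounded potential and so still
terminates. Second, when the size bounds are tight enough that no
single move is feasible (e.g. exactly balanced parts), a bounded sample
of pairwise swaps is tried. The exhaustive-enumeration oracle in the
test suite audits the resulting cuts against the true balanced minimum
on small instances.

The consensus cluster count defaults to the median k of the ensemble's
partitions. `hgpaPartition`'s own imbalance tolerance defaults to 0.2;
the experiment harness passes 0.3 because its outer splits are grouped
by subject, and subject sampling makes the realized cluster sizes
noisier than the balanced ideal — with 0.2, a clean zero-cut consensus
can be infeasible on the train side for purely combinatorial reasons.

## Iterated SVD imputation

Missing cells are initialized at their column means, then the completed
block is repeatedly normalized (per-column z-score; sample SD),
approximated by a truncated SVD at rank d, the masked cells replaced by
the approximation, and the block denormalized, until the largest change
in an imputed cell (original units) falls below `tol` (default 1e-6) or
`maxIter` (default 100) is reached. The normalization is refit each
pass; this matters: with centers frozen to the observed-cell statistics,
the true completion of an exactly rank-d matrix is *not* a fixed point
(observed-only centering perturbs the row space and raises the rank by
one), and exact recovery is impossible. `maxIter = 1` gives the literal
single-pass five-step procedure. The default rank counts the singular
values of the initialized normalized block above the Marchenko–Pastur
noise edge `sqrt(rows) + sqrt(features)`: normalized columns have unit
variance, so a pure-noise matrix of this shape tops out at that edge
and only values above it carry structure. A cumulative-variance rule
(e.g. 90% of squared Frobenius mass) looks natural but fails here
precisely because of the normalization — z-scoring flattens the
spectrum, the rule then keeps nearly full rank, and hard-imputing at
near-full rank fits observed noise and extrapolates badly into the
masked cells (recovery errors *larger* than column-mean imputation).
Observed cells are never altered, bitwise.

## PCA and routing

PCA is fitted per cluster on the covariance (n − 1 denominator) of the
cluster's training rows only, retaining the smallest number of
components whose cumulative explained variance reaches 0.95 (the
retention rule is configurable; the choice is recorded in the fitted
basis). Eigenvector signs are fixed by making each component's
largest-magnitude loading positive, so bases are reproducible across
linear-algebra backends. Clustering runs on the raw (imputed) feature
space and PCA follows within clusters: the groups are defined by where
recordings lie in the measured features, while decorrelation is a
regression concern; fitting PCA per cluster also lets each group keep
the directions that matter for *its* rows.

Unseen rows must be routed to a cluster model. Each stored cluster
carries its centroid and per-feature SDs (imputed feature space), and a
row goes to the cluster maximizing the diagonal-Gaussian log-likelihood:
the per-dimension standardized squared distance plus the
log-determinant term `2·Σ log(sd)`. For clusters of equal spread this
reduces exactly to nearest-centroid routing. The simpler rules fail in
a specific, instructive way when groups differ in spread (as they do in
the heterogeneous regime): plain Euclidean routing hands the wide
cluster's fringe to the narrow cluster, and scale-normalized distance
without the log-determinant lets the wide cluster poach the narrow
clusters' tails — in ~16 dimensions the chi-square spread of a
standardized distance is comparable to the margin, and only the
likelihood form keeps the error rate negligible. Misrouted rows are
predicted by the wrong group's model and err by roughly the
between-group offset, so even a percent of misrouting erases the
benefit of clustering. Routing labels are returned with every
prediction for audit.

Clusters with fewer than `max(folds, minClusterSize)` training rows
(default 25 = 5 folds × 5 rows) are merged into a global fallback
model.

## Evaluation

`computeMetrics` reports RMSE, MAE (mean absolute error), Willmott's
IA = 1 − Σ(P−O)² / Σ(|P−Ō| + |O−Ō|)², PA (Pearson correlation), and
adjusted R² = 1 − (1 − PA²)(n − 1)/(n − m − 1) with m the predictor
count — for cluster-wise models, the cluster-size-weighted mean of the
retained component counts. When predictions are constant their
correlation with the observations is undefined and PA is reported as 0.
The outer evaluation is grouped by subject — all recordings of a
subject stay on one side of every split — because recordings of one
subject are strongly dependent and row-wise splits leak identity;
row-wise splitting exists as an option for comparability. The default
outer scheme is 10-fold grouped cross-validation; the experiment used
in the acceptance script is a single grouped 70/30 split.

The built-in comparison baselines are deliberately *plain*: one
grid-search-tuned global SVR fitted directly on the imputed features,
and one global multiple linear regression on the same features. PCA,
clustering and bagging are all components of the proposed method, so
the baselines get none of them — they represent what a practitioner
would fit without the pipeline.

# The synthetic generator

`generateTelemonitoring` emulates the telemonitoring schema so that
every stage has a ground-truth oracle: ~40 subjects with ~100–200
recordings each (defaults 40 × 150), 16 correlated voice features,
age/sex/test-time covariates, and the two bounded targets.

Structural choices, each made once:

- **Subjects carry cluster membership**: all recordings of a subject
  share the subject's latent group, and a subject-level random shift
  (0.3 within-cluster SD per feature) makes recordings of one subject
  dependent — the reason the harness splits by subject.
- **Feature scales** decay geometrically, 0.05·0.8^(j−1) down to
  ~0.002: a few strong measures dominate the variance and carry the
  UPDRS-relevant signal, the rest are small jitter-like measures. This
  mirrors the magnitude profile of voice panels and gives the two
  properties the pipeline's fixed grids presuppose — covariance PCA
  retains the informative directions, and pairwise distances sit in the
  RBF grid's operating range. A flat equal-scale design looks innocuous
  but makes the kernel either myopic or blind at every grid γ.
- **Cluster placement**: mean offsets of length `clusterSeparation` (in
  within-cluster SD units) along mutually orthogonal directions
  restricted to the strong-feature subspace, so separation survives in
  Euclidean feature space as well as per-dimension.
- **Within-cluster correlation** comes from a rank-3 latent factor with
  strength `featureCorrelation` (default 0.3) — the multicollinearity
  PCA is there to remove.
- **Heterogeneous regime** (`distinctTargets = TRUE`): each group has
  its own target function — Motor-UPDRS is a group level (15–40 across
  groups) plus a sine of the first standardized feature (amplitude
  3–6, frequency 0.8–2), a linear term in the second (|slope| 2–5),
  and a centered quadratic in the third (1–3); Total-UPDRS is an
  affine function of the motor signal plus its own group-specific
  feature term; both drift slowly with test time (0.02 points/day) and
  carry Gaussian noise (`targetNoiseSD`, default 2 points). Groups also
  differ in within-cluster feature spread (multipliers spanning a
  ratio of 2.5). This is the regime in which cluster-then-regress
  genuinely beats one global model: no single coefficient set *or*
  kernel bandwidth serves all groups.
- **Null regime** (`distinctTargets = FALSE`, separation 0): one shared
  target function and equal spreads, where clustering can only cost.
- Targets are clipped to their scale bounds after noise; clipped row
  indices are logged on the returned object so tests can exclude
  saturated rows.

What the generator does **not** emulate: the marginal distributions of
any real voice panel feature-by-feature, measurement drift or device
effects, missingness that is informative rather than uniform, and
disease progression beyond a linear time trend. Passing tests
demonstrate that the pipeline recovers structure *of the kind the
method assumes*; they are silent on how strongly real telemonitoring
cohorts exhibit that structure.

# Desk-scale settings

The experiment harness (`runExperiment`) and the acceptance script use
problem sizes chosen as the package's desk-scale defaults: cohorts of
1,500 recordings (60 subjects × 25), the fast grids, 8-member
ensembles, 5-fold tuning, and a hyperparameter tuning subsample of
`tuningRows = 200` rows per model (the grid search sees a seeded
subsample; final ensembles always train on all rows of their cluster).
`svrGrids("full")` and `tuningRows = Inf` reproduce the full published
protocol. The SOM uses 50 epochs inside the harness and 200 standalone.

# Numerical conventions

- Column normalization z-scores with the sample (n−1) SD; constant
  columns are an error naming the column.
- EM ties in the argmax responsibility go to the lowest component
  index; the variance floor is logged on the model.
- Grid-search folds come from a seeded shuffle; all seeds derive from
  one master seed per run, so a run is a pure function of its
  configuration.
- Bootstrap member i uses seed + i; a degenerate resample (fewer than
  two unique rows) is redrawn with a fresh sub-seed.
- The SVR solver tolerance defaults to libsvm's 1e-3; tighten to ~1e-7
  when exact KKT structure matters (e.g. verifying that points strictly
  inside the tube carry zero dual coefficients).
- Cluster labels are 1-based throughout.

# Known limitations

- The consensus solvers are heuristics: HGPA's greedy refinement
  carries no optimality certificate (the suite audits it against
  exhaustive enumeration only on small instances), and CSPA's
  agglomeration is one of several reasonable similarity reclusterings.
- Routing assumes clusters are usefully summarized by a centroid and
  per-feature SDs; strongly non-elliptical groups would need the full
  mixture responsibilities instead.
- The published evaluation-metric formulas contain internal
  inconsistencies (an MAE printed with squared differences, a garbled
  correlation expression); this package reports the standard
  definitions (MAE as mean absolute error, PA as Pearson correlation,
  Willmott's IA), so printed values elsewhere that follow the
  non-standard forms are not directly comparable.
- Imputation assumes the feature block is approximately low-rank and
  missingness is unstructured; it never imputes targets.

# A small worked run

```{r demo, eval = FALSE}
cfg <- experimentConfig(
  data = syntheticConfig(nSubjects = 12, recordingsPerSubject = 10,
                         nClusters = 3, clusterSeparation = 6, seed = 7),
  ensemble = list(list(type = "em", k = 3), list(type = "em", k = 4)),
  consensusMethods = "hgpa", targetK = 3,
  grids = svrGrids("fast"), tuningRows = 60, minClusterSize = 10,
  scheme = "split", seed = 7)
res <- runExperiment(cfg)
res$report
res$details$ariTruth
```

The same run is reachable from a shell through the thin command-line
wrapper:

```sh
Rscript inst/scripts/updrs.R run \
  --config inst/extdata/demo_run.yaml --out demo_out
```

which writes `report.csv` and a `manifest.json` sufficient to reproduce
the run byte for byte.
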