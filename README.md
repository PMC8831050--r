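# UPDRSens

Cluster-ensemble support vector regression for predicting Parkinson's
disease severity (Motor-UPDRS, 0–108, and Total-UPDRS, 0–176) from
telemonitoring voice features.

Telemonitoring cohorts are heterogeneous: groups of patients differ both
in where their voice measures lie and in how those measures map to
clinical severity, so one global regression model underfits everyone at
once. This package implements a hybrid pipeline that discovers the
groups first and regresses within them:

1. **Missing-value imputation** by iterated truncated SVD on the
   normalized feature block: masked cells start at their column means
   and are repeatedly replaced by a rank-*d* approximation until the
   imputed values stop moving.
2. **Base clusterings** by expectation-maximization Gaussian mixtures
   (responsibilities p(m|x) ∝ wₘ·φ(x; μₘ, σₘ), argmax assignment) at
   several k, and online self-organizing maps at several lattice sizes.
3. **Consensus fusion** of the resulting cluster ensemble by majority
   voting (Hungarian-aligned modal labels), CSPA (average-linkage
   reclustering of the co-association similarity Sᵢⱼ = fraction of
   partitions co-clustering rows i and j), or HGPA (balanced minimal
   hyperedge cut by multi-restart greedy refinement).
4. **Per-cluster PCA** (0.95 cumulative-variance retention) to remove
   the multicollinearity of the voice measures.
5. **Per-cluster bagged SVR**: for each cluster and each target, eight
   ε-insensitive RBF support vector regressors on bootstrap resamples,
   prediction = member mean. The kernel is K(x,y) = exp(−‖x−y‖²/γ²);
   hyperparameters come from exhaustive 5-fold grid search over
   γ ∈ [0.01, 0.1] (step 0.005), ε ∈ [0.0001, 0.002] (step 0.0001),
   C ∈ [3, 4.1] (step 0.005), or a reduced "fast" grid.
6. **Evaluation** by RMSE, MAE, Willmott's index of agreement,
   prediction accuracy (Pearson correlation), and adjusted
   R² = 1 − (1 − R²)(n−1)/(n−m−1), under subject-grouped outer splits.

A synthetic telemonitoring generator with known group structure, known
per-group target functions, and controllable noise/missingness provides
a ground-truth oracle for every stage; global SVR and multiple linear
regression baselines are built in for comparison. The methods vignette
(`vignettes/hybrid-updrs-pipeline.Rmd`) documents the models, the
parameter choices and the design decisions in detail.

## Worked example

```r
library(UPDRSens)

cfg <- experimentConfig(
  data = syntheticConfig(nSubjects = 12, recordingsPerSubject = 10,
                         nClusters = 3, clusterSeparation = 6, seed = 7),
  ensemble = list(list(type = "em", k = 3), list(type = "em", k = 4)),
  consensusMethods = "hgpa", targetK = 3,
  grids = svrGrids("fast"), tuningRows = 60, minClusterSize = 10,
  scheme = "split", seed = 7)
res <- runExperiment(cfg)
print(res)
```

```
UPDRS pipeline experiment
 ensemble_size     composition     method      target  rmse   mae     ia     pa
             2 EM k=3 + EM k=4       hgpa motor_updrs 3.531 2.763 0.9613 0.9307
             2 EM k=3 + EM k=4       hgpa total_updrs 5.942 5.149 0.9392 0.8868
             1      global_svr global_svr motor_updrs 5.145 4.124 0.8910 0.8925
             1      global_svr global_svr total_updrs 8.113 6.107 0.8440 0.8289
             1      global_mlr global_mlr motor_updrs 6.188 5.083 0.8748 0.7750
             1      global_mlr global_mlr total_updrs 9.292 7.931 0.8339 0.7095
 r2_adjusted  n
      0.8418 40
      0.7476 40
      0.6552 40
      0.4694 40
      0.3229 40
      0.1578 40
consensus ARI vs true labels:
hgpa 
   1
```

Reading the report: each row is one model and one target evaluated on
the held-out recordings (here 40 rows of a grouped 70/30 split of a
120-recording synthetic cohort with three planted patient groups). The
HGPA-consensus cluster-wise SVR ensemble predicts Motor-UPDRS with RMSE
3.53 points versus 5.15 for a single plain global SVR and 6.19 for
global multiple linear regression — the heterogeneity the cohort was generated
with is exactly what cluster-then-regress exploits. The consensus
partition recovered the planted grouping perfectly (adjusted Rand
index 1).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/updrs.R synth --config synth.yaml --out data.csv
Rscript inst/scripts/updrs.R mask --fraction 0.1 --seed 1 data.csv masked.csv
Rscript inst/scripts/updrs.R impute masked.csv dense.csv
Rscript inst/scripts/updrs.R run --config inst/extdata/demo_run.yaml --out out/
```

`run` writes `report.csv` plus a `manifest.json` that reproduces the run
byte for byte.

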