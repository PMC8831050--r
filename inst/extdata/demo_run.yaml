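# Demo pipeline run at desk scale: synthetic 3-group telemonitoring data,
# EM base clusterings fused by HGPA, cluster-wise SVR ensembles, global
# SVR and MLR baselines.
synthetic:
  nSubjects: 12
  recordingsPerSubject: 10
  nClusters: 3
  clusterSeparation: 6
  seed: 7
ensemble:
  - type: em
    k: 3
  - type: em
    k: 4
consensus_methods: [hgpa]
target_k: 3
grid: fast
tuning_rows: 60
min_cluster_size: 10
scheme: split
train_fraction: 0.7
seed: 7
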