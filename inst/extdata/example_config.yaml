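# Example pipeline configuration: study-sized synthetic dataset with a
# planted sparse signal. Swap `input` for a compounds block to run on a
# real table:
#   input:
#     type: compounds
#     path: compounds.csv
#     k_ref: 2.3e5          # reference quenching rate constant (1/(M s))
input:
  type: synthetic
  n_samples: 74
  n_descriptors: 60
  n_fp_bits: 2048
  fp_density: 0.05
  blocks:
    - size: 6
      rho: 0.9
    - size: 5
      rho: 0.8
    - size: 4
      rho: 0.6
  planted:
    desc_0021: 1.0
    desc_0022: -0.8
    desc_0023: 0.8
    desc_0024: 0.6
    desc_0025: -0.6
  noise_sd: 0.866
  seed: 0
featurization:
  backend: stub            # stub | toolkit | quantum
  radius: 2
  n_bits: 2048
selection:
  threshold: 0.95          # mandatory: pairwise |r| pruning cutoff
models:
  algorithms: [xgboost, lightgbm, catboost, random_forest, adaboost, lasso, dnn]
  random_states: [0, 10, 100]
  loocv: false
  hyperparameters:
    xgboost:
      nrounds: 150
    random_forest:
      ntree: 300
importance:
  top_k: 7
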