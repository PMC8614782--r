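## Shared fixtures: small feature tables and compound sets built in code.

make_ft <- function(m, kind = "descriptor") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  featureTable(m, kind = kind)
}

rand_ft <- function(n, p, seed = 1, prefix = "v") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  make_ft(m)
}

## small, well-formed compound records (real SMILES, synthetic SOAC values)
stub_records <- function() {
  list(
    compoundRecord("c1", "CCO", name = "ethanol", soac = 0.5),
    compoundRecord("c2", "c1ccccc1O", name = "phenol", soac = 2.0),
    compoundRecord("c3", "CC(C)=CCO", name = "prenol", soac = 1.2),
    compoundRecord("c4", "Oc1ccc(O)cc1", name = "hydroquinone", soac = 8.0),
    compoundRecord("c5", "CC1=CC(=O)CC(C)(C)C1", name = "isophorone", soac = 0.9)
  )
}

write_compound_csv <- function(path, rows) {
  writeLines(c("id,name,smiles,soac", rows), path)
  path
}

## fast hyperparameters for grid-level tests
fast_hp <- function() {
  list(xgboost = list(nrounds = 100L),
       random_forest = list(ntree = 150L),
       adaboost = list(nEstimators = 15L),
       lightgbm = list(num_boost_round = 100L),
       dnn = list(max_iter = 600L))
}

## a ModelRun with a prescribed importance vector and r2
fake_run <- function(importance, r2, algorithm = "random_forest",
                     featureSet = "descriptor", randomState = 0L) {
  methods::new("ModelRun", algorithm = algorithm, featureSet = featureSet,
               randomState = as.integer(randomState), hyperparameters = list(),
               r2 = r2, rmse = 0.5, rmseLoo = NA_real_,
               importance = importance,
               predictions = c(s1 = 0), trainIds = "s0", testIds = "s1")
}

## algorithms whose backing implementation exists in this installation
available_algorithms <- function(importance_only = FALSE) {
  algs <- c("lasso", "random_forest", "xgboost", "adaboost", "lightgbm")
  if (!soacqspr:::.py_lib_available("lightgbm"))
    algs <- setdiff(algs, "lightgbm")
  if (!importance_only && soacqspr:::.py_lib_available("sklearn"))
    algs <- c(algs, "dnn")
  algs
}
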