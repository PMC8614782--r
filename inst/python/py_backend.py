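"""Subprocess model backends (LightGBM, MLP regressor).

Called by the R package with a JSON job file:
  {
    "algorithm": "lightgbm" | "mlp",
    "mode": "fit" | "predict" | "loocv",
    "train": "<csv: first column y, rest features>",   (fit, loocv)
    "test": "<csv: features only>",                    (optional, fit)
    "model": "<model file path>",                      (out for fit, in for predict; lightgbm only)
    "newdata": "<csv: features only>",                 (predict)
    "params": {...},
    "seed": int,
    "out": "<json result path>"
  }
Results: {"predictions": [...], "importance": {feature: gain}, "loocv_abs_errors": [...]}
Single-threaded and deterministic for a fixed seed.
"""
import json
import sys

import numpy as np
import pandas as pd


class LightGBM:
    def __init__(self, job):
        import lightgbm as lgb
        self.lgb = lgb
        params = {
            "objective": "regression",
            "verbosity": -1,
            "num_threads": 1,
            "deterministic": True,
            "force_row_wise": True,
            "seed": int(job.get("seed", 0)),
        }
        user = dict(job.get("params", {}))
        self.rounds = int(user.pop("num_boost_round", 300))
        params.update(user)
        self.params = params
        self.booster = None

    def fit(self, X, y):
        dtrain = self.lgb.Dataset(X, label=y, params={"verbosity": -1})
        self.booster = self.lgb.train(self.params, dtrain,
                                      num_boost_round=self.rounds)

    def predict(self, X):
        return self.booster.predict(X)

    def importance(self):
        gain = self.booster.feature_importance(importance_type="gain")
        return dict(zip(self.booster.feature_name(), gain.tolist()))

    def save(self, path):
        self.booster.save_model(path)

    def load(self, path):
        self.booster = self.lgb.Booster(model_file=path)


class MLP:
    """Small fixed multilayer perceptron; standardized inputs."""

    def __init__(self, job):
        from sklearn.neural_network import MLPRegressor
        p = dict(job.get("params", {}))
        self.model = MLPRegressor(
            hidden_layer_sizes=tuple(p.get("hidden_layer_sizes", [64, 32])),
            alpha=float(p.get("alpha", 1e-3)),
            max_iter=int(p.get("max_iter", 2000)),
            solver="adam",
            random_state=int(job.get("seed", 0)),
        )
        self.mu = None
        self.sd = None

    def fit(self, X, y):
        self.mu = X.mean(axis=0)
        self.sd = X.std(axis=0)
        self.sd[self.sd == 0] = 1.0
        self.model.fit((X - self.mu) / self.sd, y)

    def predict(self, X):
        return self.model.predict((X - self.mu) / self.sd)

    def importance(self):
        return None

    def save(self, path):
        raise SystemExit("mlp: model persistence not supported; refit instead")

    load = save


BACKENDS = {"lightgbm": LightGBM, "mlp": MLP}


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    backend = BACKENDS[job.get("algorithm", "lightgbm")](job)
    mode = job["mode"]
    result = {}

    if mode in ("fit", "loocv"):
        train = pd.read_csv(job["train"])
        y = train.iloc[:, 0].to_numpy()
        X = train.iloc[:, 1:]

    if mode == "fit":
        backend.fit(X, y)
        if job.get("model"):
            backend.save(job["model"])
        if job.get("test"):
            result["predictions"] = backend.predict(pd.read_csv(job["test"])).tolist()
        imp = backend.importance()
        if imp is not None:
            result["importance"] = imp
    elif mode == "predict":
        backend.load(job["model"])
        result["predictions"] = backend.predict(pd.read_csv(job["newdata"])).tolist()
    elif mode == "loocv":
        errs = []
        n = len(y)
        for i in range(n):
            idx = np.arange(n) != i
            backend.fit(X.iloc[idx], y[idx])
            errs.append(abs(float(y[i]) - float(backend.predict(X.iloc[[i]])[0])))
        result["loocv_abs_errors"] = errs
    else:
        raise SystemExit(f"unknown mode: {mode}")

    with open(job["out"], "w") as fh:
        json.dump(result, fh)


if __name__ == "__main__":
    main(sys.argv[1])
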