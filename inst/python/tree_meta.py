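"""Tree-based fusion meta-learners called from R.

Fits, per outer fold, either a random survival forest (scikit-survival)
tuned by seeded random search over the configured grid (selected by
Harrell C-index on inner validation folds), or a gradient-boosted tree
classifier on the binary event-by-t* endpoint tuned by exhaustive
depth x learning-rate grid search (selected by log-loss). Emits, per
fold, the tuned model's predicted absolute risk at t* for every patient
(training rows are used by the caller only to calibrate a survival-curve
mapping) and, for the survival forest, test-row survival curves on the
requested evaluation grid.

Usage: python tree_meta.py --data data.csv --config config.json --out out.json
Exit code 3 signals missing learner packages.
"""

import argparse
import json
import sys

try:
    import numpy as np
    import pandas as pd
except ImportError as exc:  # pragma: no cover
    sys.stderr.write("missing numpy/pandas: %s\n" % exc)
    sys.exit(3)

try:
    from sksurv.ensemble import RandomSurvivalForest
    from sksurv.util import Surv
except ImportError as exc:
    RandomSurvivalForest = None
    _SKSURV_ERR = exc

try:
    from sklearn.ensemble import GradientBoostingClassifier
    from sklearn.metrics import log_loss
except ImportError as exc:  # pragma: no cover
    GradientBoostingClassifier = None
    _SKLEARN_ERR = exc

FEATURES = ["score_clinical", "score_demographic", "score_radiomic"]


def as_list(v):
    """JSON auto-unboxing turns length-1 vectors into scalars."""
    return v if isinstance(v, list) else [v]


def stratified_folds(strata, k, rng):
    """Fold ids (1..k), round-robin within shuffled strata."""
    n = len(strata)
    folds = np.zeros(n, dtype=int)
    order = []
    for val in np.unique(strata):
        idx = np.where(strata == val)[0]
        order.extend(rng.permutation(idx).tolist())
    folds[np.asarray(order)] = np.arange(n) % k + 1
    return folds


def cindex(time, event, risk):
    """Harrell C-index (ties credit 0.5); comparable pair = earlier event."""
    num = den = 0.0
    order = np.argsort(time)
    t, d, r = time[order], event[order], risk[order]
    for i in range(len(t) - 1):
        if d[i] != 1:
            continue
        later = t > t[i]
        m = later.sum()
        if m == 0:
            continue
        den += m
        num += (r[i] > r[later]).sum() + 0.5 * (r[i] == r[later]).sum()
    return num / den if den > 0 else np.nan


def step_surv_at(times_grid, unique_times, surv_vals, t):
    """Right-continuous step survival function evaluated at t."""
    idx = np.searchsorted(unique_times, t, side="right") - 1
    if idx < 0:
        return 1.0
    return float(surv_vals[idx])


def rsf_risk_at(model, X, t_star):
    fns = model.predict_survival_function(X, return_array=True)
    ut = model.unique_times_
    idx = np.searchsorted(ut, t_star, side="right") - 1
    if idx < 0:
        s = np.ones(X.shape[0])
    else:
        s = fns[:, idx]
    return 1.0 - s


def rsf_surv_matrix(model, X, eval_times):
    fns = model.predict_survival_function(X, return_array=True)
    ut = model.unique_times_
    out = np.ones((X.shape[0], len(eval_times)))
    for j, t in enumerate(eval_times):
        idx = np.searchsorted(ut, t, side="right") - 1
        if idx >= 0:
            out[:, j] = fns[:, idx]
    return out


def sample_rsf_grid(grid, n_sample, rng):
    combos = [(m, ns, nt, sp)
              for m in as_list(grid["mtry"])
              for ns in as_list(grid["node_size"])
              for nt in as_list(grid["n_trees"])
              for sp in as_list(grid["n_splits"])]
    n_sample = min(int(n_sample), len(combos))
    pick = rng.choice(len(combos), size=n_sample, replace=False)
    return [combos[i] for i in pick]


def fit_rsf(Xtr, ytr_time, ytr_event, params, seed):
    mtry, node_size, n_trees, n_splits = params
    y_struct = Surv.from_arrays(event=ytr_event.astype(bool), time=ytr_time)
    model = RandomSurvivalForest(
        n_estimators=int(n_trees),
        max_features=int(mtry),
        min_samples_leaf=int(node_size),
        # the available learner has no per-variable random-split-count
        # parameter; the split dimension maps to min_samples_split
        min_samples_split=max(2, int(n_splits)),
        n_jobs=1,
        random_state=int(seed),
    )
    model.fit(Xtr, y_struct)
    return model


def run_rsf(df, cfg):
    if RandomSurvivalForest is None:
        sys.stderr.write("scikit-survival unavailable: %s\n" % _SKSURV_ERR)
        sys.exit(3)
    rng = np.random.RandomState(cfg["seed"])
    X = df[FEATURES].to_numpy()
    time = df["time"].to_numpy()
    event = df["event"].to_numpy()
    folds = df["fold"].to_numpy().astype(int)
    eval_times = np.asarray(as_list(cfg["eval_times"]), dtype=float)
    inner_k = int(cfg["inner_k"])
    results = []
    insample = bool(cfg.get("insample", False))
    for f in sorted(np.unique(folds)):
        if insample:
            tr = np.ones(len(folds), dtype=bool)
            te = np.ones(len(folds), dtype=bool)
        else:
            tr = folds != f
            te = ~tr
        candidates = sample_rsf_grid(cfg["rsf"], cfg["rsf"]["n_sample"], rng)
        inner = stratified_folds(event[tr], inner_k,
                                 np.random.RandomState(cfg["seed"] * 131 + f))
        Xtr, ttr, etr = X[tr], time[tr], event[tr]
        best = None
        for params in candidates:
            cs = []
            for g in range(1, inner_k + 1):
                fit_idx = inner != g
                val_idx = ~fit_idx
                if etr[fit_idx].sum() == 0 or etr[val_idx].sum() == 0:
                    continue
                m = fit_rsf(Xtr[fit_idx], ttr[fit_idx], etr[fit_idx],
                            params, cfg["seed"] * 977 + f)
                cs.append(cindex(ttr[val_idx], etr[val_idx],
                                 m.predict(Xtr[val_idx])))
            score = float(np.nanmean(cs)) if cs else -np.inf
            if best is None or score > best[0]:
                best = (score, params)
        params = best[1]
        model = fit_rsf(Xtr, ttr, etr, params, cfg["seed"] * 977 + f)
        pred_all = rsf_risk_at(model, X, cfg["t_star"])
        surv_te = rsf_surv_matrix(model, X[te], eval_times)
        results.append({
            "fold": int(f),
            "params": {"mtry": int(params[0]), "node_size": int(params[1]),
                       "n_trees": int(params[2]), "n_splits": int(params[3]),
                       "inner_cindex": best[0]},
            "pred_all": pred_all.tolist(),
            "surv_test": surv_te.tolist(),
        })
    return {"folds": results}


def run_gbt(df, cfg):
    if GradientBoostingClassifier is None:
        sys.stderr.write("scikit-learn unavailable: %s\n" % _SKLEARN_ERR)
        sys.exit(3)
    X = df[FEATURES].to_numpy()
    time = df["time"].to_numpy()
    event = df["event"].to_numpy()
    folds = df["fold"].to_numpy().astype(int)
    t_star = float(cfg["t_star"])
    inner_k = int(cfg["inner_k"])
    grid = [(int(d), float(lr))
            for d in as_list(cfg["gbt"]["max_depth"])
            for lr in as_list(cfg["gbt"]["learning_rate"])]
    n_estimators = int(cfg["gbt"]["n_estimators"])
    # landmark labels: 1 = event by t*, 0 = under observation past t*,
    # censored before t* excluded from training
    label = np.where(time > t_star, 0.0,
                     np.where(event == 1, 1.0, np.nan))
    results = []
    insample = bool(cfg.get("insample", False))
    for f in sorted(np.unique(folds)):
        tr = np.ones(len(folds), dtype=bool) if insample else folds != f
        use = tr & ~np.isnan(label)
        Xu, yu = X[use], label[use]
        if len(np.unique(yu)) < 2:
            sys.stderr.write("fold %d: all landmark labels identical\n" % f)
            sys.exit(2)
        inner = stratified_folds(yu, inner_k,
                                 np.random.RandomState(cfg["seed"] * 131 + f))
        best = None
        for depth, lr in grid:
            losses = []
            for g in range(1, inner_k + 1):
                fit_idx = inner != g
                val_idx = ~fit_idx
                if len(np.unique(yu[fit_idx])) < 2 or val_idx.sum() == 0:
                    continue
                m = GradientBoostingClassifier(
                    max_depth=depth, learning_rate=lr,
                    n_estimators=n_estimators,
                    random_state=cfg["seed"] * 977 + f)
                m.fit(Xu[fit_idx], yu[fit_idx])
                p = m.predict_proba(Xu[val_idx])[:, 1]
                losses.append(log_loss(yu[val_idx], p, labels=[0.0, 1.0]))
            score = float(np.nanmean(losses)) if losses else np.inf
            if best is None or score < best[0]:
                best = (score, depth, lr)
        _, depth, lr = best
        model = GradientBoostingClassifier(
            max_depth=depth, learning_rate=lr, n_estimators=n_estimators,
            random_state=cfg["seed"] * 977 + f)
        model.fit(Xu, yu)
        pred_all = model.predict_proba(X)[:, 1]
        results.append({
            "fold": int(f),
            "params": {"max_depth": depth, "learning_rate": lr,
                       "n_estimators": n_estimators,
                       "inner_logloss": best[0]},
            "pred_all": pred_all.tolist(),
            "surv_test": None,
        })
    return {"folds": results}


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--data", required=True)
    ap.add_argument("--config", required=True)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()
    with open(args.config) as fh:
        cfg = json.load(fh)
    df = pd.read_csv(args.data)
    if cfg["kind"] == "rsf":
        out = run_rsf(df, cfg)
    elif cfg["kind"] == "gbt":
        out = run_gbt(df, cfg)
    else:
        sys.stderr.write("unknown kind: %s\n" % cfg["kind"])
        sys.exit(2)
    with open(args.out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
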