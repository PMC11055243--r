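"""Independent maximum-likelihood Gaussian-HMM oracle (hmmlearn).

Reads a JSON job from the file given as argv[1]:
  {"mode": "score" | "fit",
   "start": [...], "trans": [[...]], "means": [...], "sds": [...],
   "sequences": [[...], ...], "n_iter": int, "tol": float}
and prints a JSON result to stdout. "score" evaluates the log-likelihood of
the supplied parameters; "fit" runs classical (ML) Baum-Welch from them.
"""
import json
import sys

import numpy as np
from hmmlearn.hmm import GaussianHMM


def build(job):
    k = len(job["start"])
    m = GaussianHMM(n_components=k, covariance_type="diag",
                    min_covar=1e-12, init_params="", params="stmc",
                    n_iter=job.get("n_iter", 500), tol=job.get("tol", 1e-8),
                    implementation="scaling")
    m.startprob_ = np.asarray(job["start"], dtype=float)
    m.transmat_ = np.asarray(job["trans"], dtype=float)
    m.means_ = np.asarray(job["means"], dtype=float).reshape(-1, 1)
    m.covars_ = np.asarray(job["sds"], dtype=float).reshape(-1, 1) ** 2
    return m


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)
    seqs = [np.asarray(s, dtype=float).reshape(-1, 1) for s in job["sequences"]]
    X = np.concatenate(seqs)
    lengths = [len(s) for s in seqs]
    model = build(job)
    if job["mode"] == "fit":
        model.fit(X, lengths)
    out = {
        "loglik": float(model.score(X, lengths)),
        "start": model.startprob_.tolist(),
        "trans": model.transmat_.tolist(),
        "means": model.means_.ravel().tolist(),
        "sds": np.sqrt(model.covars_.ravel()).tolist(),
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
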