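"""UMAP backend for the 2D reducer.

Called by the R package via system(); not a public interface.
fit:       read reference embeddings (TSV, no header), fit a 2D UMAP with a
           fixed random state, write reference coordinates and pickle the
           fitted model.
transform: load a pickled model and transform new embeddings (never refit).
"""
import argparse
import pickle
import sys

import numpy as np


def main() -> int:
    ap = argparse.ArgumentParser()
    ap.add_argument("command", choices=["fit", "transform"])
    ap.add_argument("--in-tsv", required=True)
    ap.add_argument("--out-tsv", required=True)
    ap.add_argument("--model", required=True)
    ap.add_argument("--seed", type=int, default=42)
    ap.add_argument("--n-neighbors", type=int, default=15)
    ap.add_argument("--min-dist", type=float, default=0.1)
    args = ap.parse_args()

    X = np.loadtxt(args.in_tsv, delimiter="\t", ndmin=2)
    if args.command == "fit":
        import umap

        n_neighbors = min(args.n_neighbors, X.shape[0] - 1)
        model = umap.UMAP(
            n_components=2,
            n_neighbors=n_neighbors,
            min_dist=args.min_dist,
            metric="euclidean",
            random_state=args.seed,
            n_jobs=1,
        )
        coords = model.fit_transform(X)
        with open(args.model, "wb") as fh:
            pickle.dump(model, fh)
    else:
        with open(args.model, "rb") as fh:
            model = pickle.load(fh)
        coords = model.transform(X)
    np.savetxt(args.out_tsv, coords, delimiter="\t", fmt="%.17g")
    return 0


if __name__ == "__main__":
    sys.exit(main())
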