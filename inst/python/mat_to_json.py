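"""Convert a per-patient gadoxetate time-series MAT file to JSON.

Canonical layout: a struct array (or cell of structs) named ``patients``
with fields id, times, liver_dr1, liver_sem, spleen_dr1, spleen_sem,
weight, stage (numeric 0-4). A ``--map canonical=actual,...`` option
renames fields for files using a different vocabulary. Output JSON:
{"patients": [...], "warnings": [...]}.
"""
import argparse
import json
import sys

import numpy as np
from scipy.io import loadmat

CANONICAL = ["id", "times", "liver_dr1", "liver_sem",
             "spleen_dr1", "spleen_sem", "weight", "stage"]
REQUIRED = ["times", "liver_dr1", "spleen_dr1"]


def as_list(x):
    return np.asarray(x, dtype=float).ravel().tolist()


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mat_path")
    ap.add_argument("json_path")
    ap.add_argument("--map", default="", dest="field_map")
    args = ap.parse_args()

    fmap = dict(kv.split("=", 1) for kv in args.field_map.split(",") if kv)
    mat = loadmat(args.mat_path, squeeze_me=True, struct_as_record=False)
    if "patients" not in mat:
        sys.exit("no 'patients' variable in MAT file")
    patients = np.atleast_1d(mat["patients"])

    warnings, out = [], []
    for i, rec in enumerate(patients):
        fields = set(rec._fieldnames)
        get = lambda name: getattr(rec, fmap.get(name, name), None)
        missing = [f for f in REQUIRED
                   if fmap.get(f, f) not in fields]
        if missing:
            sys.exit(f"patient {i}: missing required fields {missing}")
        extra = fields - {fmap.get(f, f) for f in CANONICAL}
        if extra:
            warnings.append(
                f"patient {i}: ignoring unknown fields {sorted(extra)}")
        times = as_list(get("times"))
        n = len(times)
        entry = {
            "id": str(get("id")) if fmap.get("id", "id") in fields
                  else f"patient_{i + 1:03d}",
            "times": times,
            "liver_dr1": as_list(get("liver_dr1")),
            "spleen_dr1": as_list(get("spleen_dr1")),
            "liver_sem": as_list(get("liver_sem"))
                         if fmap.get("liver_sem", "liver_sem") in fields
                         else [0.0] * n,
            "spleen_sem": as_list(get("spleen_sem"))
                          if fmap.get("spleen_sem", "spleen_sem") in fields
                          else [0.0] * n,
        }
        if fmap.get("weight", "weight") in fields:
            entry["weight"] = float(np.asarray(get("weight")).ravel()[0])
        if fmap.get("stage", "stage") in fields:
            entry["stage"] = int(np.asarray(get("stage")).ravel()[0])
        else:
            warnings.append(
                f"patient {i}: no fibrosis stage; loading as unknown")
        out.append(entry)

    with open(args.json_path, "w") as fh:
        json.dump({"patients": out, "warnings": warnings}, fh)


if __name__ == "__main__":
    main()
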