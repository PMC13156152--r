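"""Exact MILP backend: solves batches of integer programs with HiGHS.

Reads a JSON problem batch from the file given as argv[1] and writes a JSON
result list to argv[2]. The batch shares one constraint matrix (triplet
form, 1-based indices) across problems; each problem carries its own
objective (maximised) and optionally one extra <= row, which is how
epsilon-constraint floors are injected without rebuilding the model.
"""

import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import csr_matrix

STATUS = {0: "optimal", 1: "iteration-limit", 2: "infeasible",
          3: "unbounded", 4: "numerical"}


def main(infile, outfile):
    with open(infile) as fh:
        payload = json.load(fh)
    n = int(payload["n_var"])
    n_con = int(payload["n_con"])
    A = csr_matrix(
        (payload["a_val"],
         (np.asarray(payload["a_row"], dtype=int) - 1,
          np.asarray(payload["a_col"], dtype=int) - 1)),
        shape=(n_con, n),
    )
    b_ub = np.asarray(payload["b_ub"], dtype=float)
    bounds = Bounds(np.asarray(payload["lb"], dtype=float),
                    np.asarray(payload["ub"], dtype=float))
    integrality = np.asarray(payload["integrality"], dtype=int)
    gap = float(payload.get("gap", 1e-4))

    results = []
    for prob in payload["problems"]:
        c = np.asarray(prob["c"], dtype=float)
        constraints = [LinearConstraint(A, -np.inf, b_ub)]
        extra = prob.get("extra")
        if extra:
            cols = np.asarray(extra["col"], dtype=int) - 1
            Ae = csr_matrix(
                (np.asarray(extra["val"], dtype=float),
                 (np.zeros(len(cols), dtype=int), cols)),
                shape=(1, n),
            )
            constraints.append(
                LinearConstraint(Ae, -np.inf, [float(extra["rhs"])]))
        res = milp(c=-c, constraints=constraints, integrality=integrality,
                   bounds=bounds, options={"mip_rel_gap": gap})
        out = {"status": STATUS.get(res.status, "unknown"),
               "success": bool(res.success)}
        if res.x is not None:
            out["x"] = [float(v) for v in res.x]
            out["objective"] = float(-res.fun)
            out["gap"] = (float(res.mip_gap)
                          if getattr(res, "mip_gap", None) is not None
                          else 0.0)
        results.append(out)

    with open(outfile, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
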