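"""Batch LP/MILP solving service for the flexnets R package.

Reads a JSON file containing a list of problems, solves each with
scipy's HiGHS interface, and writes a JSON list of results.

Each problem:
  {"c": [...],
   "Aeq": {"i": [...], "j": [...], "x": [...], "m": M, "n": N},
   "beq": [...], "Aub": {...}, "bub": [...],
   "lb": [...], "ub": [...],           # nulls mean +/- infinity
   "integrality": [...] (optional 0/1 per variable)}

Result: {"status": "optimal"|"infeasible"|"unbounded"|"error",
         "x": [...], "fun": value}
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog, milp, LinearConstraint, Bounds
from scipy.sparse import coo_matrix


def mat(d):
    if d is None or d["m"] == 0:
        return None
    return coo_matrix(
        (d["x"], (np.asarray(d["i"], dtype=int), np.asarray(d["j"], dtype=int))),
        shape=(d["m"], d["n"]),
    ).tocsc()


def clean(v, repl):
    a = np.array([repl if x is None else x for x in v], dtype=float)
    return a


def solve_one(p):
    n = len(p["c"])
    c = np.asarray(p["c"], dtype=float)
    Aeq, beq = mat(p.get("Aeq")), np.asarray(p.get("beq") or [], dtype=float)
    Aub, bub = mat(p.get("Aub")), np.asarray(p.get("bub") or [], dtype=float)
    lb = clean(p.get("lb", [0] * n), -np.inf)
    ub = clean(p.get("ub", [None] * n), np.inf)
    integrality = p.get("integrality")
    try:
        if integrality is not None and any(integrality):
            cons = []
            if Aeq is not None:
                cons.append(LinearConstraint(Aeq, beq, beq))
            if Aub is not None:
                cons.append(LinearConstraint(Aub, -np.inf, bub))
            res = milp(
                c=c,
                constraints=cons,
                bounds=Bounds(lb, ub),
                integrality=np.asarray(integrality, dtype=int),
            )
            status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                      3: "unbounded"}.get(res.status, "error")
            x = None if res.x is None else res.x.tolist()
            fun = None if res.fun is None else float(res.fun)
        else:
            res = linprog(
                c=c, A_ub=Aub, b_ub=bub if Aub is not None else None,
                A_eq=Aeq, b_eq=beq if Aeq is not None else None,
                bounds=np.column_stack([lb, ub]), method="highs",
            )
            status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                      3: "unbounded"}.get(res.status, "error")
            x = None if res.x is None else res.x.tolist()
            fun = None if res.fun is None else float(res.fun)
    except Exception as exc:  # pragma: no cover - defensive
        return {"status": "error", "message": str(exc)}
    return {"status": status, "x": x, "fun": fun}


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = [solve_one(p) for p in problems]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
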