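"""Independent optimal-transport oracle for the test suite.

Reads a JSON spec {"cost": [[...]], "pairs": [{"a": [...], "b": [...]}]}
and writes a JSON array of minimal transport costs, one per pair, solved
as an explicit linear program (HiGHS). Used to cross-check the package's
CDF-based 1D Wasserstein distance and its min-cost-flow EMD.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def transport_cost(cost, a, b):
    n, m = cost.shape
    c = cost.reshape(-1)
    a_eq = []
    for i in range(n):
        row = np.zeros((n, m))
        row[i, :] = 1.0
        a_eq.append(row.reshape(-1))
    for j in range(m):
        row = np.zeros((n, m))
        row[:, j] = 1.0
        a_eq.append(row.reshape(-1))
    b_eq = np.concatenate([a, b])
    res = linprog(c, A_eq=np.array(a_eq), b_eq=b_eq, bounds=(0, None),
                  method="highs")
    if not res.success:
        raise RuntimeError(res.message)
    return float(res.fun)


def main():
    spec = json.load(open(sys.argv[1]))
    cost = np.asarray(spec["cost"], dtype=float)
    out = [transport_cost(cost, np.asarray(p["a"], dtype=float),
                          np.asarray(p["b"], dtype=float))
           for p in spec["pairs"]]
    json.dump(out, open(sys.argv[2], "w"))


if __name__ == "__main__":
    main()
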