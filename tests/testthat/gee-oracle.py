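"""Independent GEE reference fits via statsmodels.

Reads a CSV with columns: dataset, patient_id, x1, x2, outcome.
Fits a binomial GEE with an exchangeable working correlation per dataset
and writes params + working correlation to the output CSV.
"""
import sys
import warnings

import numpy as np
import pandas as pd
import statsmodels.api as sm

warnings.filterwarnings("ignore")


def main(inp, outp):
    df = pd.read_csv(inp)
    rows = []
    for k, d in df.groupby("dataset", sort=True):
        X = sm.add_constant(d[["x1", "x2"]])
        try:
            model = sm.GEE(d["outcome"], X, groups=d["patient_id"],
                           family=sm.families.Binomial(),
                           cov_struct=sm.cov_struct.Exchangeable())
            r = model.fit(maxiter=500, ctol=1e-11)
            rows.append([k, *r.params.values, float(r.cov_struct.dep_params)])
        except Exception:
            rows.append([k, np.nan, np.nan, np.nan, np.nan])
    out = pd.DataFrame(rows, columns=["dataset", "b0", "b1", "b2", "rho"])
    out.to_csv(outp, index=False)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
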