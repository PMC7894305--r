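"""Independent coalescent oracle for the expected joint SFS.

Populations are simulated as haploid lineages with
2 * nu * Nref chromosomes (the diploid size nu * Nref).  Simulates replicate genealogies of a two-population piecewise-constant
demography with msprime and reports the branch-mode joint allele frequency
spectrum, averaged over replicates, scaled per unit theta = 4 Nref mu L
(i.e. divided by 4 Nref), together with Monte-Carlo standard errors.

Usage: python afs_oracle.py <spec.json> <out.json>

spec.json:
  n1, n2        haploid sample sizes
  reps          number of replicates
  seed          RNG seed
  Nref          reference diploid size (default 1000)
  anc           {"nuA": float, "TA": float}  (optional ancestral size change)
  epochs        list, oldest first, of {"T","nu1","nu2","m12","m21"}
                with T in units of 2 Nref generations and m in units of
                2 Nref m (population-scaled)
  m_factor      multiplier applied to all migration rates (island class)
"""
import json
import sys

import msprime
import numpy as np


def build_demography(spec, nref, m_factor):
    dem = msprime.Demography()
    epochs = spec["epochs"]
    newest = epochs[-1]
    dem.add_population(name="P1", initial_size=2.0 * newest["nu1"] * nref)
    dem.add_population(name="P2", initial_size=2.0 * newest["nu2"] * nref)
    anc = spec.get("anc") or {"nuA": 1.0, "TA": 0.0}
    dem.add_population(name="ANC", initial_size=2.0 * anc["nuA"] * nref)

    def mig(per2n):
        return m_factor * per2n / (2.0 * nref)

    # backwards-time rate of lineage movement P1 -> P2 equals the forwards
    # fraction of P1 replaced by migrants from P2 per generation (m12)
    dem.set_migration_rate(source="P1", dest="P2", rate=mig(newest["m12"]))
    dem.set_migration_rate(source="P2", dest="P1", rate=mig(newest["m21"]))

    # accumulate epoch boundaries newest -> oldest
    t = 0.0
    for idx in range(len(epochs) - 1, -1, -1):
        ep = epochs[idx]
        t += 2.0 * nref * ep["T"]
        if idx > 0:
            prev = epochs[idx - 1]
            dem.add_population_parameters_change(
                time=t, population="P1", initial_size=2.0 * prev["nu1"] * nref)
            dem.add_population_parameters_change(
                time=t, population="P2", initial_size=2.0 * prev["nu2"] * nref)
            dem.add_migration_rate_change(
                time=t, source="P1", dest="P2", rate=mig(prev["m12"]))
            dem.add_migration_rate_change(
                time=t, source="P2", dest="P1", rate=mig(prev["m21"]))
    dem.add_population_split(time=t, derived=["P1", "P2"], ancestral="ANC")
    if anc["TA"] > 0:
        dem.add_population_parameters_change(
            time=t + 2.0 * nref * anc["TA"], population="ANC",
            initial_size=2.0 * nref)
    dem.sort_events()
    return dem


def branch_afs_mean(spec, nref, m_factor, reps, seed):
    dem = build_demography(spec, nref, m_factor)
    n1, n2 = spec["n1"], spec["n2"]
    reps_iter = msprime.sim_ancestry(
        samples={"P1": n1, "P2": n2}, ploidy=1, demography=dem,
        sequence_length=1, num_replicates=reps, random_seed=seed)
    s = np.zeros((n1 + 1, n2 + 1))
    s2 = np.zeros_like(s)
    for ts in reps_iter:
        afs = ts.allele_frequency_spectrum(
            sample_sets=[list(range(n1)), list(range(n1, n1 + n2))],
            mode="branch", polarised=True, span_normalise=False)
        s += afs
        s2 += afs * afs
    mean = s / reps
    var = s2 / reps - mean ** 2
    se = np.sqrt(np.maximum(var, 0.0) / reps)
    return mean / (4.0 * nref), se / (4.0 * nref)


def main():
    with open(sys.argv[1]) as fh:
        spec = json.load(fh)
    nref = float(spec.get("Nref", 1000.0))
    reps = int(spec["reps"])
    seed = int(spec.get("seed", 1))
    m_factor = float(spec.get("m_factor", 1.0))
    mean, se = branch_afs_mean(spec, nref, m_factor, reps, seed)
    with open(sys.argv[2], "w") as fh:
        json.dump({"mean": mean.tolist(), "se": se.tolist(),
                   "reps": reps}, fh)


if __name__ == "__main__":
    main()
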