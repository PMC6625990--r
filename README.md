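# flextail

Integrative, desk-scale modeling of flexible protein tails attached to
rigid cores, driven by crosslinking mass spectrometry (XL-MS) distance
restraints and validated against small-angle X-ray scattering (SAXS) —
together with the binding-kinetics and thermal-stability computations that
accompany such studies.

## Who this is for

Structural biologists and method developers who want a self-contained,
fully testable implementation of the XL-MS + SAXS tail-modeling workflow:
conformational sampling of a Cα tail under flat-harmonic crosslink
restraints, Debye-equation SAXS profiles with Guinier and χ² fitting, an
energy/χ²/held-out-crosslink selection cascade with RMSD leader
clustering, and structural metrics (Shrake–Rupley SASA, interface burial,
RMSF). A synthetic-data module generates every input class with known
ground truth, so the entire pipeline is exercised end to end without any
downloads.

## The core model

A crosslink between residues *i* and *j* restrains their Cα distance *d*
by a flat-harmonic penalty

    f(d) = 0                                   if d <= x0 + tol
    f(d) = ((d - x0 - tol) / sigma)^2          otherwise

with defaults x0 = 15 Å, tol = 15 Å, σ = 1 — i.e. a free window up to
30 Å, the DSS threshold: the 11.4 Å spacer plus two 6.4 Å lysine side
chains give a ~24 Å geometric cap, widened to 30 Å for dynamics. Tail
conformations are sampled by two-stage Monte-Carlo pivot moves (annealed
collapse, then refinement and minimization) under clash + screened
electrostatics + restraint energy; models are then filtered by energy
rank, SAXS χ² (analytic scale, 1/(N−1) normalization), and held-out
crosslink satisfaction, clustered by tail RMSD after core superposition,
and reduced to per-cluster lowest-energy representatives.

## Worked example

```r
library(flextail)

# 1:1 binding kinetics at published-scale rates
rc <- combine_kinetics(k_a = 1.3e5, k_d = 0.031)
print(rc)
#> k_a = 1.3e+05 /M/s, k_d = 0.031 /s, K_D = 2.38e-07 M (0.24 uM)

# DSS crosslinker geometry
max_linker_distance(linker_geometry())
#> [1] 24.2

# end-to-end synthetic benchmark: simulate a truth tail + 4 crosslinks,
# sample 200 models, select by energy/chi2/held-out link, cluster
b <- run_benchmark(seed = 1, n_models = 200)
print(b)
#> synthetic benchmark: 200 models -> cascade 100 -> 28 -> 24 -> 7 clusters
#>   representative model 60: tail RMSD to truth 14.14 A (ensemble 25th pct 20.18 A) -> enriched
```

The benchmark line reads: of 200 sampled models, 100 survive the energy
stage, 28 the χ² < 2 stage and 24 the held-out-crosslink stage; the
representative of the largest cluster sits at 14.1 Å tail-RMSD to the
known truth, inside the best quartile of the whole ensemble (20.2 Å), so
selection enriched truth-like models.

Crosslink satisfaction reporting on any model + link table:

```r
sys <- benchmark_system()
xl  <- simulate_crosslinks(sys, n_true = 4, n_decoy = 0, seed = 2)
satisfaction(sys$tail_truth, xl, threshold = 30)
#> crosslink satisfaction: 4/4 links < 30 A (fraction 1.000)
```

Command-line wrappers for the crosslink tools are installed under
`exec/`: `xl-report --model m.pdb --links l.csv --threshold 30` and
`xl-fdr --matches matches.csv --copies 10 --fdr 0.05`.

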