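---
title: "Integrative modeling of flexible protein tails with flextail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative modeling of flexible protein tails with flextail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flextail)
```

## The problem

Many proteins carry terminal regions that are invisible in crystal
structures because they are flexible, yet are functionally essential — for
example a charged C-terminal tail that folds back onto a basic surface
patch of an armadillo-repeat core and stabilizes it. Such regions can be
modeled by combining three information sources:

* **Crosslinking mass spectrometry (XL-MS).** A lysine-reactive
  crosslinker of known spacer length (DSS, 11.4 Å) bridges residue pairs
  that come close in solution. Geometrically, the spacer plus two lysine
  side chains (6.4 Å each) caps the Cα–Cα separation at ~24 Å; allowing
  for protein dynamics, identified pairs impose an upper-bound restraint
  of 30 Å.
* **Small-angle X-ray scattering (SAXS).** A solution scattering curve
  `I(q)` constrains the global shape; candidate models are scored by the
  discrepancy χ² between their theoretical profile and the experiment.
* **Conformational sampling under an energy model.** Tail conformations
  are generated by two-stage Monte-Carlo sampling (a hot, coarse collapse
  stage followed by refinement and minimization) with the crosslink
  restraints applied as flat-harmonic penalties.

`flextail` implements this workflow at desk scale: Cα-resolution sampling,
restraint mathematics, SAXS computation and fitting, a
selection cascade with clustering, structural metrics (SASA, interface
burial, RMSF), and the binding/thermal kinetics computations that
typically accompany such a study (biolayer-interferometry 1:1 kinetics,
steady-state binding, thermal melts, one-phase association).

## The restraint model

A crosslink between residues *i* and *j* contributes

$$f(d) = \begin{cases} 0 & d \le x_0 + \mathrm{tol} \\
\left(\frac{d - x_0 - \mathrm{tol}}{\sigma}\right)^2 & \text{otherwise}
\end{cases}$$

with defaults $x_0 = 15$ Å, tol $= 15$ Å, $\sigma = 1$, i.e. zero penalty
up to 30 Å and a quadratic wall beyond. Only the upper bound is enforced:
with these parameters the window reaches down to 0 Å, so a lower-bound
branch would never activate; we implement the one-sided rule explicitly.

```{r}
flat_harmonic(c(10, 30, 32), flat_harmonic_params())
max_linker_distance(linker_geometry())   # DSS + 2 lysines
```

## The sampling energy

Production studies use a full atomic force field; at Cα resolution we use
a documented coarse-grained surrogate with three terms
(see `energy_weights()`):

* soft-sphere clash: $\sum_{d_{ij} < d_\mathrm{min},\ |i-j|>1}
  (d_\mathrm{min} - d_{ij})^2$ with $d_\mathrm{min} = 4$ Å;
* screened electrostatics between charged residue classes (+1 Arg/Lys,
  −1 Asp/Glu): $\sum q_i q_j e^{-d_{ij}/\lambda}/d_{ij}$ with screening
  length $\lambda = 10$ Å, a Debye–Hückel form at roughly physiological
  ionic strength;
* the flat-harmonic crosslink restraints.

The selection cascade treats the energy purely as a sortable score, so
this substitution is architectural rather than an attempt at numerical
mimicry of any particular force field. Weights default to 1 each; the
terms are of comparable magnitude on the packaged synthetic system.

Moves are **pivot rotations**: a random tail residue is chosen and
everything downstream rotates rigidly about its Cα by a random angle
about a random axis. Pivots preserve virtual bond lengths (3.8 Å) exactly
by construction and never move the core. Helical segments are excluded
from internal pivoting, so they move as rigid bodies. Stage 1
(default 2000 steps, ±60°) runs Metropolis acceptance under geometric
cooling from T = 5 to T = 0.2 (dimensionless, matching the energy scale);
stage 2 (default 1000 steps, ±10°) refines at the final temperature and
ends with greedy per-pivot golden-section line-search minimization. Each
model *m* uses seed `base_seed + m`, making every model independently
reproducible.

## The synthetic data generator

All tests and the acceptance benchmark run on synthetic systems with
known ground truth, generated by the package itself:

* `build_core()` — a Cα-only solenoid of 32-residue repeats (an
  8-residue h1 helix perpendicular to a 12+12 antiparallel hairpin),
  stacked along a right-handed superhelical path with ideal helix
  geometry (1.5 Å rise, 100°/residue) and exact 3.8 Å virtual bonds. The
  default 8 repeats give a 256-residue core. Every 6th residue is a
  designated lysine-surrogate crosslinking site; the four surrogates
  nearest the chain C-terminus form a spatially compact charged basic
  patch (the only charged core residues). Compactness matters: a
  coherent patch gives the electrostatic term a single well-defined
  docking site, whereas a diffuse ring of charges admits many degenerate
  docking poses and would make cluster-based selection arbitrary.
* `attach_truth_tail()` — grows a 30-residue charged tail (acidic
  stretch EDEDTDTDE-like in its first half) with clash avoidance,
  biased so the acidic stretch docks on the basic patch (centroids
  within 12 Å), then settles the conformation into a nearby local
  minimum of the clash+electrostatics energy. The relaxation step makes
  the recorded truth consistent with the sampling energy, as a native
  conformation at equilibrium would be; without it, energy ranking
  would systematically prefer non-truth-like arrangements and the
  selection logic could not be tested meaningfully.
* `simulate_crosslinks()` — true links are sampled among surrogate pairs
  within 24 Å in the truth that bridge core and tail, greedily spread
  over distinct tail sites (real crosslink sets report several different
  lysines; links within a disordered tail carry almost no positional
  information). Decoys are pairs beyond 40 Å. Scores are Uniform(20,40)
  for targets and Uniform(0,20) for decoys — disjoint by default.
* `simulate_saxs()`, `simulate_bli()`, `simulate_melt()` — observables
  with multiplicative SAXS noise (σ = 2% of I by default; the error
  model of real beamlines varies, and a multiplicative form keeps χ²
  scale-invariant), 1:1 binding traces with
  `k_obs = k_a C + k_d`, and Boltzmann-sigmoid melts.

What the generator does **not** emulate: side chains and atomic packing,
hydration-shell scattering contrast, inter-particle interference or
radiation damage in SAXS, mass-spectrometric score distributions of real
search engines, and instrument drift beyond a linear baseline. Passing
tests therefore demonstrate the correctness of the pipeline's logic and
numerics, not the accuracy of any particular force field or the quality
of real experimental data.

## The selection cascade

```{r, eval = FALSE}
cfg <- cascade_config(top_n_energy = 500, chi_cutoff = 2.0,
                      heldout_links = held, link_threshold = 30,
                      rmsd_cutoff = 2.5, min_cluster_size = 14,
                      top_k_energy = 10)
surv <- filter_cascade(entries, cfg)
cl   <- rmsd_cluster(surv$survivors, cfg, align_subset = core,
                     cluster_subset = tail)
reps <- select_representatives(cl, surv$survivors, cfg)
```

Stage A keeps the best `top_n_energy` models by energy (ties broken by
model id, for full determinism); stage B keeps models with χ² below the
cutoff; stage C keeps models whose *held-out* crosslinks — links withheld
from sampling — fall under the distance threshold. Survivors are
clustered by leader clustering: models are visited in ascending-energy
order and join the first cluster whose leader is within the RMSD cutoff
(measured on the tail after superposition on the rigid core), else found
a new cluster. Clusters smaller than `min_cluster_size` that contain no
top-`top_k_energy` model are rejected as minor; each retained cluster is
represented by its lowest-energy member. Leader clustering with
energy-ordered seeding is our documented stand-in for the various
clustering tools used in production studies, which rarely print their
algorithms; the cutoff semantics match the usual 2.5 Å usage.

## SAXS numerics

`debye_profile()` evaluates the Debye equation
$I(q) = \sum_{ij} f_i f_j \sin(q d_{ij})/(q d_{ij})$ with constant
per-residue weights in Cα mode (default 60 effective electrons — roughly
an average residue). There is no hydration shell or excluded-volume term,
so absolute χ² values against real deposited curves are approximated, not
reproduced; χ² comparisons *within* one model ensemble, which is what the
cascade uses, are unaffected. `guinier()` iterates the classic
$\ln I$ vs $q^2$ fit, shrinking the window to $qR_g < 1.3$ until the
estimate is stable; for strongly elongated particles the usual low-q
truncation bias (a few per cent underestimate) applies, which is why
recovery checks use globular test particles. `chi_square()` uses the
analytic scale $c = \sum I_e I_m/\sigma^2 \big/ \sum I_m^2/\sigma^2$ and
the $1/(N-1)$ normalization. `multistate_fit()` enumerates all candidate
subsets up to three states (pool capped at 50 for desk-scale runtime) and
solves each weight problem by non-negative least squares.

## The end-to-end benchmark

`run_benchmark()` wires everything together on the packaged synthetic
system: 4 true crosslinks are simulated, three drive sampling and the
fourth is held out for selection; 200 models are sampled from an extended
(undocked) start with the standard two-stage schedule; models are
scored against the noiseless truth SAXS curve carrying a nominal 5%
uncertainty band (χ² requires a finite weighting scale; 5% places the
χ² < 2 stage in a regime where it retains the best-fitting minority);
the cascade, clustering (15 Å tail cutoff — between-model tail RMSDs on
a 30-residue coil are an order of magnitude larger than for the
near-rigid production case, so the production 2.5 Å cutoff would place
every model in its own cluster) and representative selection follow. The
benchmark reports whether the representative of the largest retained
cluster lies within the best quartile of tail-RMSD to truth — i.e.
whether selection *enriches* truth-like models relative to the raw
ensemble.

```{r, eval = FALSE}
b <- run_benchmark(seed = 1, n_models = 200)
print(b)
```

## Kinetics and thermal analyses

The binding computations follow the standard 1:1 model. Dissociation
phases are fit as $R_0 e^{-k_d t}$ plus a free plateau; association
phases as $R_\mathrm{eq}(1 - e^{-k_\mathrm{obs} t})$ plus a free
baseline, with $k_a = (k_\mathrm{obs} - k_d)/C$. Commercial analysis
software leaves such details (offsets, weighting) unprinted; we use
unweighted least squares with the free offsets above. Replicates combine
as the mean of individual rates, with
$K_D = \overline{k_d}/\overline{k_a}$ — the printed convention — rather
than averaging per-trace ratios. Melting temperatures are reported both
from a Savitzky–Golay (window 5, quadratic) smoothed derivative maximum
with parabolic peak interpolation, and from a Boltzmann sigmoid fit; the
sigmoid is the headline value for noise robustness. Steady-state binding
uses the one-site hyperbola; when responses are effectively linear in
concentration the fit is flagged (`low_curvature`) and $K_D$ reported as
unbounded rather than a spurious number.

## Numerical choices and degenerate inputs

* Residue addressing is 1-based author numbering everywhere; gaps are
  allowed (disordered loops in deposited structures).
* PDB parsing keeps altloc 'A' or blank and rejects insertion codes;
  multi-model files keep the first model with a warning.
* SAXS rows with σ ≤ 0 are dropped with a warning; unsorted q is sorted.
* Ties in energy are always broken by ascending model id.
* `superpose()` enforces a proper rotation (det = +1), so mirror images
  superpose with positive residual RMSD; collinear point sets are
  rejected.
* SASA uses Shrake–Rupley quadrature with a golden-spiral point set
  (960 points, probe 1.4 Å; Cα-mode pseudo-residue radius 3.0 Å). The
  radii table is a documented convention: interface areas computed by
  different servers and radii sets spread by several per cent.
* RMSF aligns frames to an iteratively refined Procrustes mean, making
  the profile independent of frame order.
* Truth-tail growth retries from fresh sub-seeds (bounded) and errors
  with advice to change the seed if the docking post-condition cannot be
  met.

## Known limitations

Cα resolution throughout the synthetic path (all-atom input is accepted
by the readers and by SASA/interface/RMSF); no hydration-shell SAXS
modeling; the coarse-grained energy is a surrogate, so absolute energies
are not comparable to force-field scores; Guinier estimates on strongly
elongated particles carry the standard truncation bias; the enumeration
bound of 50 candidates in multi-state fitting.

## Problem sizes used in tests

The test-suite runs the full benchmark at 200 models x 10 seeds with the
default 2000+1000-step schedule, parameter-recovery checks at 40-200 stochastic
replicates, and Boltzmann/uniform-sampling oracles at a few hundred to a
few tens of thousands of draws — sizes at which the stochastic
tolerances asserted in the tests are comfortably stable.
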