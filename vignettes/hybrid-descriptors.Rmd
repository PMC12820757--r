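---
title: "Hybrid quantum-mechanical descriptors: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantum-mechanical descriptors: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantdesc)
```

This vignette is the package's own account of the methods it implements: the
representations, the two regression engines, the curation and attribution
tooling, the synthetic-data generator that stands in for real datasets, and
the numerical and design choices made where more than one defensible option
existed.

## Units and conventions

All user-facing quantities use one fixed internal convention: coordinates in
Angstrom, energies in eV, dipoles in e·Å, polarizabilities in Bohr³
(a₀³). Parsers convert at read time (`1 Hartree = 27.211386245988 eV`,
`1 e·Bohr = 0.529177210903 e·Å`, `1 kcal/mol = 0.0433641 eV`). The one
deliberate exception: Coulomb-matrix and Bag-of-Bonds distances are in Bohr,
because that is the descriptor's original convention and changes only a
global scale.

## Geometric representations

**Coulomb matrix.** `M_ii = 0.5 Z_i^2.4`, `M_ij = Z_i Z_j / r_ij` (Bohr).
Its eigenvalue multiset is rotation/translation invariant; the matrix itself
is not permutation invariant, which motivates bagging.

**Bag-of-Bonds.** One bag per element (diagonal entries) and per unordered
element pair (off-diagonal entries), each sorted descending and zero-padded
to the dataset-wide maximum count, concatenated in canonical (Z, then
(Z,Z')) order. The layout (`fit_bag_spec()`) is a deterministic function of
the dataset; every molecule maps to one fixed-length vector, invariant to
atom permutation and rigid motion. Same-element pairs are counted once
(i < j).

**SLATM (molecule-level).** Three blocks under one `slatm_spec()`:

- one-body: atom count × Z per universe element;
- two-body, per unordered element pair:
  `S2(r) = Σ_{i<j} Z_i Z_j r_ij⁻⁶ N(r; r_ij, σ₂) Δr` on a radial grid —
  a London-dispersion-weighted distance spectrum;
- three-body, per (center element, unordered neighbor-element pair) bag:
  `S3(θ) = Σ Z_i Z_j Z_k (1 + 3 cos θ_i cos θ_j cos θ_k) / (r_ij r_ik r_jk)³
  N(θ; θ_i, σ₃) Δθ` — the Axilrod–Teller–Muto triple-dipole weight, with
  θ_i the angle at the center atom, each geometric triple counted once per
  center, and both center legs within the cutoff.

Grid defaults: r ∈ [0.8, 4.8] Å, Δr = 0.03 Å, σ₂ = 0.05 Å; θ ∈ [0, π],
Δθ = 0.03 rad, σ₃ = 0.05 rad; three-body cutoff 4.8 Å. These follow the
descriptor's reference-implementation conventions; the exact grid is not
canonical in the literature, so this package's formula (normal density ×
grid step, i.e. a Riemann sum of a smeared spectrum) is stated explicitly
and is the normative dialect for all tests. The Gaussian smearing makes the
vector smooth in the coordinates — perturbing one atom by 1e-4 Å moves the
vector by a relative ~1e-3, with no grid-boundary discontinuities — which
kernel methods need.

## The electronic descriptor

`build_dqm()` assembles, in fixed order:

1. **global** (10): Fermi energy, band energy, electron count, reference
   density energy E_H0, self-consistent-charge energy E_scc, third-order
   correction E_3rd, repulsion energy E_rep, many-body dispersion energy
   E_mbd, dipole norm ‖µ_TB‖, HOMO–LUMO gap;
2. **eMO** (8 by default): frontier orbital eigenvalues. The source material
   for this layout fixes only the dimension (8), not which orbitals; we take
   the 4 highest occupied plus 4 lowest unoccupied, ascending, a window
   symmetric around the gap so that entries 4/5 bracket the HOMO–LUMO gap
   exactly. Both window sizes are configurable.
3. **atom** (n_max): Mulliken charges in input atom order, zero-padded to
   the largest molecule in the dataset. Raw atom order breaks permutation
   invariance; an optional canonical ordering (by Z, then charge) is
   provided, off by default because zero-padding semantics imply the raw
   order.

**Scaling policy.** Whether features were standardized before kernel
evaluation is not something the descriptor definitions fix. The package
default z-scores D_QM (its components span eV, electron counts and
elementary charges — heterogeneous units on very different scales) and
leaves geometric blocks raw (their entries are already on one physical
scale, and L1 kernel distances over thousands of grid points are the signal
itself). Both choices are per-experiment configurable via
`standardize_block()`; scalers are fitted on training rows only, constant
features map to 0, and the transform inverts to 1e-10.

## Kernel ridge regression

`krr()` solves `(K + λI) α = y` by Cholesky, with up to five steps of
iterative refinement; every fit must meet
`‖(K + λI)α − y‖∞ ≤ 1e-8 ‖y‖∞` or it aborts advising a larger λ. Laplacian
and Gaussian kernels only; both satisfy k(x,x) = 1.

`krr_optimize()` implements joint split/hyperparameter selection: for each
of `n_splits` seeded random train/validation splits, L-BFGS-B minimizes the
**validation MAE** over (log10 σ, log10 λ) in the box [-2, 6] × [-12, 0]
from three starting points (a median-heuristic anchor plus two seeded
random starts); the winner across splits is refit on its training split.
Numerical choices worth noting:

- the objective is MAE, matching how models here are reported;
- hyperparameter candidates whose dual solve cannot meet the residual
  invariant (near-singular K at tiny λ and huge σ) are treated as
  infeasible (a large penalty), so the optimizer cannot converge to a model
  the fitter would reject;
- the final refit uses the winning training split *only* — not
  train+validation — so the reported validation MAE remains an honest
  estimate. Refitting on train+val might squeeze out a little accuracy but
  silently biases the number used for selection; we chose honesty.
- distances are precomputed once per split; σ enters only through the
  exponential, so the optimization loop is exact, not approximated.

`delta_krr()` trains on `y_target − y_baseline` and adds the baseline back
at prediction. The correction is mean-centered before the kernel fit (kernel
machines have no intercept; without centering even a constant offset is only
approximated), so constant-shift recovery is exact.

## Second-order gradient boosting

The reference learner (`gbt()`) is a from-scratch implementation of
second-order boosting for squared error with the ½ convention: gradients
`g = ŷ − y`, Hessians `h = 1`. Trees are grown by exact greedy search over
all features and all midpoints between consecutive distinct values; a node
splits only if `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ)] − γ`
is strictly positive; leaves take the closed-form weight `−G/(H+λ)`.
Ties in gain resolve to the first candidate in (feature, threshold) order,
making trees fully deterministic. The test suite proves the grower identical
(structure, gains, weights) to an independent brute-force enumerator, and
checks agreement with a production boosting library on toy cases — that
library serves as a cross-check, never as the engine.

`fps_select()` is greedy max-min (farthest point) sampling with
lowest-index tie-breaks; the default seed point is the medoid, a
deterministic and scale-free choice. `tune_boost()` is a seeded sequential
random search scored by mean 5-fold CV negative RMSE; the trial sequence
depends only on the seed, so extending `trials` extends the same sequence
and can only improve the returned best. The published default space
(η log-uniform [0.01, 0.3], depth 3–10, 100–1000 rounds, λ log-uniform
[1e-3, 10], γ ∈ [0, 5]) lives in `default_boost_space()` as data, not code.
A Bayesian optimizer would find good regions in fewer trials; the seeded
random search was chosen for exact reproducibility and zero dependencies,
and is a stated stand-in.

## Conformer curation

`kabsch_rmsd()` superposes by SVD with the determinant sign fix (proper
rotations only: a chiral structure and its mirror image are *not* treated as
congruent). Atom correspondence is positional — no graph matching.
Admission (`admit_ensemble()`) keeps conformers within 12.0 kcal/mol of the
reference energy *and* at least 0.1 Å RMSD from the reference (the
reference itself always stays); both thresholds are config.
`cluster_conformers()` runs average-linkage agglomeration on the pairwise
RMSD matrix, cuts at a configurable height (default 1.0 Å), and keeps the
lowest-energy member per cluster. Average linkage and lowest-energy
representatives are our choices — the linkage and representative rule are
not fixed by the procedure being emulated, and the cut height that produced
published ensemble counts on external data is not stated there, so those
counts are not reproduction targets. Hydrogens are included in RMSD by
default (toggle provided).

## Evaluation and attribution

`regression_metrics()` reports MAE, RMSE, R² = 1 − SS_res/SS_tot, and the
residual vector with the fixed convention **residual = prediction − true**.
R² on zero-variance truth is flagged undefined rather than fabricated.
`learning_curve()` holds out one fixed seeded test set and nests the
training subsets (smaller ⊂ larger), so points along the curve differ only
in training data.

`exact_shapley()` computes interventional Shapley values by full coalition
enumeration (d ≤ 15): the value of a coalition is the mean prediction over
background rows with out-of-coalition features replaced by background
values. Enumeration guarantees local accuracy (Σφ + baseline = f(x)) and
symmetry to machine precision, and serves as the package's own oracle; the
linear-game closed form `φ_j = a_j (x_j − mean background_j)` is verified in
tests. The interventional (background-replacement) value function was
chosen over tree-path-dependent expectations because it is model-agnostic
and exactly enumerable; no delegated fast explainer backend ships, so
requests beyond 15 features error with guidance instead of silently
switching semantics.

## The synthetic-data generator

`gen_toy_molecules()` draws random compositions over a palette (default
H/C/N/O, 3–8 atoms) and rejection-samples coordinates in a size-scaled box
with a 0.8 Å minimum separation. These are geometric point clouds, not
chemically bonded structures: they exercise every invariance, bagging and
spectrum code path, but carry no bond-length statistics or conformational
physics. Passing tests on them demonstrates correctness of the machinery,
not chemical accuracy on real molecules.

`gen_mock_qm()` emits internally consistent records: the stated gap equals
the eigenvalue gap, Mulliken charges sum to zero, and energy components are
size-extensive (linear in atom count plus noise). The two headline
calibrations — Pearson ρ = 0.94 between mock ‖µ_TB‖ and the hidden
reference dipole, ρ = −0.61 between mock E_mbd and the hidden reference
polarizability, matching the correlation structure tight-binding properties
show against high-level reference labels — are imposed by construction: the
mock quantity is linear in the hidden reference plus independent Gaussian
noise, with the loading set from the target ρ (a degenerate Gaussian
copula). Because the relation is linear with independent noise, the
population Pearson correlation equals the calibration exactly under any
reference marginal, and sample correlations at n = 5000 sit within a few
thousandths of it. Marginals are placed so dipole norms are positive in
practice (the guard at 0 triggers with probability ~3e-5 and was never
observed at n = 5000). The hidden references play the role of high-fidelity
labels and are documented as synthetic stand-ins, never as physics.

`gen_targets()` produces regression targets from a disclosed generative
model (coefficients returned), including a mixed kind drawing signal from
both a geometric and an electronic column subset — the harness behind the
hybrid-benefit test: a model seeing only geometry cannot explain the
electronic component, so SLATM⊕D_QM beats pure SLATM at fixed seed.

## Problem sizes and determinism

The test suite runs entirely on synthetic data at desk scale: invariance
sweeps use 50 molecules × 10 random rigid motions/permutations; KRR
recovery uses 200 rows; tree-oracle comparisons use 25 datasets of ≤ 20 × 3;
the hybrid-benefit experiment uses 240 molecules with a 150/50/40
train/val/test partition; generator calibrations are measured at n = 5000.
Every stochastic step is seeded, and seeded runs are bit-reproducible
(archives compare byte-identical). JSON serialization writes 17 significant
digits, so model and dataset round trips are exact.

## Known limitations

- No electronic-structure engine is included or shelled out to: records
  come from parsing existing output files or from the mock generator.
- SLATM is molecule-level only; the atomic/local variant is out of scope.
- The boosted learner omits row/column subsampling, histogram splits and
  classification losses — it is a reference implementation tuned for
  verifiability, not large-scale speed.
- Exact Shapley is exponential by design; beyond 15 features you must
  explain feature subsets.
- Kabsch RMSD assumes positional atom correspondence; symmetry-aware
  matching (e.g. for permutable hydrogens) is not performed.
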