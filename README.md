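# quantdesc

Hybrid quantum-mechanical molecular descriptors for property regression.

## What this package is for

Predicting molecular properties — physicochemical ones like the dipole moment
µ, polarizability α, atomization energy E_AT and HOMO–LUMO gap, or biological
endpoints like acute toxicity (LD50) and lipophilicity (logD) — from 3D
structures is usually done with *geometric* descriptors. Those capture atom
types and interatomic distances/angles but miss electronic structure. This
package builds **hybrid representations** that concatenate cheap geometric
descriptors with an **electronic descriptor** assembled from semi-empirical
tight-binding output, and trains two regression engines on them. It is aimed
at cheminformatics practitioners who have XYZ geometries and tight-binding
results files and want interpretable, desk-scale property models.

The building blocks:

- **Coulomb matrix (CM)** — `M_ii = 0.5 Z_i^2.4`, `M_ij = Z_i Z_j / r_ij`
  (distances in Bohr).
- **Bag-of-Bonds (BOB)** — CM entries sorted into fixed-length, zero-padded
  per-pair-type bags, giving a permutation- and rotation-invariant vector.
- **SLATM** — one-body element counts, London-weighted (`r^-6`) two-body
  radial spectra, and Axilrod–Teller–Muto-weighted three-body angular
  spectra, Gaussian-smeared on fixed grids.
- **D_QM** — the electronic block: 10 global tight-binding quantities
  (Fermi energy, band energy, electron count, five energy components
  including the many-body dispersion energy E_mbd, the dipole norm ‖µ_TB‖,
  and the HOMO–LUMO gap), 8 frontier orbital eigenvalues, and per-atom
  Mulliken charges zero-padded to the largest molecule.
- **Kernel ridge regression (KRR)** — `ŷ(x) = Σ_i α_i k(x, x_i)` with
  Laplacian `exp(-‖x-x'‖₁/σ)` or Gaussian `exp(-‖x-x'‖₂²/2σ²)` kernels and
  `α = (K + λI)⁻¹ y`; (σ, λ) and the train/validation split are optimized
  jointly (L-BFGS-B over log10 σ, log10 λ across seeded random splits).
- **Second-order gradient-boosted trees** — exact greedy splits maximizing
  `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ)] − γ` with leaf
  weights `−G/(H+λ)`, plus farthest point sampling and seeded
  cross-validated tuning.
- Support tooling: conformer curation (Kabsch RMSD, energy/RMSD admission
  windows, RMSD hierarchical clustering), delta learning, learning curves,
  residual reports, and exact (enumerative) Shapley feature attribution.

A synthetic-data module generates toy molecules and mock tight-binding
records with calibrated correlation structure, so the entire pipeline runs
and is tested without any external dataset or electronic-structure program.

## Worked example

Generate a synthetic dataset, build BOB and D_QM blocks, and compare a
geometry-only model against the hybrid on the hidden reference dipole:

```r
library(quantdesc)

mols <- gen_toy_molecules(300, mock_spec(), seed = 11)
mock <- gen_mock_qm(mols, mock_spec(), seed = 12)
ds   <- qd_dataset(mols, mock$records)

space <- fit_descriptor_space(ds)
bob <- geometry_block(ds, space$bag)
dqm <- standardize_block(dqm_block(ds))
hyb <- concat_blocks(bob, dqm)
print(hyb)
#> <descriptor block BOB+DQM> 300 x 157

y <- mock$references$mu   # hidden reference dipole, eA
cfg <- krr_config(n_train = 180, n_val = 60, n_splits = 2, seed = 1,
                  kernel = "laplacian")
fit_bob <- krr_optimize(bob$matrix, y, cfg)
fit_hyb <- krr_optimize(hyb$matrix, y, cfg)
print(fit_hyb)
#> KRR split/hyperparameter optimization (2 splits, laplacian kernel)
#>   winner: split 1, sigma = 1368, lambda = 0.0001812, val MAE = 0.2365

held <- fit_bob$test_idx
regression_metrics(y[held], predict(fit_bob, bob$matrix[held, ]))$MAE
#> [1] 0.5754153
ev <- regression_metrics(y[held], predict(fit_hyb, hyb$matrix[held, ]))
c(ev$MAE, ev$R2)
#> [1] 0.2927752 0.7004184
```

The geometry-only model cannot see the electronic degrees of freedom that
drive the synthetic dipole, so its held-out MAE (0.58 eÅ) is roughly the
spread of the target; adding the electronic block halves the error
(0.29 eÅ, R² = 0.70). The same workflow applies to real data: read
geometries with `read_xyz()`, parse tight-binding output with
`parse_tb_results()`, attach targets with `property_table()`, and persist
everything with `save_dataset()` / `load_dataset()`.

A thin command-line wrapper over these functions ships in
`inst/scripts/qdesc-cli.R` (subcommands `make-fixtures`, `curate`,
`train-krr`, `learning-curve`).

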