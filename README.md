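# mdbind

Post-simulation inference for binding-affinity differences between variants
of a biomolecular complex — for example a natural T-cell receptor (TCR) and
an affinity-engineered point mutant, each bound to the same peptide–MHC —
from molecular-dynamics trajectory ensembles. The package does not run MD;
it implements the full analysis stack that turns simulated ensembles into
an energetic and dynamic rationale for an affinity change:

- **Stability & flexibility** — RMSD after optimal (Kabsch) superposition,
  block-averaged per-residue RMSF, mass-weighted radius of gyration,
  geometric hydrogen-bond counts, residue-pair distance distributions and
  contact occupancies, with a discard-equilibration convention (default:
  the first 200 ns of every replica is excluded from averages).
- **MM/PBSA-style energetics** — for groups A (receptor) and B (ligand),
  every term is ΔE = E(complex) − E(A) − E(B):
  short-range Coulomb `f·qᵢqⱼ/r` and Lennard-Jones
  `4ε[(σ/r)¹² − (σ/r)⁶]` sums within a 1.2 nm cutoff (ΔE_SR), a cutoff-free
  full-range variant (ΔE_Coul/LJ), an apolar solvation term
  γ·SAS + b (γ = 0.00542·4.184·100 kJ/mol/nm², b = 0.92·4.184 kJ/mol) on
  Shrake–Rupley accessible areas, and a polar solvation term from a built-in
  finite-difference linearized Poisson–Boltzmann solver (harmonic-mean face
  dielectrics, Debye–Hückel boundary, SOR). Residue-pairwise energies are
  gated by a 6 Å any-frame contact rule; replica means are reported with the
  standard deviation of the mean σ_μ.
- **Correlation networks & allosteric paths** — generalized correlation
  r_MI = √(1 − e^(−2I/3)) from a Kraskov k-nearest-neighbour mutual
  information estimator on Cα displacement vectors, filtered by a
  5 Å / 70%-occupancy contact map, edge weights −log₁₀ r_MI, and Dijkstra
  shortest paths with deterministic (lexicographic) tie-breaking.
- **Entropy & free energy** — Schlitter configurational entropy
  S = (k_B/2) ln det[1 + (k_B T e²/ħ²) M^½ C M^½] with the binding-entropy
  cycle −TΔΔS_b, and work-based ΔG estimation from forward/backward
  nonequilibrium work sets via the Bennett acceptance ratio (BAR) or the
  Crooks Gaussian intersection (CGI), combined into
  ΔΔG_b = ΔG_mut(complex) − ΔG_mut(receptor).
- **Synthetic data with planted truth** — Gaussian ensembles with planted
  correlations, harmonic wells with analytic covariance, parent/mutant toy
  complexes with a controllable interfacial salt bridge, planted allosteric
  paths, and Crooks-consistent Gaussian work sets, so that every stage is
  testable against closed forms without external data.

Input structures are standard PDB files (single- or multi-model, read
through bio3d); binary trajectory formats plug in through a documented
array-based adapter (`as_trajectory()`). Internal units are nm, ps, kJ/mol,
elementary charges and amu.

## Worked example

```r
library(mdbind)

## 1. synthetic parent/engineered complex pair with a planted salt bridge
tc <- gen_toy_complex(toy_complex_spec(n_frames = 100, seed = 1))

## 2. MM/PBSA-style interaction energy summary (PB term skipped here)
mmpbsa_summary(tc$mutant$trajectory, "receptor", "ligand", pb = NULL)
#> <energy_summary> Delta terms, kJ/mol (sigma_mu in parentheses)
#>   E_SR             -438.080   [n=100]
#>   E_CoulLJ_full    -348.949   [n=100]
#>   E_solv_polar           NA   [n=0]
#>   E_solv_apolar      -5.078   [n=100]

## 3. contact-gated residue-pair energies (6 A any-frame rule)
gates <- anyframe_contact_pairs(tc$mutant$trajectory, "receptor", "ligand")
pair_energy_series(tc$mutant$trajectory, gates)
#> # A tibble: 6 x 7
#>   res_a res_b label_a label_b coulomb      lj   total
#> 1     1    26 R:BEA1  L:BEA26 -397.   -0.332  -397.
#> 2     2    26 R:BEA2  L:BEA26   45.8  -0.0297   45.8
#> ...

## 4. allosteric-path recovery on a planted-correlation system
gp <- gen_planted_path(10, path = c(1, 4, 7, 10), rho_on = 0.9,
                       rho_off = 0.1, n_frames = 5000, seed = 2)
cp <- correlation_pipeline(gp$trajectory)
g  <- build_graph(cp$average, occupancy_contact_map(gp$trajectory))
paths <- shortest_paths_corr(g, "S:BEA1", "S:BEA10")
paths$path[[1]]
#> [1] "S:BEA1"  "S:BEA4"  "S:BEA7"  "S:BEA10"
tidy(paths)$total_weight
#> [1] 0.559

## 5. work-based free energies: two legs of the thermodynamic cycle
complex_leg  <- bar_delta_g(gen_work_sets(-10, 2, n_forward = 300,
                                          n_backward = 300, seed = 3))
isolated_leg <- bar_delta_g(gen_work_sets(-6, 2, n_forward = 300,
                                          n_backward = 300, seed = 4))
ddg_cycle(complex_leg, isolated_leg)
#> <free_energy_cycle> DDG_b = -3.970 +/- 0.115 kJ/mol
#>   complex leg  -9.936, isolated leg -5.966 kJ/mol
```

The energy summary shows the engineered (mutant) toy complex binding more
strongly through its short-range term; the pair table attributes nearly all
of it to the planted salt-bridge pair `R:BEA1--L:BEA26`; the recovered path
is exactly the planted residue chain; and the two alchemical legs combine
to the planted ΔΔG_b = −4 kJ/mol within the bootstrap uncertainty.

A full multi-stage run over a config (flexibility → energetics →
correlation/network → entropy → ΔΔG, with per-stage seeds and delimited
reports) goes through `run_config()` / `run_pipeline()` / `write_report()`;
see the methods vignette (`vignettes/methods.Rmd`).

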