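---
title: "Methods: binding energetics, correlation networks and free-energy analysis in mdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding energetics, correlation networks and free-energy analysis in mdbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mdbind implements the analysis layer that sits on top of molecular-dynamics
simulations of a two-component complex — typically a receptor variant pair
(e.g. a natural and an affinity-engineered TCR) bound to a common partner
(e.g. a peptide–MHC). This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## Containers and conventions

A `topology` holds the ordered atom table (names, elements, masses,
charges, Lennard-Jones σ/ε), the derived residue table and named groups;
a `trajectory_ensemble` holds one or more replicas of time-stamped frames.
Internal units are fixed project-wide: nm, ps, kJ/mol, elementary charges,
amu; PDB Å values are converted at the file boundary. Residues are indexed
1-based and contiguous internally, while the original author (PDB)
numbering is retained as the reporting label, since published residue
identifiers follow author numbering.

Every time-averaged quantity honours a *discard window* (default 200 ns):
large protein complexes typically need on the order of 100–200 ns to
equilibrate, so frames with `time <= discard` are kept in the object but
excluded from averages. Replica aggregation is uniform across the package:
quantities are averaged within each replica first, then across replicas,
and the replica spread is reported as the standard deviation of the mean,
σ_μ = sd(replica means)/√n_replicas.

Binding (interaction) quantities follow the single-trajectory end-state
convention ΔE = E(complex) − E(A) − E(B), with the component terms
evaluated on the complex frames restricted to each group; for pairwise
non-bonded sums the bonded contributions cancel identically, leaving the
inter-group pair sum. (Where the convention is sometimes typeset with an
ambiguous sign on the third term, this package uses the standard reading
above.)

## Flexibility metrics

*RMSD* uses the closed-form Kabsch superposition (SVD with a determinant
correction) on a fit selection, measured on a possibly different selection.
*RMSF* is block-averaged: within each block (default 100 ns) frames are
iteratively superposed (2 iterations) to the block-mean structure, the
per-atom fluctuation is computed about that mean, and the profile is the
mean over blocks, then replicas. Whether the fluctuation fit should be
per-block or against a global reference is a genuinely open choice;
per-block is implemented because it removes slow rigid-body drift exactly
as window averaging intends. Superposition necessarily absorbs the six
rigid-body degrees of freedom; on synthetic bead systems whose beads
fluctuate about a *fixed* reference this bias is measurable, so
`rmsf_blocked(..., superpose = FALSE)` recovers planted amplitudes exactly
and is what the closed-form tests use.

Hydrogen bonds use the common geometric criterion D···A ≤ 0.35 nm and
H–D···A angle ≤ 30°, both inclusive, with both thresholds exposed as
parameters; donor–hydrogen pairing can be inferred geometrically
(`infer_donors()`, covalent cutoff 0.115 nm). Contact occupancies are the
fraction of analysis frames with the pair distance at or below the
threshold — all thresholds in the package are inclusive (≤ / ≥), matching
the documented boundary behaviour of the contact-gating rules.

## Energetics

Short-range non-bonded energies sum Coulomb `f·qᵢqⱼ/r` (f = 138.935458
kJ·mol⁻¹·nm·e⁻²) and Lennard-Jones `4ε[(σ/r)¹²−(σ/r)⁶]` over inter-group
atom pairs within r_c = 1.2 nm (Lorentz–Berthelot combination). The
full-range ΔE_Coul/LJ term is computed as the *cutoff-free direct pair
sum* (minimum-image when a box is present) rather than an Ewald
reciprocal-space treatment: at the package's scale the direct sum is exact
for non-periodic systems and serves as the semantic stand-in for
"interactions beyond the cutoff"; a dispersion correction is likewise
subsumed by the cutoff-free LJ sum. Residue-pairwise tables are gated by
the 0.6 nm *any-frame* contact rule and aggregate exactly the same pair
matrices as the group total, which is why Σ(pair energies) equals the
group interaction energy to machine precision — the test suite asserts
1e-6 relative.

SASA uses the Shrake–Rupley construction with a deterministic golden-spiral
point set (default 960 points/atom; 960→3840 changes totals by < 0.5% on
the test fixtures) and probe radius 0.14 nm. Because the point lattice is
fixed in space, naive Shrake–Rupley is only approximately
rotation-invariant; coordinates are therefore first rotated into a
canonical principal-axes frame (axis signs fixed by the third moment of the
projections), making accessible areas invariant under rigid motion to
floating-point precision. The apolar term is γ·SAS + b with
γ = 0.00542·4.184·100 kJ/mol/nm² and b = 0.92·4.184 kJ/mol; in the
three-term binding difference the offset enters once, negatively:
ΔE_apolar = γ·ΔSAS − b.

The polar term solves the *linearized* Poisson–Boltzmann equation on a
7-point finite-difference grid: default spacing 0.0325 nm, solute
dielectric 4, solvent dielectric 78.5, padding 1.0 nm. Face dielectrics are
harmonic means with the solute fraction of each edge sampled at three
points against the union of atomic spheres (default radius 2^{1/6}σ/2, the
Lennard-Jones energy-minimum radius, overridable); boundary potentials are
Debye–Hückel screened Coulomb values; iteration is SOR with
ω = 2/(1 + π/n). The reaction-field energy is
½Σqᵢ(φ_solvated − φ_reference) where the reference solve uses the solute
dielectric everywhere on the *same grid*, cancelling the grid self-energy.
On the Born ion (q = 1 e, a = 0.2 nm, ε 1→78.5) the solver lands well
inside 5% of the analytic −342.91 kJ/mol at 0.025 nm spacing with error
decreasing under refinement (the acceptance tests measure both). Ionic
strength defaults to 0 — the salt concentration used in the MD force field
does not have to apply to the continuum solve, and no published setting
prescribes one — with a config knob for the Debye term. The solver is
deliberately linearized: parity with a nonlinear production PB code is a
non-goal, and polar values should be read as a consistent comparative
term, not an absolute solvation energy.

MM/PBSA cadence: the short-range and apolar terms are evaluated on a dense
snapshot set and the polar term on a ~10× sparser one (defaults reproduce
an 800/80-snapshot cadence for a 1 μs trajectory sampled at 1 ns with a
200 ns discard).

## Correlation networks and allosteric paths

Inter-residue coupling uses the generalized correlation coefficient
r_MI = √(1 − e^(−2I/d)) with d = 3, where I is the mutual information
between the two residues' 3-D Cα displacement vectors. The estimator is
Kraskov algorithm 1 (k = 6 neighbours, Chebyshev metric) — the method
itself specifies no estimator settings, so k is exposed as config. MI is
computed on *joint 3-D* vectors (d = 3), the standard form of the method,
rather than per-dimension. Frames are strided (default 10) before
estimation because kNN MI estimators assume weakly dependent samples, and
globally superposed to the ensemble mean so rigid-body motion cannot
masquerade as correlation. On Gaussian ensembles with per-dimension
correlation ρ the closed form gives r_MI = |ρ|; the acceptance suite
requires recovery within ±0.05 at n = 5000, k = 6 for ρ ∈ {0, 0.3, 0.6,
0.9}.

The correlation matrix is filtered by a contact map (any heavy-atom pair
within 0.5 nm in ≥ 70% of frames, both inclusive); surviving pairs become
edges with weight −log₁₀ r_MI (weight 0 ⇔ perfect correlation; r_MI ≤ 0
edges are omitted as infinitely weak). Sequence-adjacent residues are
retained as edges by default (a flag can exclude them). Shortest paths use
an O(n²) Dijkstra; among equal-weight shortest paths the lexicographically
smallest node sequence is returned, a deterministic tie policy documented
here because published "preferential" paths are unique only up to ties.
Correlation matrices are estimated per replica and averaged; system
comparisons are element-wise differences of the replica means.

## Entropy and work-based free energies

Schlitter's formula S = (k_B/2) ln det[1 + (k_B T e²/ħ²) M^½ C M^½] is an
upper bound on the configurational entropy from the mass-weighted Cartesian
covariance C of the superposed analysis frames. The prefactor is assembled
in SI units (masses amu→kg, covariance nm²→m²) because the argument must be
dimensionless and unit bookkeeping is the dominant implementation risk; the
determinant is evaluated through eigenvalues with small negative values
clamped at zero. Covariances are computed per replica and the entropies
averaged (a pooled mode exists). A diagnostic flags fewer than 3N effective
samples. On harmonic-well ensembles both the Schlitter and the quantum
harmonic-oscillator entropies have closed forms, so the upper-bound
property and the 2%-recovery check are directly assertable. The binding
cycle is plain algebra: ΔS_b = S(complex) − ΣS(parts) per system and
−TΔΔS_b = −T(ΔS_b,1 − ΔS_b,2).

Work-based ΔG estimation consumes direction-labelled work sets. BAR solves
the Bennett self-consistent equation on the forward works and the negated
backward works by bracketed root finding; CGI intersects the two fitted
Gaussians (midpoint of means for equal variances). Uncertainties are
seeded bootstraps (default 100 resamples). Non-overlapping work
distributions attach an explicit warning. The synthetic generator draws
W_f ~ N(ΔG + βσ²/2, σ²) and W_b ~ N(−ΔG + βσ²/2, σ²), which satisfies the
Crooks relation exactly in distribution, so BAR must recover the planted
ΔG (bias < 0.05 kJ/mol at n = 10⁴, β σ² ≈ 1.5 in the acceptance suite) and
two generated legs must recombine to the planted ΔΔG. The cycle
ΔΔG_b = ΔG_mut(complex) − ΔG_mut(receptor) propagates uncertainties in
quadrature.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of spec + seed (the global RNG stream is
left untouched) and guarantee only the statistical/geometric property each
test needs:

- `gen_gaussian_ensemble()` — i.i.d. (optionally AR(1)) frames with planted
  per-dimension correlations; positive-definiteness of the requested
  correlation matrix is validated, not repaired.
- `gen_harmonic_wells()` — per-dimension variance k_B T/k with the analytic
  covariance attached; the oracle for RMSF and Schlitter.
- `gen_toy_complex()` — a 50-bead receptor/ligand pair whose variants
  differ in exactly one declared bead; the default mutant tightens an
  interfacial salt bridge from 0.55 to 0.35 nm with 0.02 nm thermal
  jitter, so the mutant must show a more negative ΔE_SR and a higher
  planted-contact occupancy under identical settings.
- `gen_planted_path()` — plants both contact geometry and correlation
  structure. Exact pairwise correlations of 0.9 along a chain with low
  correlation elsewhere are *mathematically impossible* (positive
  definiteness forces corr(i, i+2) ≥ 0.62 when both chain edges are 0.9),
  so the generator plants ρ_on on path edges and closes the matrix with the
  Markov (max-product) rule — the strongest admissible structure — while
  the geometry guarantees that path shortcuts are not contacts: path
  residues lie on a line at 0.45 nm spacing and the remaining residues form
  a weakly-correlated detour arc, so an alternative route always exists and
  recovery is a real discrimination task. A few geometry-induced contacts
  between path and detour beads carry the (small) Markov-product
  correlations rather than exactly ρ_off; they are never competitive.
- `gen_work_sets()` — Crooks-consistent Gaussians as above.

Frames are i.i.d. by default (closed-form checks require it); the AR(1)
knob exists to stress block averaging. None of the generators attempt
physical protein geometry, force-field realism, solvent structure, or
conformational substates. Passing tests therefore demonstrate correctness
of the estimators and pipelines under their stated assumptions — they do
not demonstrate convergence or accuracy on real microsecond protein
trajectories, where sampling error, anharmonicity and forced protonation
choices dominate.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to make sampling
error small relative to each tolerance: 5000-frame ensembles for
correlation recovery (the estimator bias of KSG at k = 6 is well under
0.05 in r_MI there), 2·10⁴ frames for Schlitter (2% tolerance), 10⁴ works
per direction for BAR (0.05 kJ/mol bias), 100-frame/50-residue toy
complexes for energetic identities (which hold to machine precision
regardless of length), a 0.025 nm PB grid for the Born check, and 500
random ≤ 8-node graphs against exhaustive path enumeration. Tie detection
in Dijkstra uses a 1e-9 relative tolerance; LJ/Coulomb cutoffs and all
contact thresholds are inclusive; the PB grid aligns the first atom on a
grid node to keep the point-charge discretization consistent between the
solvated and reference solves.

## The pipeline

`run_config()` validates every stage's parameters before any computation;
`run_pipeline()` executes flexibility → energetics → correlation →
entropy → work-based ΔΔG with per-stage seeds derived deterministically
from the master seed, records stage failures in a manifest without
aborting the rest, and is bit-reproducible for identical config + seed.
`write_report()` emits delimited tables (energy terms × systems with σ_μ,
pair-energy and occupancy tables, edge lists, per-edge path weights) plus
a plain-text summary. The package is library-first: the exported functions,
this vignette and `scripts/acceptance.R` are the supported entry points.

## Known limitations

- The PB solver is linearized and grid-based; absolute polar energies
  carry discretization error (sub-percent on the Born ion at the default
  spacing, unquantified for irregular shapes) and are not comparable to
  nonlinear production solvers beyond the comparative setting.
- Kraskov MI at small sample sizes is biased low; strided replicas of a
  few hundred samples are adequate for ranking edges (path recovery) but
  not for absolute r_MI values near 1.
- Schlitter entropy is an upper bound and converges slowly in N; the
  low-sampling diagnostic should be heeded.
- Shrake–Rupley areas depend weakly on the point count; the canonical
  orientation makes them rigid-motion invariant but principal axes can be
  unstable for highly symmetric coordinate sets.
- No periodic-boundary reassembly is performed; trajectories are assumed
  whole-molecule and, if periodic, minimum-image distances are only applied
  when a box is supplied.
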