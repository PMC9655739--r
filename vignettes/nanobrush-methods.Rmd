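---
title: "Methods: geometry, statistics and energetics in nanobrush"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, statistics and energetics in nanobrush}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Carbon nanotubes intended for biomedical use are commonly coated with
grafted poly(ethylene oxide) (PEO) brushes to suppress non-specific
protein adsorption. Whether a short peptide adsorbs onto such a coated
tube — and how deeply it penetrates the brush — depends on the grafting
density of the brush, the hydropathy of the peptide, and the solvent
(vacuum, water, or physiological saline). `nanobrush` provides the full
computational tool chain for studying this question on atomistic
configurations: deterministic construction of the coated-tube systems,
cylindrical-geometry spatial statistics, hydrogen-bond and
secondary-structure analysis, conformational descriptors, and MM-PBSA
binding free energies. Because converged molecular-dynamics ensembles are
expensive and not redistributable here, the package also ships a
synthetic-ensemble generator with exactly known statistical ground truth,
so that every estimator can be validated end to end at desk scale.

## System construction

**Tube geometry.** A zigzag (n, 0) nanotube is obtained by rolling a
graphene sheet with lattice constant a = 0.246 nm (C–C bond a/√3 =
0.142 nm). The diameter is d = (a/π)·√(n² + nm + m²); for (10, 0) this
gives 0.7830 nm, quoted as 0.8 nm at one decimal. The sidewall area and
the grafting densities are computed with the *nominal* (one-decimal)
diameter: area = π · 0.8 · 4.1 = 10.3 nm², so 4, 8 and 16 chains give
σ = 0.388, 0.776 and 1.553 nm⁻². This "report-parity" convention is
deliberate: it is the only convention under which all five published
setup numbers (diameter, area, three densities) are reproduced
simultaneously; the exact-diameter area (10.09 nm²) is also computed and
reported alongside. The translational period of the zigzag cell is
√3·a with 4n carbons per period; as many complete periods as fit in the
requested length are generated, every atom lying exactly on the cylinder
of radius d/2. Tube carbons are uncharged and flagged immobile — they
participate only in non-bonded interactions.

**Grafting pattern.** The reference description says only that chains are
"evenly distributed". We realize this as a deterministic rings ×
angular-slots pattern (r rings, k = n_chains/r slots, adjacent rings
offset by half a slot, rings symmetric about the tube midplane). When the
ring count is not given explicitly, the factorization of n_chains that
*maximizes the minimum anchor–anchor geodesic distance* on the cylinder
is chosen. An earlier, simpler rule (fewest rings such that a ring is not
over-filled) was considered and rejected: for 16 chains it packs eight
anchors per ring only ~0.25 nm apart, which a random placement beats —
contradicting the max-min reading of "evenly distributed" that the
package tests enforce. The capacity limit is σ ≤ 1.6 nm⁻² (16 chains on
the reference tube), the densest brush studied. Anchors are recorded as
bond records to the nearest sidewall carbon; no bonded force terms are
evaluated downstream.

**PEO chains.** Each chain is an all-atom (–CH₂–CH₂–O–)ₙ strand with a
terminal methoxy group (3n + 1 heavy atoms), laid out as a stretched 7/2
helix with a rise of 0.28 nm per monomer and helix radius 0.18 nm, then
rotated to point radially outward from its anchor. Exact internal
coordinates of the initial helices are not specified in the reference
description; these values give near-ideal C–C/C–O spacings along the
backbone and an end-to-end length within 10 % of n × rise.

**Homopeptides.** Gly/Ser/Val 24-mers are built by NeRF chain extension
from standard peptide internal coordinates (N–CA 0.1458, CA–C 0.1525,
C–N 0.1329 nm; τ(N–CA–C) = 111.2°; ω = 180°), with every residue at the
same (φ, ψ). The default conformation is extended β (−135°, 135°) — the
initial conformation is not stated in the reference description, and an
extended start is the conventional unbiased choice. The N-terminus is
protonated (NH₃⁺) and the C-terminus dissociated (COO⁻); per-residue
charges are a simplified OPLS-like set that reproduces the formal
charges (+1/−1 termini, zero net) and can be overridden wholesale by a
per-atom parameter table. Residue compositions (Gly 7, Ser 11, Val 16
atoms; +2 H and +1 O at the termini) are asserted at build time.

**Placement, solvation, salt.** The peptide is rigidly rotated (a fixed
set of the 24 proper cube rotations) and translated radially until the
closest peptide–system contact lies in [gap, gap + 0.02] nm, gap =
0.3 nm by default; among admissible orientations the one maximizing the
number of peptide atoms within 0.6 nm of the brush is kept. Water is a
rigid 3-site model placed on a jittered cubic lattice at 33.3 nm⁻³ with
deletion of molecules whose oxygen falls within 0.28 nm of a solute
heavy atom; for a pristine tube in a 6 nm box this yields ≈ 6 985
molecules, within 0.5 % of the reference count of 7 010. NaCl at
9.0 g·dm⁻³ (0.154 mol·dm⁻³, molar mass 58.44 g·mol⁻¹) replaces
round(c·N_A·V_water) randomly chosen waters by Na⁺ and as many by Cl⁻,
preserving electroneutrality. All stochastic steps take an explicit
integer seed.

## Synthetic ensembles and what they do (and do not) show

`generate_ensemble()` places the peptide rigidly each frame with its
centre of mass at a radial distance drawn from Normal(ρ₀, σ_ρ) truncated
below at the sidewall radius (rejection sampling keeps configurations
physical), uniform in angle and axial position, plus optional per-atom
Gaussian jitter; water can be resampled per frame from an inhomogeneous
density bulk · g(ρ). `generate_hbond_ensemble()` produces
donor–hydrogen–acceptor triples that sit inside the geometric criterion
(collinear, 0.29 nm) with probability p and outside it (0.45 nm)
otherwise. `ideal_gas_frames()` is the Poisson null for the density and
RDF estimators. Frames are labelled at 10 ps spacing purely for report
parity; no dynamics is implied, and successive frames are independent.

These ensembles exercise every estimator against known parameters — the
package's primary acceptance surface — but they deliberately do *not*
emulate correlated dynamics, brush deformation under peptide insertion,
or solvent structure beyond a prescribed radial profile. Passing the
recovery tests therefore demonstrates estimator correctness, not the
reproduction of any trajectory-dependent published value (peptide D and
R_g tables, hydrogen-bond counts, or absolute binding energies), which
would require tens of nanoseconds of atomistic molecular dynamics of up
to ~56 000 waters plus continuum-solver parameters that are not public.

## Spatial statistics

Cylindrical density profiles count selected atoms in concentric shells
of thickness 0.1 nm and length 4.1 nm centred on the tube midpoint
(atoms outside the axial slab are excluded); both raw mean counts per
shell and number densities per nm³ are emitted, since the published
figure axis does not disambiguate the two. PEO profiles use heavy atoms
only; peptide profiles use all atoms. RDFs use the minimum-image
convention in the cubic box (profiles do not — the tube is unique in the
box) and are normalized so an ideal gas gives 1. The centre-of-mass
sidewall distance D = ρ_COM − R is signed, not clipped. R_g is
mass-weighted with per-axis components satisfying
R_g² = R_gx² + R_gy² + R_gz² exactly. Superposition is a Kabsch SVD fit
with reflection rejection; the reported RMSD series is unweighted (the
conventional definition), with mass-weighted fitting available.

## Hydrogen bonds, bridges, secondary structure

A hydrogen bond exists when the donor–acceptor distance is ≤ 0.35 nm and
the deviation from linearity is ≤ 30°. The angular deviation is measured
between the D→H and D→A vectors (the common analysis-package
convention); the alternative 180° − ∠(D–H···A) reading is available via
`hbond_criterion(convention = "DHA")` because the verbal criterion is
ambiguous at the margins. Donors are hydrogens covalently bonded to N or
O; acceptors are all oxygens, so PEO contributes acceptors only and the
tube neither. Bonds are classified intra-peptide / peptide–water /
peptide–PEO / PEO–water by the donor and acceptor group labels; counts
are per simulation cell. Detection uses a cell grid whose output is
test-enforced to equal the all-pairs computation exactly.

A sodium bridge is a Na⁺ within 0.32 nm of at least one PEO oxygen and
one peptide oxygen simultaneously; 0.32 nm is the typical first minimum
of Na⁺–O pair distributions and is configurable, as no value is
published.

Secondary structure is assigned by backbone hydrogen-bond patterns in
priority order (two consecutive i→i+4 turns → α-helix; two consecutive
i→i+3 → 3₁₀-helix; paired nonlocal bridges → β-sheet; a lone bridge →
isolated bridge; an unextended i→i+3/4/5 bond → turn; else coil). This
is a documented stand-in for table-driven assignment programs: the
empirical hydrogen-bond energy function and torsion-propensity tables of
those programs are *not* reimplemented, but the six class labels match,
so reports are comparable. Ideal α (−57°, −47°) and 3₁₀ (−49°, −26°)
builds are labelled correctly on all interior residues, which is the
calibration the package enforces.

## MM-PBSA energetics

The binding free energy uses the single-trajectory scheme: receptor
(tube + brush) and ligand (peptide) coordinates are extracted from each
complex frame, so the intramolecular term cancels identically and is
carried as an explicit zero to preserve the full decomposition
structure. Gas-phase terms are computed without cutoffs (distance
switching belongs to the dynamics engine, not to rescoring):
E_vdW = Σ 4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶] with geometric-mean combination
for both σ and ε, and E_coul = Σ f q_i q_j / r with
f = 138.935458 kJ·mol⁻¹·nm·e⁻². The entropic term is omitted, following
the practice that it does not improve prediction accuracy for trends.

The polar term solves the linearized Poisson–Boltzmann equation by
finite differences: solute dielectric (default 2) inside the union of
atom spheres of radius 2^{1/6}σ/2, solvent dielectric (default 78.4)
outside, harmonic averaging of the face dielectric across the boundary,
Debye screening (κ² from the ionic strength, 0.154 mol·dm⁻³ for saline)
in the solvent region only, Dirichlet boundaries from the single-centre
Debye–Hückel potential, and red-black successive over-relaxation (ω =
2/(1 + sin(π/N)), relative update tolerance 10⁻⁶) in compiled code. The
reaction-field energy is ½Σq_i(φ_solvated − φ_reference) with the
reference solve on the identical grid and charge assignment, so the grid
self-energy cancels. A Born ion (q = 1 e, R = 0.2 nm) is reproduced
within 0.8 % at the default 0.05 nm spacing, with the error decreasing
monotonically under refinement 0.1 → 0.05 → 0.025 nm. The nonpolar term
is γ·SASA with γ = 0.0227 kJ·mol⁻¹·Å⁻² and zero offset — these, like
ε_in, are unpublished for the reference calculations and follow common
MM-PBSA practice; all are configuration-exposed. SASA uses Shrake–Rupley
quadrature on a deterministic Fibonacci lattice (960 points/atom,
≈ 0.1 % on a lone sphere). Frame averaging defaults to the final third
of the trajectory, the analogue of last-segment averaging over a
production run.

Because the continuum parameters are not published, absolute binding
energies are not reproducible even in principle from the public record;
the package therefore validates the machinery (closed forms, oracle
equality, cycle identity ΔG_bind = ΔE_vdW + ΔE_coul + ΔΔG_pol +
ΔΔG_nonpol per frame) rather than published ΔG values.

## Numerical choices and degenerate inputs

* Deterministic everything: builds are bit-identical; all random draws
  (solvent jitter, ion replacement, ensembles) flow from explicit seeds.
* Orientation search ties in `place_peptide()` resolve to the first of
  the fixed 24-rotation set; the radial approach is solved by bisection
  to the 0.02 nm window.
* Zero-σ polar hydrogens get a 0.05 nm cavity floor in the PB dielectric
  map so the molecular surface stays closed.
* Empty selections, empty trajectories, zero-mass selections, hydrogens
  without a bonded donor, overlapping receptor/ligand selections, and
  sub-5-residue secondary-structure queries raise typed errors rather
  than returning silent zeros.
* Problem sizes used by the shipped tests and the acceptance script:
  500-frame ensembles for parameter recovery, 100-frame ideal-gas nulls,
  ≤ 0.025 nm PB grids on single-ion systems and 0.1 nm grids on
  desk-scale complexes. These sizes give the statistical power the
  checks need (99 % confidence bands, 3σ Poisson bands) while keeping a
  full run on one CPU in minutes.

## Known limitations

* Only zigzag (m = 0) tubes can be built; armchair/chiral geometry is
  out of scope (the diameter arithmetic accepts any chirality).
* No force-field assignment, minimization, or dynamics: configurations
  are generated, not propagated, and the per-atom charges/LJ parameters
  shipped by the builders are simplified defaults meant to be overridden
  by a parameter table for quantitative rescoring.
* The secondary-structure stand-in ignores hydrogen-bond energetics and
  torsion statistics; marginal assignments can differ from table-driven
  programs.
* The PB solver is a regular-grid SOR solver without focusing; very
  large solutes at fine spacing are slow by construction.
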