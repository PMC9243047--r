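---
title: "Methods: conformer ensembles, RRHO thermochemistry and the anomer reaction ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer ensembles, RRHO thermochemistry and the anomer reaction ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucanomer)
```

## Scope and model

`nucanomer` implements the thermodynamic side of the question of why
β-nucleotides (and the thymine-on-deoxyribose / uracil-on-ribose
pairing) dominate nucleic acids: standard Gibbs energies of the
building blocks and their condensation products, compared between the α
and β anomers along two assembly orders. The electronic-structure
problem itself is deliberately out of scope — energies enter through a
pluggable backend contract, served either by the built-in surrogate
potential or by records parsed from quantum-chemistry log fixtures. The
pipeline, the statistics on top of the energies, and the reaction
bookkeeping are the package's subject matter.

Workflow order mirrors the study protocol: randomized conformer
generation over the sugar's exocyclic torsions, local optimization of
every conformer, deduplication into unique minima, cumulative Boltzmann
selection, a relaxed scan around the glycosidic (or phosphate) torsion,
unconstrained refinement with frequency vetting, and finally the
species-level Gibbs-energy ledger.

## Conformer sampling

The rotatable set for a furanose is selected by rule: every H-O-C-C
torsion whose oxygen is a hydroxyl oxygen, plus the exocyclic
O-C5′-C4′-C3′ ("beta") torsion. For the ribofuranose toy this yields 5
torsions; for the 2′-deoxy analogue, 4. The original description of the
deoxy case counts "only 3 angles of the H-O-C-type"; we read this as 3
hydroxyl torsions *plus* the retained beta torsion and implement the
4-torsion plan (the selector is rule-driven, so either reading is a
one-line change at the call site).

Angles are drawn independently and uniformly from [−180°, 180°). The
upstream tool's exact sampling distribution is not documented anywhere
we could rely on, so uniform independent sampling is adopted as the
simplest faithful reading of "randomly varying" the dihedrals. One
seeded RNG per sampling plan makes ensembles bit-reproducible, and the
seed is recorded in each conformer's provenance. The default plan size
is 1000 conformers, the ensemble size used for the furanose searches;
tests and the acceptance script use 6–50 conformers on toy molecules,
sizes chosen so the whole suite exercises every stage in well under a
minute per file while leaving the statistical contracts (uniformity,
determinism, dedup behaviour) fully testable.

Deduplication merges two optimized conformers when their energies agree
within 0.1 kcal/mol *and* every torsion agrees within 15° under the
periodic distance; clusters are the transitive closure of that
relation, represented by their lowest-energy member (ties broken by
sample index). Both tolerances are configurable; no published values
exist for them, and the defaults are chosen to be small against the
surrogate's barrier heights (2 kcal/mol, 120° well spacing).

## The surrogate backend

The surrogate potential is a deliberately minimal molecular-mechanics
form: harmonic bonds E = k(r−r₀)², cosine torsions
E = V/2·(1+cos(nφ−γ)), and 12-6 pairs E = ε[(r_m/r)¹² − 2(r_m/r)⁶].
`default_surrogate_params()` builds it around a reference geometry:
bonds from the perceived bond graph (covalent-radius sum × 1.15), stiff
1-3 wells standing in for angle terms (keeping the functional form
within the three declared term types), soft long-range wells for pairs
four or more bonds apart, and a 3-fold torsion (V = 2 kcal/mol, γ = 0)
on each rotatable dihedral. It is rigid-motion invariant by
construction and makes no claim to quantitative chemistry; its job is
to give the pipeline a fast, deterministic, analytically understood
energy surface on which every contract (descent, constraint
satisfaction, scan topology) can be verified exactly.

Optimization is BFGS over Cartesians (RMS gradient tolerance 1e-4
kcal/mol/Å, 500-iteration budget; "negligible forces" is the only
guidance available, so the tolerance is our choice). Frozen torsions
are enforced by a stiff harmonic restraint (2×10⁴ kcal/mol/rad²) whose
centre is shifted between BFGS rounds so the restrained minimum lands
on the exact target angle; the sub-1e-7-degree residual is removed by a
final rigid rotation of the distal fragment. Convergence is judged on
the gradient projected onto the constraint-satisfying subspace. An
unconverged optimization is flagged, never silent, and a reported
energy is never above the input energy.

Frequencies come from a central-difference mass-weighted Hessian; the
six (five for linear tops) near-zero external modes are dropped by
magnitude, and modes below −1 cm⁻¹ count as imaginary. On a harmonic
diatomic the single mode matches the analytic √(k/μ) value to the
finite-difference tolerance.

## Thermochemistry

RRHO corrections use the ideal-gas standard state at the stated T and P
(defaults 298.15 K, 1 atm): Sackur–Tetrode translation, classical
rigid-rotor rotation with symmetry number 1 (the molecules of interest
are asymmetric; σ is configurable), and harmonic-oscillator vibration.
ZPE = ½Σhcν̃ with no frequency scaling factor (none is prescribed for
the workflow this mirrors). No solution-phase standard-state correction
is applied for either phase tag — "aqueous" is metadata selecting which
fixture or keyword set a backend uses, not simulated physics. All
constants are pinned to CODATA-2018 in one table; note that the
commonly quoted k_BT(298 K) ≈ 0.5 kcal/mol is a rounding artefact — the
package returns 0.59.

## Boltzmann selection

Weights are w_i = exp(−(E_i−E_min)/k_BT)/Σ, stabilized by the minimum
shift. Selection sorts by weight (ties by original index) and keeps the
shortest prefix reaching the threshold (default 0.5 — "at least 50% of
Z"). The selection temperature defaults to 298.15 K; the temperature
actually used for Z upstream is unstated, so it is exposed as a
parameter. Weights are computed from the raw energies of the stage that
produced the ensemble, without degeneracy corrections — again a choice
documented here because the source is silent.

## Relaxed scans

A scan steps one torsion over `start + 60°·k`, k = 0..5 by default,
freezing it at each grid point and relaxing everything else. Whether
the published 6×60° grid starts at the initial angle or at zero is
ambiguous; start-at-initial is the default and the start angle is a
protocol field. Grid points are visited sequentially, each started from
the previous relaxed structure — chain continuation, standard practice
for "soft" scans though not explicitly stated in the protocol we
mirror. Unconverged points are flagged and excluded from the argmin
(ties resolved toward the smaller wrapped angle). Refinement reruns an
unconstrained optimization from the argmin structure and accepts it as
a minimum only with zero imaginary modes.

## The reaction ledger

Species records carry role, sugar, base, anomer, phase, pathway
provenance, E, E+ZPE, G°, formula and charge. Composite formulas follow
condensation stoichiometry (one water per bond formed) from the real
molecular formulas (C₅H₁₀O₅ ribose, etc.) even when geometries in the
pipeline are toys. The phosphate enters as H₂PO₄⁻, so every
phosphate-bearing species carries charge −1; the product's protonation
state is otherwise unspecified upstream and this is the implemented
assumption. Every step is element- and charge-balanced before its ΔG°
is formed; all 80 enumerated reactions (2 pathways × 2 sugars × 5 bases
× 2 anomers × 2 phases) pass this check in the test suite.

Nucleotide records are keyed by pathway provenance because the two
assembly orders end in different local minima; Hess's law is enforced
within a provenance, and the ΔΔG° comparison
(ΔG°_{i+j})_β − (ΔG°_{i+j})_α is antisymmetric under swapping the
anomer labels by construction.

Printed report tables round to one decimal, half away from zero;
unrounded values are always retained in the JSON side file. The shipped
reference table of per-step DFT Gibbs energies contains a handful of
rows whose printed totals disagree with their own printed steps at the
last decimal (rounding of unrounded intermediates upstream); the
accessor returns both the recomputed and the printed numbers so the
discrepancy is visible rather than silently absorbed, and checked
comparisons use self-consistent rows.

## Synthetic data and what passing tests mean

The generator family produces (i) toy molecules with the correct bond
topology and hydroxyl patterns but idealized planar-ring geometries,
(ii) conformer ensembles whose dominant Boltzmann weight w* is
back-solved in closed form (shift the non-lowest energies by
−k_BT·ln[(1−w*)/(w*·S)]), and (iii) full species registries in which a
planted anomer offset δ, per-pathway effects, and a planted
sugar-exchange advantage are recoverable *exactly* (to 1e-9, zero
noise) by `anomer_delta`, `pathway_comparison`, `ddg_compare` and
`sugar_exchange_delta`. Registry noise is independent normal on G°,
default 0.

Passing these tests certifies the arithmetic, the selection logic, the
constraint mechanics and the bookkeeping — it does not certify
quantum-chemical accuracy, ring-pucker realism (no Cremer–Pople
coordinates; ring torsions are never sampled), solvation physics, or
anharmonic effects. Those are explicit non-goals: the package treats
energies as backend-supplied.

## Numerical choices and degenerate inputs

* Torsions: IUPAC sign convention, range (−180°, 180°]; collinear
  central bonds raise a degenerate-torsion error; rotating a torsion
  whose central bond lies in a ring is refused.
* XYZ output prints 6 decimals; read∘write is the identity at that
  precision. Z-matrix reconstruction places atoms by
  distance/angle/torsion and reproduces declared torsions to 1e-6°.
* Overlapping nonbonded pairs (r < 0.1 Å) are a hard error, not a
  large number.
* Empty ensembles, empty dihedral plans with n > 1, registries with
  missing species, and unbalanced reactions all fail with typed,
  descriptive errors; report generation degrades to explicit gap lists
  instead of failing.

## Problem sizes

The test suite runs the statistical contracts at sizes chosen for tight
feedback: 10 000 draws for the uniformity check, 200 random ensembles
against the brute-force selection oracle, 100 random optimizer starts
for the descent property, 50-record parser round-trips, and pipelines
of 4–12 conformers on the methanol toy for byte-identity checks. The
acceptance script uses a 100-conformer planted ensemble and an
8-conformer end-to-end run. All are the package's own choices for a
self-contained, deterministic demonstration; the sampling default for
real use remains 1000 conformers per molecule.
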