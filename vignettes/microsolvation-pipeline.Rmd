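---
title: "From sampled geometries to population-weighted detachment energies: the microsolv methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sampled geometries to population-weighted detachment energies: the microsolv methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsolv)
```

## The model

`microsolv` analyses microsolvated ion clusters — an ion plus a counted
number n of water molecules — under the standard conformer-ensemble model:
the observable measured on the cluster beam is a population-weighted average
over distinct low-energy conformers M, each contributing with its
equilibrium fraction at temperature T,

$$x_M = \frac{e^{-\Delta G_M / RT}}{\sum_j e^{-\Delta G_j / RT}},
\qquad R = 0.0019872\ \mathrm{kcal\,mol^{-1}\,K^{-1}},$$

so that, e.g., the ensemble vertical detachment energy is
$\mathrm{VDE}_{avg} = \sum_M x_M\,\mathrm{VDE}_M$. The assumptions behind
this are (i) conformers interconvert slowly relative to the measurement but
equilibrated during preparation at T; (ii) relative Gibbs free energies
$\Delta G_M$ are adequate at a single temperature (no conformational-entropy
corrections beyond what the supplied G values carry); and (iii) plain
Boltzmann weights — no degeneracy factors. Assumption (iii) is a declared
choice: it reproduces the published three-water fractions we ship as
reference data (0.18 for the most stable conformer, 0.02 for the
water-on-water outlier at ΔG = 1.4 kcal/mol), so nothing more elaborate is
warranted by the data the pipeline sees.

Detachment energies are pure charge-state energy differences:
VDE is final-state-at-frozen-geometry minus initial state; ADE uses the
relaxed final state, so ADE ≤ VDE whenever the final-state surface is well
behaved. The package treats violations as data-quality warnings, not
errors, because they legitimately arise from unconverged or
differently-corrected supplied energies.

Water binding free energies use the generalized many-fragment counterpoise
scheme: every fragment (solute and each water) is evaluated in its own
basis and in the full-cluster basis at the cluster geometry, and
$\mathrm{BSSE} = \sum_f [E_f(\mathrm{own}) - E_f(\mathrm{ghost})] \ge 0$
under the variational contract. Whether monomers should instead be taken at
their own relaxed geometries (which would fold a deformation term into the
binding energy) is genuinely open; we bind to in-cluster monomer energies
as supplied and record the scheme name in output metadata, so the choice is
visible rather than silent.

The quantity we correlate with binding strength is the *incremental* VDE
shift, VDE(n) − VDE(n−1), not the absolute VDE. Both readings of "the
increase of VDE with the number of water molecules" are defensible a
priori; only the incremental reading is perfectly linear in WBE/n for the
shipped reference values (R² = 1.000 vs ≈ 0.98 for absolute VDEs), and the
physics favours it too — each added water contributes one increment of
electrostatic stabilisation and one increment of binding energy.

## Clustering stage

Sampled frames are compared by minimal RMSD: superposition is computed on
solute heavy atoms only (Kabsch, proper rotation enforced), while the RMSD
is evaluated over all heavy atoms, so waters discriminate conformers but do
not distort the fit — hydration-site geometry is precisely the feature we
want to separate on. Chemically indistinguishable waters are matched
between frames by minimum-cost assignment on water-oxygen distances
(an O(n³) Hungarian solver) before the RMSD is taken; otherwise two frames
differing only by solvent relabelling would look structurally distinct.

Clusters come from the Daura/GROMOS neighbour-count algorithm: repeatedly,
the frame with most neighbours within the cutoff founds a cluster that
absorbs those neighbours. The founder is the representative. Defaults:
cutoff 1.0 Å on heavy atoms. Ties — in neighbour counts and in cluster
sizes — always break toward the lowest original frame index, which makes
the whole stage deterministic. Degenerate inputs fail loudly: empty
matrices, non-positive cutoffs, sub-3-atom or collinear superposition
selections (planar solutes are fine; only rank ≤ 1 is rejected).

## The synthetic generator: what it emulates, what it does not

The generator stands in for both the molecular-dynamics sampler and the
electronic-structure engine, with known ground truth:

* **System.** A rigid toy dianion with two unit-negative sites — a
  deprotonated-amine-like nitrogen and a phosphate-like oxygen, default
  separation 8 Å, plus neutral ring/ribose-like atoms — surrounded by rigid
  point-charge waters (O–H 0.9572 Å, H–O–H 104.52°, charges −0.834/+0.417 e).
* **Energy.** Coulomb 332.0637·q_iq_j/r over all intermolecular pairs plus
  one Lennard-Jones term (σ = 3.0 Å, ε = 0.15 kcal/mol) between heavy atom
  pairs. Restricting LJ to heavy atoms is deliberate: with a single (σ, ε)
  also on hydrogens, no hydrogen could approach an acceptor to
  hydrogen-bonding distance, and the hydration-site stage would have
  nothing to classify. Intramolecular pairs never contribute — fragments
  are rigid, and the pipeline never analyses internal degrees of freedom.
* **Sampling.** Metropolis Monte Carlo over rigid-body water moves at the
  ensemble temperature (default 298.15 K): local translations
  (≤ 0.3 Å) and rotations (≤ 30°), plus, with probability `p_jump` (default
  0.1), either a uniform reposition inside a hard-wall sampling sphere or a
  point inversion through the midpoint of two charged sites. The inversion
  move is what makes the two hydration basins — separated by ~8 Å and tens
  of kT — mutually reachable in desk-scale runs; it is an involution and
  hence a symmetric proposal, and water's achirality makes the inverted
  rigid body a valid placement. The hard wall prevents evaporation and
  keeps the uniform jump a symmetric proposal on a bounded state space.
  One seed determines everything; sampler and observable-noise streams are
  derived separately from it.
* **Observable.** VDE(conformer) = vde0 + Σ per-water site increments +
  Gaussian noise; ADE = VDE − 0.35 eV. Defaults vde0 = 1.30 eV and
  increments 0.50 (amine), 0.25 (phosphate), 0.15 (ring), 0.10 (ribose OH
  and water–water) eV mirror the measured shift ladder of the reference
  system, so the generator's ground truth lives on the same scale as the
  real data.

What the toy does *not* emulate: real force-field energetics, solute
flexibility (sugar-pucker or phosphate rotations), polarisation or
charge transfer, proton transfer, and any electronic-structure detail.
Consequently, passing the recovery tests demonstrates that the *pipeline* —
sampling, clustering, weighting, site classification, averaging — is
unbiased and correctly plumbed; it says nothing about whether a particular
force field or DFT functional is accurate for a real nucleotide dianion.

For ensembles produced by the sampler there are no per-conformer Gibbs
energies, so representatives are weighted by their cluster populations,
converted to effective free energies ΔG = −RT ln(pop/pop_max) purely so the
same table-building code serves both paths. Cluster population is the
consistent estimator of basin probability when frames are Boltzmann
samples; supplied ΔG values take precedence in file-based runs, matching
how the reference tables were produced (QM free energies on representative
geometries).

## Hydration sites

Hydrogen bonds are geometric: donor–acceptor distance ≤ 3.5 Å and
D–H···A angle ≥ 140°, N/O donors with covalent hydrogens (≤ 1.2 Å, same
fragment), N/O acceptors, intrafragment pairs excluded. The reference
analysis assigned sites visually, so there is no published criterion to
match; 3.5 Å/140° are conventional structural-biology defaults, both
configurable and recorded in output metadata. Each water's bonds map to the
site tag of the partner atom (carbonyl O11 and ring nitrogens both count as
the purine-ring site); a single primary site per water is chosen by the
fixed priority amine > phosphate > purine ring > ribose OH > water–water,
and waters with no bond are NONE. Site occupancies weight each water by its
conformer's x_M, so the occupancy table integrates to the mean number of
bound waters.

## Numerical choices

* Temperature: 298.15 K internally by default; recomputations of published
  fractions use 298 K as printed. The RT difference (< 0.0003 kcal/mol)
  never moves a 2-decimal result.
* Unit conversions: 627.5095 kcal/mol and 27.211386 eV per hartree; units
  are always declared by the caller, never autodetected.
* Boltzmann weights shift ΔG by the minimum before exponentiating, so large
  free-energy spreads cannot underflow the normalisation; fractions sum to
  1 within 1e−12.
* Weighted averages over truncated printed tables renormalize by the
  listed-weight sum — the convention that reproduces the published
  aggregates from the rows the tables actually list.
* The population threshold (default x_M ≥ 0.01) affects *display only*;
  every computation runs over the full record set.
* Report rounding follows the reference-table precision (ΔG one decimal,
  energies two, fractions two); internal computation is full precision.
  One consequence, visible in the unit tests: rows that print the same
  rounded ΔG can print different fractions, because the published weights
  were computed before rounding — rounded inputs reproduce them only to
  ±0.01.
* Extended-XYZ output uses %.6f coordinates and LF endings; read(write(E))
  is exact to 1e−6 Å by construction.

## Problem sizes

The test suite and the acceptance script run the sampler at desk scale,
chosen so statistical assertions have meaningful power while the whole
suite stays in the couple-of-minutes range: 30 000 MC steps with a 20 %
burn-in and stride 50 (480 recorded frames) for two-basin occupancy and
ground-truth recovery, 20 independent 4 000-step runs for the site-ranking
check, and ≤ 8-frame ensembles wherever an exhaustive oracle (brute-force
clustering, exhaustive water permutations, rotation-grid superposition) is
the comparison. Recovery assertions use three binomial standard errors of
the basin-occupancy estimate; with 480 near-independent frames that is
about 0.017 eV on the recovered ensemble-mean VDE.

## Known limitations

* The clustering cutoff and metric are declared defaults, not values
  inferred from the reference study, which never published its own.
* Binding energetics require externally supplied fragment energies; the
  package checks the variational sign of each counterpoise contribution but
  cannot detect a wrong basis pairing.
* The toy energy surface around an isolated charged site has a nearly
  degenerate orientational shell of minima; tests that reason about "the"
  global minimum therefore compare radial distance and energy rather than
  absolute placement.
* Site classification is purely geometric; energetic hydrogen-bond scoring
  or charge-density analysis is out of scope.
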