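---
title: "Quantifying force-regulated protein interfaces with mechbond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying force-regulated protein interfaces with mechbond}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechbond)
```

## The problem

Adhesion receptors work under load. For a complex like DNAM-1/CD155 —
an NK/T-cell activating receptor binding its ligand at an immune synapse —
the question is not only *how strong* the interface is at rest but *how
tensile force reshapes it*: some hydrogen bonds strengthen under load
(catch bonds), some weaken (slip bonds), and the whole interface can show a
biphasic force dependence with a threshold force at which dissociation is
minimal. mechbond provides the analysis layer for this kind of study: it
consumes equilibrium, force-clamp or force-ramp trajectories and produces
bond occupancies, interface energetics, dissociation probabilities,
allostery metrics and a per-pair classification of force-response modes.

Running the MD itself (solvation, force fields, thermostats, the pulling
protocol) is out of scope by construction: the package starts from
coordinates.

## Model and statistics

**Hydrogen bonds.** A donor–hydrogen⋯acceptor triple qualifies in a frame
when the donor–acceptor distance is at most `max_da_distance` (default
3.5 Å) and the deviation of the D–H⋯A angle from linearity is at most
`max_dha_deviation` (default 30°, i.e. the angle itself is ≥ 150°). The
"deviation from linearity" reading of the angular criterion follows the
convention of the common MD analysis tools; both cutoffs are plain
arguments. Donor chemistry is deliberately simple and configurable: N and O
heavy atoms carrying a covalently attached hydrogen (≤ 1.25 Å, same
residue) donate; N and O accept. Structures lacking explicit hydrogens on
donor atoms are rejected with an error rather than silently scoring
nothing — hydrogen placement is a modelling step that belongs upstream.

**Occupancy.** The occupancy (survival ratio) of a residue pair is the
fraction of frames with at least one qualifying bond between the two
residues. Multiple simultaneous atom-level bonds between the same residues
count once — published per-pair occupancy tables are residue-pair granular,
and this collapsing matches them.

**Dissociation probability.** With per-bond occupancies $o_i$ and the
assumption that bonding events are independent and fully responsible for
binding, the probability that no bond is formed is

$$ f_D = \prod_i (1 - o_i). $$

This product is the unique probability of simultaneous absence under the
independence assumption; the package adopts it as *the* definition and
cross-checks it against joint Monte-Carlo simulation in the tests. An empty
bond set gives $f_D = 1$ (no bonds — certain dissociation) with a warning.
Profiles of $f_D$ over force are typically normalized to the zero-force (or
wild-type) mean, so the reference condition reads 1.

**Buried surface.** SASA uses the Shrake–Rupley construction with a 1.4 Å
water probe and Bondi van der Waals radii (hydrogens included — the systems
carry explicit hydrogens). The quadrature point set is a fixed
golden-section spiral (default 960 points/atom), so values are
bit-reproducible; refining the grid changes an isolated-atom surface by
well under 1%. Buried SASA is two-sided,
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$ — the magnitude
convention consistent with reported interface sizes on the order of
1600–1700 Å² for this class of complex.

**Interaction energy.** The interface energy between two selections sums
Coulomb ($k q_i q_j / r$, $k = 332.0636$ kcal·Å·mol⁻¹·e⁻²) and 12-6
Lennard-Jones terms (Lorentz–Berthelot combination) over cross pairs within
a 12 Å cutoff, both scaled by the standard polynomial switching function
over 10–12 Å so the energy is continuous at the boundary. No Ewald
summation or reaction field is attempted: a cross-selection lattice sum is
not well defined for an interface term, and ranking/trend analysis — the
use this quantity serves here — does not need it. Absolute values therefore
differ from any particular MD engine's report; orderings and force trends
are the meaningful output.

**Allostery metrics.** RMSD superposes each frame onto the reference by the
optimal least-squares rigid transform before scoring (delegated to bio3d's
Kabsch implementation; an independent SVD oracle guards it in the tests).
DMC is the distance between (mass-weighted, by default — "mass center"
taken literally) centers of two loop selections; the packaged defaults for
the DNAM-1/CD155 loops are residues 72–79 (receptor D1, C″–D loop) and
53–59 (ligand, B–C loop). The cross-angle κ between two β-strands is the
angle between the first principal axes of their Cα sets. The principal-axis
definition is a package choice — a strand "direction" has no unique
definition — and the angle is folded to [0°, 90°] so it is independent of
axis orientation; the raw signed angle is available via `fold = FALSE` for
trend plots. β-strand residue ranges for real structures must be supplied
by the user: automatic secondary-structure assignment is out of scope.

**Rupture force.** From a force–time trace, the rupture force is the
maximum of the moving-average-smoothed force (window 11 frames) restricted
to the window before the interface H-bond count first reaches zero. "The
force the complex sustains before letting go" has no standard formal
definition; smoothed pre-dissociation maximum is a transparent one, and the
window is a parameter. Traces that never dissociate fall back to the global
smoothed maximum with a warning.

**Mode classification.** A bond's occupancy over the ordered force grid is
reduced to a sign pattern of successive differences with a dead band
ε (default 0.05 occupancy units, applied to replicate means): rises are
`+`, falls are `−`, sub-ε changes drop out, runs collapse. The pattern maps
to `steady` (empty), `catch_slip` (`+−`, or pure `+` flagged
`pure_catch`), `slip_catch` (`−+` / `−`), `catch_slip_catch` (`+−+`),
`slip_catch_slip` (`−+−`); anything longer is `complex` with the raw
pattern preserved. Thresholds from `biphasic_threshold()` are reported on
the force grid only — no interpolation — because clamp campaigns measure at
grid forces and a sub-grid "threshold" would be an artifact of the curve
model, not the data.

**Replicate statistics.** Equilibrium comparisons aggregate replicates as
mean ± SD and are compared with the unpaired two-tailed equal-variance
Student's t test; force profiles aggregate as mean ± SE, the two
conventions used in this literature. Tukey's HSD is available for
multi-group comparisons. These are thin wrappers over the standard R
implementations.

## The synthetic generator: what it emulates, what it does not

Every downstream stage is validated against trajectories with *planted*
ground truth. `generate_complex()` lays out two glycine-like chains (five
backbone atoms per residue, 9 Å residue spacing, 12 Å chain separation —
far enough that no unplanted pair can ever satisfy the criteria), and for
each planted bond keeps two geometry templates: bound (donor–acceptor
2.9 Å, D–H⋯A deviation 10° — comfortably inside the cutoffs) and unbound
(5.0 Å — comfortably outside). `generate_trajectory()` draws each bond's
presence per frame as Bernoulli($o(F)$), switches the acceptor and hydrogen
between templates accordingly, and jitters every coordinate uniformly
within ±0.025 Å (max displacement < 0.05 Å, preserving detector margins on
both sides). The tests verify the planted presence matrix is recovered
*exactly*, frame by frame.

Occupancy-versus-force curves are Gaussian-bump parametrizations:
baseline ± amplitude·exp(−(F−F₀)²/2w²), with a sum of two bumps for the
triphasic modes. Published force-response thermographs for this system
report shapes, not functional forms, so the parametrization — and the
specific demo parameters — are package choices made once: the five-mode
demo set uses bumps centered at 50 pN (width 20 pN) for the biphasic modes
and 25/100 pN (widths 12/20 pN) for the triphasic ones, giving
step-to-step occupancy changes that are large against binomial sampling
noise at the study scale (2000 frames × 3 replicates). The clamp-campaign
demonstration plants its biphasic bonds at 25 pN, the threshold force
reported for this complex's dissociation probability.

Frames are i.i.d. by default: the occupancy statistic is a time fraction,
so dwell-time correlation adds nothing to its validation. A two-state
Markov option (`markov_rho`) with the same stationary occupancy exists for
users who want correlated survival times.

What the generator does *not* emulate: solvent, realistic backbone
dynamics, force-dependent geometry distortion, cooperative (non-independent)
bonding, or actual pulling mechanics. Passing tests on synthetic data
therefore demonstrate the *analysis layer* is correct — detection,
counting, statistics, classification — not that any MD result is
reproduced. The headline numbers of a real all-atom study (mean N_HB ≈ 9,
buried SASA ≈ 1680 Å², E ≈ −233 kcal/mol, rupture 200–250 pN for
DNAM-1/CD155) require the actual simulations; this package reproduces the
*countable and directional* results: the published per-pair occupancy
table's structure (12 pairs, 7 above the 0.40 cutoff), the direction of the
full-versus-truncated comparison (fD lower and N_HB higher with the second
receptor domain present), the vanishing of the D2-residue bond K190–E71
upon truncation, and threshold/mode recovery on planted curves.

## Numerical choices and degenerate inputs

- Units are fixed package-wide: Å, ns, pN, kcal/mol, degrees.
- Residue ranges use the author's (PDB) numbering, inclusive at both ends.
  An empty selection is an error, never an empty result — on real
  structures it almost always means an off-by-one or a residue missing
  from a truncated construct.
- Altloc: first location kept ('A' or blank); insertion codes rejected.
- The SASA sphere grid, the generator layout and every seed-derived RNG
  stream are deterministic: identical configuration and seeds give
  byte-identical reports.
- Replicate seeds derive from the base seed, the force level and the
  replicate index (kept below 2³¹), so each (system, force, replicate) run
  is reproducible in isolation.
- `fit_gaussian()` needs ≥ 4 distinct populated bins; it starts from sample
  moments and reports the moment estimates inside the error if the
  least-squares fit fails to converge.
- Zero-variance identical replicate groups compare at p = 1.
- Single-frame/single-replicate inputs are legal; their spreads are
  reported as 0 and flagged.

## Problem sizes used in the shipped checks

The test and acceptance runs use 6–12 residues per chain, 300–2000 frames,
2–3 replicates and the 0–100 pN grid in 25 pN steps. These sizes put
binomial sampling error well below every margin being asserted (3σ at
n = 2000 is ±0.031 at o = 0.5) while keeping the whole suite in the
minutes range on one core; they are analysis-scale choices, not physical
ones.

## Known limitations

- Donor/acceptor chemistry is element-based (N/O with H), not
  force-field-aware; unusual donors (S–H) need the configurable tables.
- The interface energy is a cutoff/switched sum — comparable within a
  study, not across engines or with free-energy methods.
- β-strand axes come from user-supplied residue ranges; no DSSP/STRIDE.
- The five-mode classifier sees the grid only: structure between grid
  forces is invisible, and very noisy profiles classify as `complex`
  rather than being forced into a named mode.
- fD's independence assumption ignores bond cooperativity; it is a
  comparative readout, not a kinetic model (no two-pathway Bell fitting).
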