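# mechbond

Trajectory analysis of protein–protein interface strength and its mechanical
regulation, for (steered) molecular dynamics simulations of receptor–ligand
complexes such as DNAM-1/CD155. The package is aimed at structural
bioinformaticians who already have equilibrium, force-clamp or force-ramp
trajectories in hand and want the downstream statistics: which residue pairs
hold the interface together, how strongly, and how tensile force reshapes
that picture (catch bonds, slip bonds and their transitions).

## What it computes

**Interface metrics.** A hydrogen-bonding event is scored in a frame when
the donor–acceptor distance and the donor–hydrogen⋯acceptor deviation from
linearity are below 3.5 Å and 30° (both configurable); salt bridges use a
4 Å cutoff between acidic-residue oxygens (Asp/Glu) and basic-residue
nitrogens (Lys/Arg). The *occupancy* (survival ratio) of a residue pair is
the fraction of frames in which at least one qualifying bond connects it.
Per-frame bond counts `N_HB`, Shrake–Rupley solvent-accessible surface area
(1.4 Å probe) with the standard two-sided buried-SASA definition
`SASA(A) + SASA(B) − SASA(AB)`, and a cutoff/switched pairwise nonbonded
interaction energy (Coulomb with k = 332.0636 kcal·Å·mol⁻¹·e⁻², 12-6
Lennard-Jones, 12 Å cutoff, switching from 10 Å) round out the per-frame
quantities.

**Dissociation probability.** Treating each interfacial hydrogen bond as an
independent Bernoulli event with probability equal to its occupancy `o_i`,
the probability that the interface is entirely unbonded is

```
fD = Π (1 − o_i)
```

which serves as a mechano-regulation readout once normalized to a reference
condition (zero force, or the wild-type system).

**Force response.** Profiles of any metric over an ordered clamp-force grid
(mean ± SE over replicates), biphasic-threshold detection (the grid force at
the interior extremum of the mean curve), Gaussian fits of the `N_HB`
frequency histogram, rupture-force extraction from force-ramp traces
(smoothed pre-dissociation maximum), and a five-way classification of each
residue pair's occupancy-versus-force shape: `steady`, `catch_slip`,
`slip_catch`, `catch_slip_catch`, `slip_catch_slip`.

**Allostery metrics.** Superposed Cα RMSD, steered–fixed atom distance,
distance between loop mass centers (DMC), and the cross-angle κ between two
β-strand axes (first principal component per strand, folded to [0°, 90°]).

**Synthetic ground truth.** A generator builds toy two-chain complexes whose
designated donor–acceptor pairs form hydrogen bonds per frame as Bernoulli
events following chosen occupancy-versus-force curves, with bound/unbound
geometry templates that respectively satisfy and violate the detection
criteria. Every analysis stage is validated against this planted truth.

## Worked example

Plant two bonds — one biphasic (catch–slip, occupancy peaked at 50 pN), one
steady — and run the force-clamp campaign over 0–100 pN, three replicates of
1000 frames each:

```r
library(mechbond)

specs <- list(
  bond_spec(c("A", 1), c("B", 1), "catch_slip", baseline = 0.3,
            amplitude = 0.4, center = 50, width = 20),
  bond_spec(c("A", 2), c("B", 2), "steady", baseline = 0.8))
cfg  <- generator_config(3, specs, n_frames = 1000, seed = 42)
cplx <- generate_complex(cfg)
selA <- select_residues(cplx, "A", c(1, 3))
selB <- select_residues(cplx, "B", c(1, 3))
runs <- lapply(cfg$force_grid, function(f)
  list(force = f, trajectories = lapply(1:3, function(r)
    generate_trajectory(cplx, cfg, f, replicate = r))))

rep <- run_force_clamp_analysis(runs, selA, selB)
rep
#> force-clamp report over 5 forces ( 0, 25, 50, 75, 100 pN )
#>   N_HB: biphasic threshold 50 pN (max)
#>   fD: biphasic threshold 50 pN (min)
#>   thermograph: 2 residue pairs

rep$profiles$fD
#> force_profile 'fD':
#>   force_pn       mean          se
#> 1        0 0.13324500 0.007286598
#> 2       25 0.11300700 0.003245705
#> 3       50 0.06328333 0.003028611
#> 4       75 0.10011500 0.005218277
#> 5      100 0.14692733 0.001236943

rep$thermograph
#>    res_a  res_b        F0       F25       F50       F75      F100       mode
#> 1 A:GLY2 B:GLY2 0.8013333 0.7830000 0.8003333 0.8103333 0.7866667     steady
#> 2 A:GLY1 B:GLY1 0.3296667 0.4793333 0.6820000 0.4726667 0.3110000 catch_slip
```

The dissociation probability dips exactly where the planted catch–slip bond
is strongest (50 pN) — the signature of a catch–slip transition — and the
thermograph recovers both planted mode labels from the measured occupancies.

For real structures, read a PDB with `read_structure()`, a DCD or
multi-frame XYZ with `read_trajectory()`, pick interface sides with
`select_residues()` (author numbering, chain mapping is explicit), then use
the same `run_equilibrium_analysis()` / `run_force_clamp_analysis()` /
`run_ramp_analysis()` entry points. `write_report()` exports every table as
TSV + JSON.

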