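Package: mechbond
Title: Interface Bond Occupancy and Force-Regulation Analysis for Steered MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for quantifying protein-protein
    interface strength and its mechanical regulation in (steered) molecular
    dynamics simulations. Detects geometric hydrogen bonds and salt bridges,
    computes per-pair bond occupancies, interfacial hydrogen-bond counts,
    Shrake-Rupley buried solvent-accessible surface area and pairwise
    nonbonded interaction energies; derives the interface dissociation
    probability under a bond-independence assumption, biphasic force
    thresholds, rupture forces from force-ramp traces, mass-center distance
    and beta-strand cross-angle allostery metrics; and classifies per-residue
    force responses into steady, catch-slip, slip-catch and triphasic bond
    modes. Ships a synthetic trajectory generator that plants force-dependent
    hydrogen bonds with known occupancy curves so every analysis stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
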