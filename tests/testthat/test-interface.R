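# Donor N (with H) on chain A facing acceptor O on chain B, at a chosen
# distance and hydrogen tilt.
hbond_pair_structure <- function(da = 2.9, h_tilt_deg = 0) {
  a <- h_tilt_deg * pi / 180
  toy_structure(name = c("N", "H", "O"),
                element = c("N", "H", "O"),
                resno = c(1L, 1L, 1L), chain = c("A", "A", "B"),
                xyz = rbind(c(0, 0, 0), c(sin(a), 0, cos(a)), c(0, 0, da)))
}

test_that("hydrogen-bond criteria gate on distance and linearity", {
  crit <- hbond_criteria()
  s <- hbond_pair_structure(da = 2.9, h_tilt_deg = 5)
  selA <- select_residues(s, "A", c(1, 1))
  selB <- select_residues(s, "B", c(1, 1))
  ev <- detect_hbonds(s, selA, selB, crit)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$da_distance, 2.9)
  expect_lt(ev$dha_deviation, 30)
  # distance failure
  s2 <- hbond_pair_structure(da = 3.6)
  expect_equal(nrow(detect_hbonds(s2, select_residues(s2, "A", c(1, 1)),
                                  select_residues(s2, "B", c(1, 1)), crit)),
               0L)
  # angle failure: hydrogen pointing sideways
  s3 <- hbond_pair_structure(da = 2.9, h_tilt_deg = 80)
  expect_equal(nrow(detect_hbonds(s3, select_residues(s3, "A", c(1, 1)),
                                  select_residues(s3, "B", c(1, 1)), crit)),
               0L)
})

test_that("structures without donor hydrogens raise a clear error", {
  s <- toy_structure(name = c("N", "O"), element = c("N", "O"),
                     resno = c(1L, 1L), chain = c("A", "B"),
                     xyz = rbind(c(0, 0, 0), c(0, 0, 2.9)))
  expect_error(detect_hbonds(s, select_residues(s, "A", c(1, 1)),
                             select_residues(s, "B", c(1, 1))),
               "hydrogen")
})

test_that("detector matches the exhaustive brute-force oracle", {
  for (seed in 1:12) {
    s <- random_frame(n_atoms = 50, seed = seed)
    n_res <- max(s$atoms$resno)
    selA <- select_residues(s, "A", c(1, n_res))
    selB <- select_residues(s, "B", c(1, n_res))
    ev <- detect_hbonds(s, selA, selB)
    expect_identical(event_keys(s, ev), oracle_hbonds(s, selA, selB),
                     info = paste("seed", seed))
  }
})

test_that("salt bridges respect residue classes and per-pair dedup", {
  mk <- function(resid_a, name_a, el_a, resid_b, name_b, el_b, d) {
    md_structure(data.frame(
      serial = 1:2, name = c(name_a, name_b), element = c(el_a, el_b),
      resno = c(1L, 2L), resid = c(resid_a, resid_b), chain = c("A", "B"),
      x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
  }
  s <- mk("GLU", "OE1", "O", "LYS", "NZ", "N", 3.5)
  sb <- detect_salt_bridges(s, select_residues(s, "A", c(1, 1)),
                            select_residues(s, "B", c(2, 2)))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_distance, 3.5)
  # Ser is not acidic
  s2 <- mk("SER", "OG", "O", "LYS", "NZ", "N", 3.5)
  expect_equal(nrow(detect_salt_bridges(s2, select_residues(s2, "A", c(1, 1)),
                                        select_residues(s2, "B", c(2, 2)))),
               0L)
  # two oxygens of one Asp within reach of one Arg nitrogen: one contact
  s3 <- md_structure(data.frame(
    serial = 1:3, name = c("OD1", "OD2", "NH1"),
    element = c("O", "O", "N"), resno = c(1L, 1L, 2L),
    resid = c("ASP", "ASP", "ARG"), chain = c("A", "A", "B"),
    x = c(0, 1, 2.5), y = 0, z = 0, stringsAsFactors = FALSE))
  sb3 <- detect_salt_bridges(s3, select_residues(s3, "A", c(1, 1)),
                             select_residues(s3, "B", c(2, 2)))
  expect_equal(nrow(sb3), 1L)
  expect_equal(sb3$min_distance, 1.5)
})

test_that("occupancy is the bonded-frame fraction and omits silent pairs", {
  spec <- bond_spec(c("A", 1), c("B", 1), "steady", baseline = 0.3)
  cfg <- generator_config(3, list(spec), n_frames = 100, seed = 41)
  s <- generate_complex(cfg)
  tr <- generate_trajectory(s, cfg, force = 0)
  selA <- select_residues(s, "A", c(1, 3))
  selB <- select_residues(s, "B", c(1, 3))
  tab <- occupancy(tr, selA, selB)
  planted_rate <- mean(attr(tr, "planted")[, 1])
  expect_equal(tab$occupancy, planted_rate)
  expect_equal(nrow(tab), 1L)  # never-bonded residues are absent
  # adding bond-free frames strictly lowers the occupancy
  longer <- md_trajectory(s, abind_frames(tr$coords,
                                          unbound_frames(s, cfg, 50)))
  tab2 <- occupancy(longer, selA, selB)
  expect_lt(tab2$occupancy, tab$occupancy)
  expect_equal(tab2$occupancy, planted_rate * 100 / 150)
})

test_that("per-frame H-bond counts sum planted bonds linearly", {
  cfg <- generator_config(6, demo_bond_specs(), n_frames = 2000, seed = 43)
  s <- generate_complex(cfg)
  tr <- generate_trajectory(s, cfg, force = 75)
  nhb <- hbond_count_series(tr, select_residues(s, "A", c(1, 6)),
                            select_residues(s, "B", c(1, 6)))
  o <- vapply(cfg$bond_specs, occupancy_curve, numeric(1), force = 75)
  sigma <- sqrt(sum(o * (1 - o)) / 2000)
  expect_lt(abs(mean(nhb) - sum(o)), 3 * sigma)
})

test_that("SASA reproduces analytic spheres and an independent grid", {
  lone <- toy_structure("C1", "C", 1L, "A", rbind(c(0, 0, 0)), "LIG")
  sel <- select_residues(lone, "A", c(1, 1))
  expect_equal(sasa(lone, sel), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # atom tightly caged by a shell of neighbours has no accessible surface
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1),
                c(0,0,-1), c(1,1,1)/sqrt(3), c(-1,-1,-1)/sqrt(3),
                c(1,-1,1)/sqrt(3), c(-1,1,-1)/sqrt(3),
                c(1,1,-1)/sqrt(3), c(-1,-1,1)/sqrt(3))
  shell <- toy_structure(paste0("C", 1:13), rep("C", 13), rep(1L, 13), "A",
                         rbind(c(0, 0, 0), dirs * 1.2), "LIG")
  per_atom <- mechbond:::.mb_sasa_per_atom(mb_coords(shell),
                                           rep(3.1, 13), 960)
  expect_equal(per_atom[1], 0)
  # two-atom system vs an independent latitude-longitude quadrature
  two <- rbind(c(0, 0, 0), c(0, 0, 2.4))
  s2 <- toy_structure(c("C1", "O1"), c("C", "O"), c(1L, 1L), c("A", "A"),
                      two, "LIG")
  got <- sasa(s2, select_residues(s2, "A", c(1, 1)))
  ref <- oracle_sasa_two_atoms(two, c(1.7, 1.52))
  expect_equal(got, ref, tolerance = 0.01)
})

test_that("buried SASA is symmetric, zero at separation, analytic at overlap", {
  far <- toy_structure(c("C1", "C2"), c("C", "C"), c(1L, 2L), c("A", "B"),
                       rbind(c(0, 0, 0), c(100, 0, 0)), "LIG")
  a <- select_residues(far, "A", c(1, 1)); b <- select_residues(far, "B", c(2, 2))
  expect_equal(buried_sasa(far, a, b), 0, tolerance = 1)
  # touching carbons: buried area equals the two spherical caps
  d <- 3.0
  near <- toy_structure(c("C1", "C2"), c("C", "C"), c(1L, 2L), c("A", "B"),
                        rbind(c(0, 0, 0), c(d, 0, 0)), "LIG")
  a2 <- select_residues(near, "A", c(1, 1))
  b2 <- select_residues(near, "B", c(2, 2))
  R <- 1.7 + 1.4
  analytic_buried <- 2 * (4 * pi * R^2) - analytic_two_sphere_sasa(R, R, d)
  got <- buried_sasa(near, a2, b2)
  expect_equal(got, analytic_buried, tolerance = 0.02 * analytic_buried)
  expect_identical(got, buried_sasa(near, b2, a2))
  expect_error(buried_sasa(near, a2, a2), "disjoint|overlap")
})

para_pair <- function(d, q = c(1, -1), eps = c(0, 0), rmin_half = c(1, 1)) {
  md_structure(data.frame(
    serial = 1:2, name = c("Q1", "Q2"), element = c("N", "N"),
    resno = c(1L, 2L), resid = "LIG", chain = c("A", "B"),
    x = c(0, d), y = 0, z = 0, charge = q, eps = eps,
    rmin_half = rmin_half, stringsAsFactors = FALSE))
}

test_that("interaction energy matches closed forms and cutoff behavior", {
  s <- para_pair(3)
  a <- select_residues(s, "A", c(1, 1)); b <- select_residues(s, "B", c(2, 2))
  e <- interaction_energy(s, a, b)
  expect_equal(e$electrostatic, 332.0636 * (1) * (-1) / 3, tolerance = 1e-12)
  expect_equal(e$electrostatic, -110.69, tolerance = 1e-4)
  expect_identical(e$total, e$electrostatic + e$van_der_waals)
  # LJ minimum: identical neutral atoms at r = Rmin give -eps
  s2 <- para_pair(3, q = c(0, 0), eps = c(0.25, 0.25),
                  rmin_half = c(1.5, 1.5))
  e2 <- interaction_energy(s2, select_residues(s2, "A", c(1, 1)),
                           select_residues(s2, "B", c(2, 2)))
  expect_equal(e2$van_der_waals, -0.25, tolerance = 1e-12)
  # beyond the cutoff: exactly zero
  s3 <- para_pair(13)
  e3 <- interaction_energy(s3, select_residues(s3, "A", c(1, 1)),
                           select_residues(s3, "B", c(2, 2)))
  expect_identical(e3$total, 0)
  # missing parameters are an error naming the atoms
  s4 <- s; s4$atoms$charge <- NA_real_
  expect_error(interaction_energy(s4, select_residues(s4, "A", c(1, 1)),
                                  select_residues(s4, "B", c(2, 2))),
               "parameters")
})

test_that("switching keeps the energy continuous and the terms symmetric", {
  # no jump at the cutoff boundary
  s_edge <- para_pair(11.999999)
  e_in <- interaction_energy(s_edge, select_residues(s_edge, "A", c(1, 1)),
                             select_residues(s_edge, "B", c(2, 2)))
  expect_lt(abs(e_in$total), 1e-6)
  # switching factor is 1 below switch-on and decreases smoothly
  sw <- mechbond:::.mb_switching(c(5, 10, 10.5, 11.5, 12, 13), 10, 12)
  expect_equal(sw[1:2], c(1, 1))
  expect_true(all(diff(sw) <= 0))
  expect_equal(sw[5:6], c(0, 0))
  # symmetry in the two selections
  s <- para_pair(4, q = c(0.6, -0.8), eps = c(0.1, 0.2),
                 rmin_half = c(1.2, 1.7))
  aa <- select_residues(s, "A", c(1, 1)); bb <- select_residues(s, "B", c(2, 2))
  expect_identical(interaction_energy(s, aa, bb)$total,
                   interaction_energy(s, bb, aa)$total)
})
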