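test_that("occupancy curves realize the five mode shapes", {
  st <- bond_spec(c("A", 1), c("B", 1), "steady", baseline = 0.5)
  expect_equal(occupancy_curve(st, c(0, 10, 200)), rep(0.5, 3))
  cs <- bond_spec(c("A", 1), c("B", 1), "catch_slip", baseline = 0.3,
                  amplitude = 0.4, center = 50, width = 20)
  o <- occupancy_curve(cs, c(0, 50, 100))
  expect_gt(o[2], o[1]); expect_gt(o[2], o[3])
  # mirrored slip-catch: o_sc = 1 - o_cs when baselines are complementary
  sc <- bond_spec(c("A", 1), c("B", 1), "slip_catch", baseline = 0.7,
                  amplitude = 0.4, center = 50, width = 20)
  f <- seq(0, 100, by = 5)
  expect_equal(occupancy_curve(sc, f), 1 - occupancy_curve(cs, f))
  # triphasic curves have the planted turning structure on the grid
  csc <- demo_bond_specs()$catch_slip_catch
  ocsc <- occupancy_curve(csc, c(0, 25, 50, 75, 100))
  expect_true(ocsc[2] > ocsc[1] && ocsc[3] < ocsc[2] && ocsc[5] > ocsc[3])
  expect_true(all(occupancy_curve(csc, seq(0, 200, 0.5)) >= 0 &
                    occupancy_curve(csc, seq(0, 200, 0.5)) <= 1))
  expect_error(occupancy_curve(st, -5), ">= 0")
})

test_that("curve parameters leaving [0,1] are rejected at construction", {
  expect_error(bond_spec(c("A", 1), c("B", 1), "catch_slip",
                         baseline = 0.9, amplitude = 0.4), "\\[0, 1\\]")
  expect_error(bond_spec(c("A", 1), c("B", 1), "slip_catch",
                         baseline = 0.2, amplitude = 0.5), "\\[0, 1\\]")
  expect_error(bond_spec(c("A", 1), c("B", 1), "nonsense"), "mode")
})

test_that("generated complex has the planted topology and is deterministic", {
  cfg <- generator_config(5, demo_bond_specs()[1:2], n_frames = 1, seed = 9)
  s <- generate_complex(cfg)
  expect_equal(sort(unique(s$atoms$chain)), c("A", "B"))
  expect_equal(length(unique(paste(s$atoms$chain, s$atoms$resno))), 10L)
  expect_equal(nrow(s$atoms), 50L)
  s2 <- generate_complex(cfg)
  expect_identical(mb_coords(s), mb_coords(s2))
  tr1 <- generate_trajectory(s, cfg, force = 25, replicate = 2)
  tr2 <- generate_trajectory(s, cfg, force = 25, replicate = 2)
  expect_identical(tr1$coords, tr2$coords)
  expect_error(generator_config(5, list(bond_spec(c("A", 99), c("B", 1))),
                                n_frames = 1), "residue 99")
})

test_that("degenerate occupancies plant exactly always/never-bound pairs", {
  specs <- list(bond_spec(c("A", 1), c("B", 1), "steady", baseline = 1),
                bond_spec(c("A", 2), c("B", 2), "steady", baseline = 0))
  cfg <- generator_config(3, specs, n_frames = 100, seed = 5)
  s <- generate_complex(cfg)
  tr <- generate_trajectory(s, cfg, force = 0)
  selA <- select_residues(s, "A", c(1, 3))
  selB <- select_residues(s, "B", c(1, 3))
  tab <- occupancy(tr, selA, selB)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 1.0)
  expect_match(tab$res_a, "GLY1$")
})

test_that("detected occupancy tracks the planted rate within binomial bounds", {
  spec <- bond_spec(c("A", 1), c("B", 1), "steady", baseline = 0.7)
  cfg <- generator_config(2, list(spec), n_frames = 2000, seed = 17)
  s <- generate_complex(cfg)
  tr <- generate_trajectory(s, cfg, force = 0)
  tab <- occupancy(tr, select_residues(s, "A", c(1, 2)),
                   select_residues(s, "B", c(1, 2)))
  expect_lt(abs(tab$occupancy - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
})

test_that("detector and generator agree frame-by-frame on planted bonds", {
  cfg <- generator_config(6, demo_bond_specs(), n_frames = 300, seed = 23)
  s <- generate_complex(cfg)
  selA <- select_residues(s, "A", c(1, 6))
  selB <- select_residues(s, "B", c(1, 6))
  for (force in c(0, 50)) {
    tr <- generate_trajectory(s, cfg, force)
    planted <- attr(tr, "planted")
    for (f in c(1, 57, 300)) {
      ev <- detect_hbonds(mb_frame(tr, f), selA, selB)
      got <- sort(ev$donor_resno)
      want <- sort(vapply(which(planted[f, ]),
                          function(b) cfg$bond_specs[[b]]$donor$resno,
                          integer(1)))
      expect_identical(got, want)
    }
    # whole-trajectory presence equals the planted matrix
    nhb <- hbond_count_series(tr, selA, selB)
    expect_identical(nhb, as.integer(rowSums(planted)))
  }
})

test_that("markov persistence keeps the stationary occupancy", {
  spec <- bond_spec(c("A", 1), c("B", 1), "steady", baseline = 0.6)
  cfg <- generator_config(2, list(spec), n_frames = 4000, seed = 31,
                          markov_rho = 0.8)
  s <- generate_complex(cfg)
  tr <- generate_trajectory(s, cfg, force = 0)
  occ <- mean(attr(tr, "planted")[, 1])
  # correlated frames: allow 3 sigma of the effective sample size
  n_eff <- 4000 * (1 - 0.8) / (1 + 0.8)
  expect_lt(abs(occ - 0.6), 3 * sqrt(0.6 * 0.4 / n_eff))
})

test_that("generator YAML configs load into equivalent objects", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_residues_per_chain: 4",
    "n_frames: 50",
    "seed: 7",
    "force_grid: [0, 25, 50]",
    "bond_specs:",
    "  - donor: [A, 1]",
    "    acceptor: [B, 1]",
    "    mode: catch_slip",
    "    baseline: 0.3",
    "    amplitude: 0.4",
    "    center: 25",
    "    width: 15"), path)
  cfg <- load_generator_config(path)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$bond_specs[[1]]$mode, "catch_slip")
  expect_equal(cfg$force_grid, c(0, 25, 50))
  s <- generate_complex(cfg)
  expect_equal(nrow(s$atoms), 40L)
})
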