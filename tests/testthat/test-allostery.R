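rigid_motion <- function(xyz, angle = 0.6, axis = c(0, 0, 1),
                         shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, `+`)
}

test_that("RMSD is zero under exact rigid motion and matches the SVD oracle", {
  set.seed(12)
  xyz <- matrix(rnorm(30), ncol = 3)
  s <- toy_structure(paste0("CA", 1:10), rep("C", 10), 1:10, "A", xyz)
  sel <- select_residues(s, "A", c(1, 10))
  moved <- rigid_motion(xyz)
  tr <- md_trajectory(s, list(xyz, moved))
  r <- rmsd_series(tr, sel)
  expect_equal(r[1], 0, tolerance = 1e-8)
  expect_lt(r[2], 1e-6)
  # deformed frame: implementation agrees with the independent Kabsch oracle
  deformed <- xyz; deformed[4, ] <- deformed[4, ] + c(2, 0, 0)
  deformed <- rigid_motion(deformed, angle = -1.1, shift = c(-4, 7, 0))
  tr2 <- md_trajectory(s, list(xyz, deformed))
  expect_equal(rmsd_series(tr2, sel)[2], oracle_rmsd(xyz, deformed),
               tolerance = 1e-6)
  # 4-point case frozen from the oracle
  ref4 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob4 <- ref4; mob4[4, 3] <- 4
  s4 <- toy_structure(paste0("CA", 1:4), rep("C", 4), 1:4, "A", ref4)
  tr4 <- md_trajectory(s4, list(ref4, mob4))
  expect_equal(rmsd_series(tr4, select_residues(s4, "A", c(1, 4)))[2],
               oracle_rmsd(ref4, mob4), tolerance = 1e-6)
})

test_that("pull distance is Euclidean and translation-invariant", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  s <- toy_structure(c("CA1", "CA2"), c("C", "C"), 1:2, "A", xyz)
  tr <- md_trajectory(s, list(xyz, sweep(xyz, 2, c(10, -5, 2), `+`),
                              rbind(c(1, 1, 1), c(1, 1, 1))))
  d <- pull_distance_series(tr, 1L, 2L)
  expect_equal(d, c(5, 5, 0))
  expect_error(pull_distance_series(tr, 1L, 99L), "out of range")
})

test_that("mass-center distance handles centroids, masses and symmetry", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0))
  s <- toy_structure(c("C1", "C2", "C3"), c("C", "C", "C"),
                     c(1L, 1L, 2L), c("A", "A", "B"), xyz, "LIG")
  l1 <- select_residues(s, "A", c(1, 1)); l2 <- select_residues(s, "B", c(2, 2))
  # equal-mass two-atom loop centroid (1,0,0) vs (1,5,0)
  expect_equal(dmc(s, l1, l2), 5)
  expect_equal(dmc(s, l1, l2), dmc(s, l2, l1))
  expect_equal(dmc(s, l1, l1), 0)
  # translation invariance
  expect_equal(dmc(rigid_motion(xyz, angle = 0), l1, l2), 5)
  # unequal masses shift the center: C at 0, O at 2 -> center x = 16/28
  s2 <- toy_structure(c("C1", "O1", "C3"), c("C", "O", "C"),
                      c(1L, 1L, 2L), c("A", "A", "B"), xyz, "LIG")
  l1b <- select_residues(s2, "A", c(1, 1))
  l2b <- select_residues(s2, "B", c(2, 2))
  mx <- 2 * 15.999 / (12.011 + 15.999)
  expect_equal(dmc(s2, l1b, l2b), sqrt((1 - mx)^2 + 25))
  expect_equal(dmc(s2, l1b, l2b, mass_weighted = FALSE), 5)
})

test_that("cross-angle reproduces analytic axes and stays in [0, 90]", {
  mk_strands <- function(dirB) {
    t <- 0:3
    xyz <- rbind(cbind(t, 0, 0),
                 cbind(t * dirB[1], t * dirB[2], t * dirB[3]) +
                   matrix(rep(c(0, 10, 0), 4), ncol = 3, byrow = TRUE))
    toy_structure(paste0("CA", 1:8), rep("C", 8), c(1:4, 5:8),
                  rep(c("A", "B"), each = 4), xyz)
  }
  s90 <- mk_strands(c(0, 1, 0))
  a <- select_residues(s90, "A", c(1, 4)); b <- select_residues(s90, "B", c(5, 8))
  expect_equal(cross_angle(s90, a, b), 90)
  s0 <- mk_strands(c(1, 0, 0))
  expect_equal(cross_angle(s0, select_residues(s0, "A", c(1, 4)),
                           select_residues(s0, "B", c(5, 8))), 0,
               tolerance = 1e-6)
  s45 <- mk_strands(c(1, 1, 0) / sqrt(2))
  expect_equal(cross_angle(s45, select_residues(s45, "A", c(1, 4)),
                           select_residues(s45, "B", c(5, 8))), 45,
               tolerance = 1e-6)
  # symmetry under relabeling and rigid motion; folding bound
  expect_equal(cross_angle(s45, select_residues(s45, "B", c(5, 8)),
                           select_residues(s45, "A", c(1, 4))), 45,
               tolerance = 1e-6)
  moved <- rigid_motion(mb_coords(s45))
  expect_equal(cross_angle(moved, select_residues(s45, "A", c(1, 4)),
                           select_residues(s45, "B", c(5, 8))), 45,
               tolerance = 1e-6)
  s135 <- mk_strands(c(-1, 1, 0) / sqrt(2))
  ang <- cross_angle(s135, select_residues(s135, "A", c(1, 4)),
                     select_residues(s135, "B", c(5, 8)))
  expect_equal(ang, 45, tolerance = 1e-6)  # folded from 135
  expect_equal(cross_angle(s135, select_residues(s135, "A", c(1, 4)),
                           select_residues(s135, "B", c(5, 8)),
                           fold = FALSE), 135, tolerance = 1e-6)
  # degenerate strand
  sdeg <- toy_structure(paste0("CA", 1:6), rep("C", 6), 1:6,
                        rep(c("A", "B"), each = 3),
                        rbind(matrix(0, 3, 3), cbind(0:2, 0, 0)))
  expect_error(cross_angle(sdeg, select_residues(sdeg, "A", c(1, 3)),
                           select_residues(sdeg, "B", c(4, 6))),
               "degenerate")
})

test_that("rupture force finds the pre-dissociation smoothed maximum", {
  # plateaued peak at 240 pN wide enough to survive the smoothing window
  tt <- seq(0, 20, length.out = 201)
  ff <- pmin(240, 30 * tt)
  ff[tt > 10] <- pmax(0, 240 - 60 * (tt[tt > 10] - 10))
  ff[tt >= 8 & tt <= 10] <- 240
  nhb <- ifelse(tt < 10.5, 3L, 0L)
  res <- rupture_force(force_trace(tt, ff, nhb))
  expect_equal(res$rupture_force, 240)
  expect_true(res$dissociated)
  # monotone rising trace without dissociation: warning + final value
  tr2 <- force_trace(tt, 10 * tt)
  expect_warning(res2 <- rupture_force(tr2), "global")
  expect_equal(res2$rupture_force, max(mechbond:::.mb_moving_average(10 * tt, 11L)))
  expect_false(res2$dissociated)
  # noisy plateaued peak recovered within 10 pN
  set.seed(99)
  noisy <- force_trace(tt, ff + rnorm(length(tt), 0, 10), nhb)
  expect_lt(abs(rupture_force(noisy, window = 11L)$rupture_force - 240), 10)
  # trace file round trip
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(time_ns = tt, force_pn = ff, n_hb = nhb),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  tr3 <- read_force_trace(path)
  expect_equal(rupture_force(tr3)$rupture_force, 240)
})
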