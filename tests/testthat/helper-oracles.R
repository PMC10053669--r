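# Independent oracles and fixture builders shared by the test files.
# Everything here is deliberately naive (triple loops, closed forms,
# Monte-Carlo) and shares no code path with the package internals it checks.

# ---- structure builders -------------------------------------------------

# Minimal structure from a coordinate table.
toy_structure <- function(name, element, resno, chain, xyz,
                          resid = "GLY") {
  md_structure(data.frame(
    serial = seq_along(name), name = name, element = element,
    resno = resno, resid = rep_len(resid, length(name)), chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# Random two-chain frame with N/O/C/H atoms packed into a box, for
# brute-force comparison. Residues get one heavy atom + one hydrogen each so
# donor-H association is exercised.
random_frame <- function(n_atoms = 50, box = 8, seed = 1) {
  set.seed(seed)
  n_res <- n_atoms %/% 2L
  heavy_el <- sample(c("N", "O", "C"), n_res, replace = TRUE)
  resno <- seq_len(n_res)
  chain <- ifelse(resno <= n_res / 2, "A", "B")
  heavy_xyz <- matrix(runif(n_res * 3, 0, box), ncol = 3)
  # hydrogen near its heavy atom (sometimes beyond the covalent cutoff, so
  # attachment logic is tested too)
  h_off <- matrix(rnorm(n_res * 3), ncol = 3)
  h_off <- h_off / sqrt(rowSums(h_off^2)) * runif(n_res, 0.9, 1.6)
  h_xyz <- heavy_xyz + h_off
  toy_structure(
    name = c(paste0(heavy_el, resno), paste0("H", resno)),
    element = c(heavy_el, rep("H", n_res)),
    resno = c(resno, resno), chain = c(chain, chain),
    xyz = rbind(heavy_xyz, h_xyz))
}

# ---- brute-force hydrogen-bond oracle ----------------------------------

# Exhaustive enumeration over all (donor, hydrogen, acceptor) triples; no
# vectorization, no candidate pruning.
oracle_hbonds <- function(structure, selA, selB,
                          max_da = 3.5, max_dev = 30, max_dh = 1.25) {
  at <- structure$atoms
  xyz <- mb_coords(structure)
  found <- character(0)
  dirs <- list(c(1, 2), c(2, 1))
  sels <- list(selA$indices, selB$indices)
  for (dir in dirs) {
    don_side <- sels[[dir[1]]]; acc_side <- sels[[dir[2]]]
    for (d in don_side) {
      if (!(at$element[d] %in% c("N", "O"))) next
      for (h in don_side) {
        if (at$element[h] != "H") next
        if (at$chain[h] != at$chain[d] || at$resno[h] != at$resno[d]) next
        if (sqrt(sum((xyz[h, ] - xyz[d, ])^2)) > max_dh) next
        for (a in acc_side) {
          if (!(at$element[a] %in% c("N", "O"))) next
          if (a == d) next
          da <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
          if (da > max_da) next
          v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          dev <- 180 - acos(min(1, max(-1, cosang))) * 180 / pi
          if (dev > max_dev) next
          found <- c(found, paste(d, h, a))
        }
      }
    }
  }
  sort(found)
}

# Key set from a detect_hbonds result, for comparison with the oracle.
event_keys <- function(structure, events) {
  if (nrow(events) == 0L) return(character(0))
  at <- structure$atoms
  find <- function(ch, rn, nm)
    which(at$chain == ch & at$resno == rn & at$name == nm)
  keys <- vapply(seq_len(nrow(events)), function(i) {
    d <- find(events$donor_chain[i], events$donor_resno[i],
              events$donor_atom[i])
    h <- find(events$donor_chain[i], events$donor_resno[i],
              events$hydrogen[i])
    a <- find(events$acceptor_chain[i], events$acceptor_resno[i],
              events$acceptor_atom[i])
    paste(d, h, a)
  }, "")
  sort(keys)
}

# ---- Kabsch superposition oracle ---------------------------------------

# Plain SVD Kabsch + RMSD, independent of the bio3d-backed implementation.
oracle_rmsd <- function(ref, mob) {
  cr <- colMeans(ref); cm <- colMeans(mob)
  A <- sweep(mob, 2, cm); B <- sweep(ref, 2, cr)
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  sqrt(mean(rowSums((fitted - B)^2)))
}

# ---- SASA oracles -------------------------------------------------------

# Shrake-Rupley with an independent latitude-longitude quadrature grid.
oracle_sasa_two_atoms <- function(xyz, radii, probe = 1.4,
                                  n_lat = 100, n_lon = 100) {
  r <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    theta <- (seq_len(n_lat) - 0.5) * pi / n_lat
    phi <- (seq_len(n_lon) - 0.5) * 2 * pi / n_lon
    grid <- expand.grid(theta = theta, phi = phi)
    pts <- cbind(sin(grid$theta) * cos(grid$phi),
                 sin(grid$theta) * sin(grid$phi),
                 cos(grid$theta)) * r[i]
    pts <- sweep(pts, 2, xyz[i, ], `+`)
    w <- sin(grid$theta) * (pi / n_lat) * (2 * pi / n_lon) * r[i]^2
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ])^2))
      exposed <- exposed & dj > r[j]
    }
    total <- total + sum(w[exposed])
  }
  total
}

# Closed-form SASA of two intersecting accessible spheres (cap removal).
analytic_two_sphere_sasa <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  (4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)) +
    (4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# ---- Monte-Carlo dissociation oracle -----------------------------------

mc_dissociation <- function(occupancies, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  none <- rep(TRUE, n_draws)
  for (o in occupancies) none <- none & (runif(n_draws) >= o)
  mean(none)
}

# ---- misc ---------------------------------------------------------------

# Hand-written PDB text for a tiny structure.
write_toy_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   GLY B   2       3.000   1.200   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# Two-system (full vs truncated) generator pair used by the end-to-end
# comparisons: steady bonds planted with the packaged equilibrium occupancy
# table. The truncated variant drops the bond whose donor residue does not
# exist after truncation.
published_occupancy_configs <- function(n_frames = 600, seed = 11) {
  tab <- equilibrium_occupancy_table()
  n <- nrow(tab)  # 12 bonds
  # chain A residues 179-190 (donors; 190 is the D2 residue lost on
  # truncation), chain B residues 60-71 (acceptors)
  donors <- 179:190
  acceptors <- 60:71
  spec_for <- function(occ, i) bond_spec(c("A", donors[i]),
                                         c("B", acceptors[i]),
                                         "steady", baseline = occ)
  wt_specs <- lapply(seq_len(n), function(i) spec_for(tab$wt_occupancy[i], i))
  dd2_keep <- which(donors != 190)
  dd2_specs <- lapply(dd2_keep, function(i)
    spec_for(tab$dd2_occupancy[i], i))
  list(
    wt = generator_config(12, wt_specs, n_frames, seed = seed,
                          resno_start = c(A = 179L, B = 60L)),
    dd2 = generator_config(11, dd2_specs, n_frames, seed = seed + 1,
                           resno_start = c(A = 179L, B = 60L)))
}

# Replicated trajectories for a config at one force.
replicate_runs <- function(config, force, n_rep = 3) {
  s <- generate_complex(config)
  lapply(seq_len(n_rep), function(r)
    generate_trajectory(s, config, force, replicate = r))
}

# Concatenate two frame arrays along the frame dimension.
abind_frames <- function(arr1, arr2) {
  out <- array(NA_real_, c(dim(arr1)[1] + dim(arr2)[1], dim(arr1)[2], 3L))
  out[seq_len(dim(arr1)[1]), , ] <- arr1
  out[dim(arr1)[1] + seq_len(dim(arr2)[1]), , ] <- arr2
  out
}

# n copies of the all-unbound reference geometry (no planted bond present).
unbound_frames <- function(structure, config, n) {
  ref <- mb_coords(structure)
  out <- array(NA_real_, c(n, nrow(ref), 3L))
  for (i in seq_len(n)) out[i, , ] <- ref
  out
}
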