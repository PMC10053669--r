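#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Classic rolling-probe quadrature: each atom's solvent-accessible sphere of
#' radius r_vdw + r_probe is sampled with a fixed, deterministic point set (a
#' golden-section spiral, so results are bit-reproducible for a given point
#' count); points falling inside any neighbour's accessible sphere are
#' occluded, and the exposed fraction times the sphere area is the atom's
#' contribution.
#'
#' @param frame an \code{md_structure} (or coordinate matrix matching
#'   \code{selection}'s structure)
#' @param selection \code{md_selection} of the atoms whose SASA is summed;
#'   only these atoms occlude each other (the selection is treated as the
#'   whole molecule)
#' @param probe probe radius, Angstrom (water = 1.4)
#' @param n_sphere_points quadrature points per atom
#' @param radii named element -> van der Waals radius table
#' @return total SASA in Angstrom^2.
#' @export
sasa <- function(frame, selection, probe = 1.4, n_sphere_points = 960,
                 radii = mb_vdw_radii()) {
  .mb_check_selection(selection)
  s <- selection$structure
  xyz_all <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  idx <- selection$indices
  xyz <- xyz_all[idx, , drop = FALSE]
  elem <- s$atoms$element[idx]
  r <- .mb_lookup_element(elem, radii, "SASA radii") + probe
  sum(.mb_sasa_per_atom(xyz, r, n_sphere_points))
}

# Deterministic unit sphere point set: golden-section spiral.
.mb_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.mb_sasa_per_atom <- function(xyz, r, n_sphere_points) {
  n <- nrow(xyz)
  pts <- .mb_sphere_points(n_sphere_points)
  out <- numeric(n)
  # neighbour lists via squared-distance threshold (r_i + max r_j)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (r[i] + r)^2
    nb <- which(d2[i, ] <= cutoff2 & seq_len(n) != i)
    if (length(nb) == 0L) { out[i] <- 4 * pi * r[i]^2; next }
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    # occluded if inside any neighbour sphere
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (sp[exposed, 1] - xyz[j, 1])^2 + (sp[exposed, 2] - xyz[j, 2])^2 +
        (sp[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj2 > r[j]^2
    }
    out[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_sphere_points
  }
  out
}

#' Buried surface area of an interface
#'
#' The standard two-sided definition: SASA(A alone) + SASA(B alone) -
#' SASA(A and B together). Non-negative up to quadrature error and symmetric
#' in the two selections.
#'
#' @inheritParams sasa
#' @param selA,selB disjoint \code{md_selection}s
#' @return buried SASA in Angstrom^2.
#' @export
buried_sasa <- function(frame, selA, selB, probe = 1.4,
                        n_sphere_points = 960, radii = mb_vdw_radii()) {
  .mb_check_selection(selA); .mb_check_selection(selB)
  .mb_check_disjoint(selA, selB)
  s <- selA$structure
  joint <- structure(list(structure = s,
                          indices = c(selA$indices, selB$indices),
                          label = paste(selA$label, "+", selB$label)),
                     class = "md_selection")
  sasa(frame, selA, probe, n_sphere_points, radii) +
    sasa(frame, selB, probe, n_sphere_points, radii) -
    sasa(frame, joint, probe, n_sphere_points, radii)
}

#' Buried-SASA time series over a trajectory
#'
#' @inheritParams buried_sasa
#' @param trajectory an \code{md_trajectory}
#' @param stride compute every \code{stride}-th frame (SASA is the costly
#'   metric; strided series are standard practice)
#' @return data.frame with \code{frame} and \code{buried_sasa} columns.
#' @export
buried_sasa_series <- function(trajectory, selA, selB, probe = 1.4,
                               n_sphere_points = 960, stride = 1L,
                               radii = mb_vdw_radii()) {
  frames <- seq(1L, mb_n_frames(trajectory), by = stride)
  vals <- vapply(frames, function(i)
    buried_sasa(mb_frame(trajectory, i), selA, selB, probe, n_sphere_points,
                radii), numeric(1))
  data.frame(frame = frames, buried_sasa = vals)
}
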