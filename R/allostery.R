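#' C-alpha RMSD series with optimal superposition
#'
#' Per frame, the selected atoms are superposed onto the reference frame by
#' the optimal least-squares rigid-body transform (Kabsch) before the RMSD is
#' taken, so global translation/rotation of a frame does not register as
#' deviation. The superposition and RMSD are delegated to \pkg{bio3d}.
#'
#' @param trajectory an \code{md_trajectory}
#' @param selection \code{md_selection} of the atoms to superpose and score
#'   (typically the C-alpha set)
#' @param reference reference frame index (default 1) or an n_atoms x 3
#'   coordinate matrix for the whole structure
#' @return numeric vector of per-frame RMSD values, Angstrom.
#' @export
rmsd_series <- function(trajectory, selection, reference = 1L) {
  .mb_check_selection(selection)
  idx <- selection$indices
  ref_xyz <- if (is.matrix(reference)) reference else
    mb_frame(trajectory, reference)
  if (nrow(ref_xyz) != dim(trajectory$coords)[2])
    stop("reference does not match the trajectory's topology", call. = FALSE)
  ref <- as.vector(t(ref_xyz[idx, , drop = FALSE]))
  n_frames <- mb_n_frames(trajectory)
  mob <- matrix(NA_real_, n_frames, length(idx) * 3L)
  for (i in seq_len(n_frames))
    mob[i, ] <- as.vector(t(mb_frame(trajectory, i)[idx, , drop = FALSE]))
  inds <- seq_len(length(idx) * 3L)
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = mob,
                           fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  dev2 <- sweep(fitted, 2, ref)^2
  sqrt(rowSums(dev2) / length(idx))
}

#' Steered-atom to fixed-atom distance series
#'
#' @param trajectory an \code{md_trajectory}
#' @param steered_atom,fixed_atom atom indices (see
#'   \code{\link{select_atom}})
#' @return numeric vector of per-frame Euclidean distances, Angstrom.
#' @export
pull_distance_series <- function(trajectory, steered_atom, fixed_atom) {
  n <- dim(trajectory$coords)[2]
  if (any(c(steered_atom, fixed_atom) < 1L) ||
      any(c(steered_atom, fixed_atom) > n))
    stop("atom index out of range", call. = FALSE)
  d <- trajectory$coords[, steered_atom, , drop = FALSE] -
    trajectory$coords[, fixed_atom, , drop = FALSE]
  sqrt(rowSums(matrix(d, ncol = 3L)^2))
}

#' Distance between mass centers of two selections (DMC)
#'
#' The allostery metric: distance between the (mass-weighted, by default)
#' centers of two loop regions, e.g. the C''-D loop of the receptor's
#' membrane-distal domain and the B-C loop of the ligand.
#'
#' @param frame an \code{md_structure} or coordinate matrix
#' @param loop1,loop2 \code{md_selection}s
#' @param mass_weighted use atomic masses (TRUE) or the geometric centroid
#' @return distance in Angstrom.
#' @export
dmc <- function(frame, loop1, loop2, mass_weighted = TRUE) {
  .mb_check_selection(loop1); .mb_check_selection(loop2)
  xyz <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  cen <- function(sel) {
    sub <- xyz[sel$indices, , drop = FALSE]
    if (mass_weighted) {
      m <- .mb_lookup_element(sel$structure$atoms$element[sel$indices],
                              mb_atomic_masses(), "mass center")
      colSums(sub * m) / sum(m)
    } else colMeans(sub)
  }
  sqrt(sum((cen(loop1) - cen(loop2))^2))
}

#' DMC time series
#' @inheritParams dmc
#' @param trajectory an \code{md_trajectory}
#' @return numeric vector, Angstrom per frame.
#' @export
dmc_series <- function(trajectory, loop1, loop2, mass_weighted = TRUE) {
  vapply(seq_len(mb_n_frames(trajectory)), function(i)
    dmc(mb_frame(trajectory, i), loop1, loop2, mass_weighted), numeric(1))
}

#' Cross-angle between two beta-strand axes
#'
#' Each strand's axis is the first principal component of its C-alpha
#' coordinates; the angle between the two axes is folded to [0, 90] degrees
#' (arccos of the absolute unit dot product) so the metric is independent of
#' axis orientation. Set \code{fold = FALSE} for the raw [0, 180] angle when
#' a signed trend is wanted.
#'
#' @param frame an \code{md_structure} or coordinate matrix
#' @param strandA,strandB \code{md_selection}s with at least 3 atoms each
#' @param fold fold to [0, 90] degrees (default TRUE)
#' @return angle in degrees.
#' @export
cross_angle <- function(frame, strandA, strandB, fold = TRUE) {
  .mb_check_selection(strandA); .mb_check_selection(strandB)
  xyz <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  axis_of <- function(sel) {
    sub <- xyz[sel$indices, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("strand '", sel$label, "' needs at least 3 atoms", call. = FALSE)
    cen <- sweep(sub, 2, colMeans(sub))
    sv <- svd(cen)
    if (sv$d[1] < 1e-9)
      stop("degenerate strand '", sel$label, "': atoms coincide",
           call. = FALSE)
    sv$v[, 1]
  }
  d <- sum(axis_of(strandA) * axis_of(strandB))
  d <- pmin(1, pmax(-1, d))
  if (fold) acos(abs(d)) * 180 / pi else acos(d) * 180 / pi
}

#' Cross-angle time series
#' @inheritParams cross_angle
#' @param trajectory an \code{md_trajectory}
#' @return numeric vector, degrees per frame.
#' @export
cross_angle_series <- function(trajectory, strandA, strandB, fold = TRUE) {
  vapply(seq_len(mb_n_frames(trajectory)), function(i)
    cross_angle(mb_frame(trajectory, i), strandA, strandB, fold), numeric(1))
}

#' Force trace container
#'
#' @param time_ns strictly increasing times, ns
#' @param force_pn force values, pN
#' @param n_hb optional per-frame interfacial H-bond count, used to restrict
#'   rupture-force detection to the pre-dissociation window
#' @return data.frame of class \code{force_trace}.
#' @export
force_trace <- function(time_ns, force_pn, n_hb = NULL) {
  if (length(time_ns) != length(force_pn))
    stop("time and force must have equal length", call. = FALSE)
  if (any(diff(time_ns) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  out <- data.frame(time_ns = time_ns, force_pn = force_pn)
  if (!is.null(n_hb)) {
    if (length(n_hb) != length(time_ns))
      stop("n_hb must match the trace length", call. = FALSE)
    out$n_hb <- n_hb
  }
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Read a force trace from TSV
#'
#' Expects 2-3 columns: \code{time_ns}, \code{force_pn} and optionally
#' \code{n_hb}.
#'
#' @param path TSV file
#' @return a \code{force_trace}.
#' @export
read_force_trace <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("time_ns", "force_pn") %in% names(tab)))
    stop("force trace needs columns time_ns, force_pn", call. = FALSE)
  force_trace(tab$time_ns, tab$force_pn, tab$n_hb)
}

#' Rupture force from a force-ramp trace
#'
#' The rupture force is the maximum of the moving-average-smoothed force
#' series restricted to the window before the interface dissociates (the
#' first time the per-frame H-bond count reaches zero, when provided). A
#' trace that never dissociates and has no interior maximum is reported with
#' a warning and the global smoothed maximum.
#'
#' @param trace a \code{\link{force_trace}}
#' @param window moving-average window, frames (odd; default 11)
#' @return list of class \code{rupture_result}: \code{rupture_force} (pN),
#'   \code{time_ns} at the maximum, and \code{dissociated} flag.
#' @export
rupture_force <- function(trace, window = 11L) {
  if (!inherits(trace, "force_trace")) stop("not a force_trace", call. = FALSE)
  n <- nrow(trace)
  if (n < window) stop("trace shorter than the smoothing window", call. = FALSE)
  sm <- .mb_moving_average(trace$force_pn, window)
  last <- n
  dissociated <- FALSE
  if (!is.null(trace$n_hb)) {
    zero <- which(trace$n_hb == 0L)
    if (length(zero)) { last <- zero[1]; dissociated <- TRUE }
  }
  seg <- sm[seq_len(last)]
  imax <- which.max(seg)
  if (!dissociated) {
    interior <- imax > 1L && imax < last
    if (!interior)
      warning("no dissociation and no interior force maximum; ",
              "reporting the global smoothed maximum", call. = FALSE)
  }
  out <- list(rupture_force = seg[imax], time_ns = trace$time_ns[imax],
              dissociated = dissociated)
  class(out) <- "rupture_result"
  out
}

#' @export
print.rupture_result <- function(x, ...) {
  cat(sprintf("rupture force: %.1f pN at %.3f ns (%s)\n", x$rupture_force,
              x$time_ns,
              if (x$dissociated) "dissociated" else "dissociation not reached"))
  invisible(x)
}

# Centered moving average; ends use the available partial window so the
# series keeps its length (no padding artifacts at the peak).
.mb_moving_average <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
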