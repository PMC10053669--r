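#' Trajectory container
#'
#' Frame-ordered Cartesian coordinates bound to one topology. Coordinates are
#' stored as an \code{n_frames x n_atoms x 3} array in Angstrom; optional
#' per-frame times (ns) must be strictly increasing and an optional per-frame
#' applied force (pN) supports force-clamp bookkeeping.
#'
#' @param topology an \code{md_structure}
#' @param coords list of n_atoms x 3 matrices, or an n_frames x n_atoms x 3
#'   array
#' @param times optional numeric vector, ns per frame
#' @param force optional numeric vector or scalar, pN per frame
#' @return An object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(topology, coords, times = NULL, force = NULL) {
  if (!inherits(topology, "md_structure"))
    stop("topology must be an md_structure", call. = FALSE)
  n_atoms <- nrow(topology$atoms)
  if (is.list(coords)) {
    n_frames <- length(coords)
    if (n_frames == 0L) stop("trajectory has no frames", call. = FALSE)
    arr <- array(NA_real_, c(n_frames, n_atoms, 3L))
    for (i in seq_len(n_frames)) {
      m <- coords[[i]]
      if (!is.matrix(m) || nrow(m) != n_atoms || ncol(m) != 3L)
        stop("frame ", i, " has ", NROW(m), " atoms; topology has ",
             n_atoms, call. = FALSE)
      arr[i, , ] <- m
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != n_atoms ||
      dim(coords)[3] != 3L)
    stop("coords must be n_frames x ", n_atoms, " x 3", call. = FALSE)
  n_frames <- dim(coords)[1]
  if (!is.null(times)) {
    if (length(times) != n_frames || any(diff(times) <= 0))
      stop("times must be one strictly increasing value per frame",
           call. = FALSE)
  }
  if (!is.null(force)) {
    if (length(force) == 1L) force <- rep(force, n_frames)
    if (length(force) != n_frames)
      stop("force must be scalar or one value per frame", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords, times = times,
                 force = force),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", mb_n_frames(x), "frames x",
      dim(x$coords)[2], "atoms",
      if (!is.null(x$force)) sprintf("(force %g-%g pN)", min(x$force),
                                     max(x$force)) else "", "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an \code{md_trajectory}
#' @return integer frame count.
#' @export
mb_n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param trajectory an \code{md_trajectory}
#' @param i frame index (1-based)
#' @return n_atoms x 3 matrix.
#' @export
mb_frame <- function(trajectory, i) {
  n <- mb_n_frames(trajectory)
  if (i < 1L || i > n) stop("frame index out of range", call. = FALSE)
  matrix(trajectory$coords[i, , ], ncol = 3L)
}

#' Frame as a structure (topology with that frame's coordinates)
#' @param trajectory an \code{md_trajectory}
#' @param i frame index
#' @return an \code{md_structure}.
#' @export
mb_frame_structure <- function(trajectory, i) {
  s <- trajectory$topology
  xyz <- mb_frame(trajectory, i)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# ---- File I/O -----------------------------------------------------------

#' Read a coordinate trajectory
#'
#' Two on-disk formats are supported: binary DCD (via \pkg{bio3d}) and a
#' plain-text multi-frame XYZ dialect. The XYZ dialect is the standard XYZ
#' block format -- an atom-count line, a comment line, then one
#' \code{name x y z} line per atom -- repeated per frame; the comment line may
#' carry \code{time=<ns>} and \code{force=<pN>} tokens which are parsed into
#' the trajectory's per-frame metadata.
#'
#' @param topology the \code{md_structure} the frames belong to
#' @param path trajectory file (\code{.dcd} or text XYZ)
#' @return An \code{md_trajectory}; coordinates in Angstrom.
#' @export
read_trajectory <- function(topology, path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    n_atoms <- nrow(topology$atoms)
    if (ncol(xyz) != 3L * n_atoms)
      stop("trajectory atom count (", ncol(xyz) / 3, ") does not match ",
           "topology (", n_atoms, ")", call. = FALSE)
    coords <- array(NA_real_, c(nrow(xyz), n_atoms, 3L))
    for (i in seq_len(nrow(xyz)))
      coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    return(md_trajectory(topology, coords))
  }
  .mb_read_multi_xyz(topology, path)
}

.mb_read_multi_xyz <- function(topology, path) {
  lines <- readLines(path, warn = FALSE)
  n_atoms <- nrow(topology$atoms)
  frames <- list(); times <- numeric(0); forces <- numeric(0)
  has_time <- TRUE; has_force <- TRUE
  pos <- 1L; frame_i <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame_i <- frame_i + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n))
      stop("frame ", frame_i, ": expected atom count at line ", pos,
           call. = FALSE)
    if (n != n_atoms)
      stop("frame ", frame_i, " has ", n, " atoms; topology has ", n_atoms,
           call. = FALSE)
    if (pos + 1L + n > length(lines))
      stop("truncated final frame ", frame_i, " (expected ", n,
           " atom lines)", call. = FALSE)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    fo <- regmatches(comment, regexec("force=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) == 2L) times <- c(times, as.numeric(tm[2])) else
      has_time <- FALSE
    if (length(fo) == 2L) forces <- c(forces, as.numeric(fo[2])) else
      has_force <- FALSE
    block <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
      stop("frame ", frame_i, ": malformed atom line ", pos + 1L + bad[1],
           call. = FALSE)
    m <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (!all(is.finite(m)))
      stop("frame ", frame_i, ": non-numeric coordinates", call. = FALSE)
    frames[[frame_i]] <- m
    pos <- pos + 2L + n
  }
  if (frame_i == 0L) stop("no frames in ", path, call. = FALSE)
  md_trajectory(topology, frames,
                times = if (has_time && length(times) == frame_i) times,
                force = if (has_force && length(forces) == frame_i) forces)
}

#' Write a trajectory in the multi-frame XYZ dialect
#'
#' @param trajectory an \code{md_trajectory}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  nm <- trajectory$topology$atoms$name
  n_atoms <- length(nm)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(mb_n_frames(trajectory))) {
    meta <- sprintf("frame=%d", i)
    if (!is.null(trajectory$times))
      meta <- paste0(meta, sprintf(" time=%.17g", trajectory$times[i]))
    if (!is.null(trajectory$force))
      meta <- paste0(meta, sprintf(" force=%.17g", trajectory$force[i]))
    xyz <- mb_frame(trajectory, i)
    writeLines(c(as.character(n_atoms), meta,
                 sprintf("%s %.17g %.17g %.17g", nm, xyz[, 1], xyz[, 2],
                         xyz[, 3])), con)
  }
  invisible(path)
}
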