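#' Geometric hydrogen-bond criteria
#'
#' A hydrogen-bonding event is scored in a frame when the donor--acceptor
#' distance and the donor-hydrogen--acceptor angular deviation from linearity
#' are below the cutoffs. The angular criterion follows the convention of the
#' common MD analysis tools: "deviation < 30 degrees" means the D-H...A angle
#' is within 30 degrees of straight, i.e. angle(D,H,A) >= 150 degrees.
#'
#' Donor chemistry is deliberately simple and configurable: N and O heavy
#' atoms carrying at least one covalently attached hydrogen (within
#' \code{max_dh_bond} of the heavy atom, same residue) act as donors; N and O
#' atoms act as acceptors.
#'
#' @param max_da_distance maximum donor--acceptor distance, Angstrom
#' @param max_dha_deviation maximum D-H...A deviation from linearity, degrees
#' @param donor_elements,acceptor_elements element symbols acting as
#'   hydrogen-bond donors (with attached H) and acceptors
#' @param max_dh_bond covalent D-H bond-length cutoff used to associate
#'   hydrogens with their heavy atom, Angstrom
#' @return An object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_dha_deviation = 30,
                           donor_elements = c("N", "O"),
                           acceptor_elements = c("N", "O"),
                           max_dh_bond = 1.25) {
  .mb_stopifnot_scalar(max_da_distance, "max_da_distance")
  .mb_stopifnot_scalar(max_dha_deviation, "max_dha_deviation")
  structure(list(max_da_distance = max_da_distance,
                 max_dha_deviation = max_dha_deviation,
                 donor_elements = toupper(donor_elements),
                 acceptor_elements = toupper(acceptor_elements),
                 max_dh_bond = max_dh_bond),
            class = "hbond_criteria")
}

# Donor-hydrogen covalent pairs within a selection, from reference
# coordinates: for each heavy donor-element atom, hydrogens of the same
# residue within max_dh_bond.
.mb_donor_h_pairs <- function(atoms, xyz, sel_idx, criteria) {
  heavy <- sel_idx[atoms$element[sel_idx] %in% criteria$donor_elements]
  hyd <- sel_idx[atoms$element[sel_idx] == "H"]
  if (length(heavy) == 0L || length(hyd) == 0L)
    return(data.frame(d = integer(0), h = integer(0)))
  d_out <- integer(0); h_out <- integer(0)
  key_h <- paste(atoms$chain[hyd], atoms$resno[hyd])
  for (d in heavy) {
    same <- hyd[key_h == paste(atoms$chain[d], atoms$resno[d])]
    if (length(same) == 0L) next
    dd <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[d, ])^2))
    att <- same[dd <= criteria$max_dh_bond]
    d_out <- c(d_out, rep(d, length(att))); h_out <- c(h_out, att)
  }
  data.frame(d = d_out, h = h_out)
}

# All candidate (donor, hydrogen, acceptor) triples across two disjoint
# selections, both directions, from reference coordinates.
.mb_hbond_triples <- function(structure, selA, selB, criteria) {
  atoms <- structure$atoms
  xyz <- mb_coords(structure)
  both <- c(selA$indices, selB$indices)
  if (!any(atoms$element[both] == "H")) {
    res <- unique(paste0(atoms$chain[both], ":", atoms$resid[both],
                         atoms$resno[both]))
    stop("no hydrogen atoms in the selections; hydrogen-bond detection ",
         "requires explicit hydrogens on donor atoms (residues: ",
         paste(utils::head(res, 8), collapse = ", "),
         if (length(res) > 8) ", ..." else "", ")", call. = FALSE)
  }
  one_way <- function(sel_d, sel_a) {
    dh <- .mb_donor_h_pairs(atoms, xyz, sel_d$indices, criteria)
    acc <- sel_a$indices[atoms$element[sel_a$indices] %in%
                           criteria$acceptor_elements]
    if (nrow(dh) == 0L || length(acc) == 0L)
      return(data.frame(d = integer(0), h = integer(0), a = integer(0)))
    data.frame(d = rep(dh$d, each = length(acc)),
               h = rep(dh$h, each = length(acc)),
               a = rep.int(acc, nrow(dh)))
  }
  rbind(one_way(selA, selB), one_way(selB, selA))
}

.mb_triple_geometry <- function(xyz, triples) {
  vd <- xyz[triples$d, , drop = FALSE] - xyz[triples$a, , drop = FALSE]
  da <- sqrt(rowSums(vd^2))
  v1 <- xyz[triples$d, , drop = FALSE] - xyz[triples$h, , drop = FALSE]
  v2 <- xyz[triples$a, , drop = FALSE] - xyz[triples$h, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  dev <- 180 - acos(cosang) * 180 / pi
  list(da = da, dev = dev)
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates all (donor heavy atom, attached hydrogen, acceptor) triples
#' across two disjoint selections -- in both donor directions -- and reports
#' each triple that satisfies the geometric criteria exactly once.
#'
#' @param frame an \code{md_structure} carrying the frame's coordinates, or
#'   an n_atoms x 3 coordinate matrix laid out like \code{selA}'s structure
#' @param selA,selB disjoint \code{md_selection}s (e.g. the two binding
#'   partners, or two domains of one chain)
#' @param criteria an \code{\link{hbond_criteria}}
#' @return data.frame of bond events: donor/hydrogen/acceptor identities,
#'   donor--acceptor distance (Angstrom) and D-H...A deviation (degrees).
#' @export
detect_hbonds <- function(frame, selA, selB, criteria = hbond_criteria()) {
  .mb_check_selection(selA); .mb_check_selection(selB)
  .mb_check_disjoint(selA, selB)
  s <- selA$structure
  xyz <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  if (nrow(xyz) != nrow(s$atoms))
    stop("frame does not match the selections' structure", call. = FALSE)
  ref <- s
  ref$atoms$x <- xyz[, 1]; ref$atoms$y <- xyz[, 2]; ref$atoms$z <- xyz[, 3]
  triples <- .mb_hbond_triples(ref, selA, selB, criteria)
  if (nrow(triples) == 0L) return(.mb_empty_events(s))
  g <- .mb_triple_geometry(xyz, triples)
  ok <- g$da <= criteria$max_da_distance &
    g$dev <= criteria$max_dha_deviation
  .mb_events_frame(s, triples[ok, , drop = FALSE], g$da[ok], g$dev[ok])
}

.mb_empty_events <- function(structure) {
  data.frame(donor_chain = character(0), donor_resno = integer(0),
             donor_resid = character(0), donor_atom = character(0),
             hydrogen = character(0),
             acceptor_chain = character(0), acceptor_resno = integer(0),
             acceptor_resid = character(0), acceptor_atom = character(0),
             da_distance = numeric(0), dha_deviation = numeric(0),
             stringsAsFactors = FALSE)
}

.mb_events_frame <- function(structure, triples, da, dev) {
  at <- structure$atoms
  data.frame(donor_chain = at$chain[triples$d],
             donor_resno = at$resno[triples$d],
             donor_resid = at$resid[triples$d],
             donor_atom = at$name[triples$d],
             hydrogen = at$name[triples$h],
             acceptor_chain = at$chain[triples$a],
             acceptor_resno = at$resno[triples$a],
             acceptor_resid = at$resid[triples$a],
             acceptor_atom = at$name[triples$a],
             da_distance = da, dha_deviation = dev,
             stringsAsFactors = FALSE)
}

# Vectorized over frames: for every candidate triple, which frames qualify.
# Hydrogen attachment is taken from the topology's reference coordinates
# (covalent bonds do not change along a trajectory).
.mb_hbond_qualify <- function(trajectory, selA, selB, criteria) {
  .mb_check_selection(selA); .mb_check_selection(selB)
  .mb_check_disjoint(selA, selB)
  s <- trajectory$topology
  triples <- .mb_hbond_triples(s, selA, selB, criteria)
  n_frames <- mb_n_frames(trajectory)
  if (nrow(triples) == 0L)
    return(list(triples = triples,
                qualify = matrix(FALSE, n_frames, 0L)))
  co <- trajectory$coords
  q <- matrix(FALSE, n_frames, nrow(triples))
  dx <- co[, triples$d, 1, drop = FALSE] - co[, triples$a, 1, drop = FALSE]
  dy <- co[, triples$d, 2, drop = FALSE] - co[, triples$a, 2, drop = FALSE]
  dz <- co[, triples$d, 3, drop = FALSE] - co[, triples$a, 3, drop = FALSE]
  da2 <- dx^2 + dy^2 + dz^2
  dim(da2) <- c(n_frames, nrow(triples))
  close_enough <- da2 <= criteria$max_da_distance^2
  idx <- which(close_enough, arr.ind = TRUE)
  if (nrow(idx)) {
    f <- idx[, 1]; t <- idx[, 2]
    v1 <- cbind(co[cbind(f, triples$d[t], 1L)] - co[cbind(f, triples$h[t], 1L)],
                co[cbind(f, triples$d[t], 2L)] - co[cbind(f, triples$h[t], 2L)],
                co[cbind(f, triples$d[t], 3L)] - co[cbind(f, triples$h[t], 3L)])
    v2 <- cbind(co[cbind(f, triples$a[t], 1L)] - co[cbind(f, triples$h[t], 1L)],
                co[cbind(f, triples$a[t], 2L)] - co[cbind(f, triples$h[t], 2L)],
                co[cbind(f, triples$a[t], 3L)] - co[cbind(f, triples$h[t], 3L)])
    cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    dev <- 180 - acos(cosang) * 180 / pi
    ok <- dev <= criteria$max_dha_deviation
    q[cbind(f[ok], t[ok])] <- TRUE
  }
  list(triples = triples, qualify = q)
}

#' Residue-pair hydrogen-bond occupancy over a trajectory
#'
#' The occupancy (survival ratio) of a residue pair is the fraction of frames
#' in which at least one qualifying hydrogen bond connects the two residues.
#' Multiple atom-level bonds between the same residues in one frame count as
#' a single event; pairs that never bond are omitted.
#'
#' @inheritParams detect_hbonds
#' @param trajectory an \code{md_trajectory}
#' @param condition optional condition label (force level, system variant)
#'   recorded in the output
#' @return data.frame of class \code{occupancy_table}: residue pair
#'   identities (the \code{selA}-side residue first), occupancy fraction and
#'   the frame count.
#' @export
occupancy <- function(trajectory, selA, selB, criteria = hbond_criteria(),
                      condition = NA_character_) {
  qual <- .mb_hbond_qualify(trajectory, selA, selB, criteria)
  n_frames <- mb_n_frames(trajectory)
  at <- trajectory$topology$atoms
  tr <- qual$triples
  if (nrow(tr) == 0L || !any(qual$qualify)) {
    out <- data.frame(res_a = character(0), res_b = character(0),
                      condition = character(0), occupancy = numeric(0),
                      n_frames = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("occupancy_table", "data.frame")
    return(out)
  }
  in_a <- tr$d %in% selA$indices
  side_a <- ifelse(in_a, tr$d, tr$a)
  side_b <- ifelse(in_a, tr$a, tr$d)
  lab <- function(i) paste0(at$chain[i], ":", at$resid[i], at$resno[i])
  pair <- paste(lab(side_a), lab(side_b), sep = "|")
  upair <- unique(pair)
  occ <- vapply(upair, function(p) {
    cols <- which(pair == p)
    mean(rowSums(qual$qualify[, cols, drop = FALSE]) > 0)
  }, numeric(1))
  keep <- occ > 0
  parts <- strsplit(upair[keep], "|", fixed = TRUE)
  out <- data.frame(res_a = vapply(parts, `[`, "", 1),
                    res_b = vapply(parts, `[`, "", 2),
                    condition = condition,
                    occupancy = unname(occ[keep]),
                    n_frames = n_frames, stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$res_a, out$res_b), ]
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Per-frame interfacial hydrogen-bond count
#'
#' N_HB(frame): the number of distinct qualifying (donor, hydrogen, acceptor)
#' triples across the interface in each frame.
#'
#' @inheritParams occupancy
#' @return integer vector, one count per frame.
#' @export
hbond_count_series <- function(trajectory, selA, selB,
                               criteria = hbond_criteria()) {
  qual <- .mb_hbond_qualify(trajectory, selA, selB, criteria)
  as.integer(rowSums(qual$qualify))
}

#' Detect salt bridges in one frame
#'
#' A salt bridge is scored when any oxygen atom of an acidic residue (Asp or
#' Glu) lies within the cutoff of any nitrogen atom of a basic residue (Lys
#' or Arg) across the interface. A residue pair is reported once per frame
#' regardless of how many O-N contacts it has.
#'
#' @inheritParams detect_hbonds
#' @param cutoff O-N distance cutoff, Angstrom
#' @return data.frame of residue-pair contacts with the minimum O-N distance.
#' @export
detect_salt_bridges <- function(frame, selA, selB, cutoff = 4.0) {
  .mb_check_selection(selA); .mb_check_selection(selB)
  .mb_check_disjoint(selA, selB)
  s <- selA$structure
  xyz <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  at <- s$atoms
  acid <- function(idx) idx[at$resid[idx] %in% c("ASP", "GLU") &
                              at$element[idx] == "O"]
  base <- function(idx) idx[at$resid[idx] %in% c("LYS", "ARG") &
                              at$element[idx] == "N"]
  pairs_one_way <- function(o_idx, n_idx) {
    if (length(o_idx) == 0L || length(n_idx) == 0L) return(NULL)
    o <- rep(o_idx, each = length(n_idx))
    n <- rep.int(n_idx, length(o_idx))
    d <- sqrt(rowSums((xyz[o, , drop = FALSE] - xyz[n, , drop = FALSE])^2))
    ok <- d <= cutoff
    if (!any(ok)) return(NULL)
    data.frame(acidic = o[ok], basic = n[ok], distance = d[ok])
  }
  res <- rbind(pairs_one_way(acid(selA$indices), base(selB$indices)),
               pairs_one_way(acid(selB$indices), base(selA$indices)))
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(acidic_res = character(0), basic_res = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  lab <- function(i) paste0(at$chain[i], ":", at$resid[i], at$resno[i])
  key <- paste(lab(res$acidic), lab(res$basic), sep = "|")
  agg <- tapply(res$distance, key, min)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(acidic_res = vapply(parts, `[`, "", 1),
                    basic_res = vapply(parts, `[`, "", 2),
                    min_distance = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
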