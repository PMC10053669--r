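#' Molecular structure container
#'
#' A light S3 wrapper around a per-atom table, the topology object shared by
#' every analysis in the package. Author (PDB) residue numbering is kept
#' as-is: all residue ranges in this package are inclusive and 1-based in the
#' author's numbering, matching how structural papers label residues
#' (e.g. "residues 19th-241st").
#'
#' @param atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resno}, \code{resid}, \code{chain}, \code{x},
#'   \code{y}, \code{z} and optionally \code{charge}, \code{eps} (kcal/mol),
#'   \code{rmin_half} (Angstrom) nonbonded parameters.
#' @return An object of class \code{md_structure}.
#' @export
md_structure <- function(atoms) {
  req <- c("serial", "name", "element", "resno", "resid", "chain",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  if (any(atoms$resno <= 0))
    stop("residue numbers must be positive (author numbering)", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) triple: ",
         key[anyDuplicated(key)], call. = FALSE)
  atoms$name <- trimws(atoms$name)
  atoms$element <- toupper(trimws(atoms$element))
  structure(list(atoms = atoms), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  ch <- mb_chain_map(x)
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      length(ch), "chain(s)\n")
  for (c_id in names(ch))
    cat("  chain ", c_id, ": residues ", ch[[c_id]][1], "-", ch[[c_id]][2],
        "\n", sep = "")
  invisible(x)
}

#' Chain to residue-range map
#'
#' @param structure an \code{md_structure}
#' @return named list, one \code{c(first, last)} residue-number pair per chain.
#' @export
mb_chain_map <- function(structure) {
  at <- structure$atoms
  out <- lapply(split(at$resno, at$chain), range)
  out[order(names(out))]
}

#' Atom coordinates as a matrix
#'
#' @param structure an \code{md_structure}
#' @return numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
mb_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# ---- PDB reading --------------------------------------------------------

#' Read a PDB file into an \code{md_structure}
#'
#' Parsing is delegated to \pkg{bio3d}; this wrapper adds the strictness the
#' rest of the pipeline relies on: a line-numbered error for malformed
#' coordinate fields, rejection of insertion codes, and altloc handling that
#' keeps only blank/'A' locations. Author residue numbering is preserved.
#'
#' @param path PDB file path.
#' @return An \code{md_structure}, one atom per kept ATOM/HETATM record.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  for (i in which(is_atom)) {
    fx <- suppressWarnings(as.numeric(substr(lines[i], 31, 38)))
    fy <- suppressWarnings(as.numeric(substr(lines[i], 39, 46)))
    fz <- suppressWarnings(as.numeric(substr(lines[i], 47, 54)))
    if (anyNA(c(fx, fy, fz)))
      stop("unparseable coordinate fields at line ", i, " of ", path,
           call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stop("insertion codes are not supported (found in ", path, ")",
         call. = FALSE)
  alt <- trimws(at$alt)
  keep <- is.na(at$alt) | alt == "" | alt == "A"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left after altloc filtering", call. = FALSE)
  elem <- trimws(at$elesy)
  need_guess <- is.na(elem) | !nzchar(elem)
  elem[need_guess] <- .mb_guess_element(at$elety[need_guess])
  chain <- at$chain
  chain[is.na(chain) | !nzchar(trimws(chain))] <- " "
  md_structure(data.frame(
    serial = at$eleno, name = at$elety, element = elem,
    resno = at$resno, resid = at$resid, chain = chain,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write an \code{md_structure} to a PDB file
#'
#' @param structure an \code{md_structure}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(mb_coords(structure))),
                   resno = at$resno, resid = at$resid, eleno = at$serial,
                   elety = at$name, chain = at$chain, elesy = at$element)
  invisible(path)
}

# ---- Parameter attachment ----------------------------------------------

#' Attach per-atom nonbonded parameters
#'
#' Joins a parameter table (charge in elementary charges, Lennard-Jones well
#' depth \code{eps} in kcal/mol and \code{rmin_half} in Angstrom) onto the
#' structure, keyed by residue name + atom name (with an optional wildcard
#' residue \code{"*"}). Energy computations require every atom of the
#' selections involved to be parameterized.
#'
#' @param structure an \code{md_structure}
#' @param params data.frame with columns \code{resid}, \code{name},
#'   \code{charge}, \code{eps}, \code{rmin_half}
#' @return the structure with parameter columns filled in.
#' @export
attach_parameters <- function(structure, params) {
  req <- c("resid", "name", "charge", "eps", "rmin_half")
  miss <- setdiff(req, names(params))
  if (length(miss))
    stop("parameter table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  at <- structure$atoms
  key_atom <- paste(at$resid, at$name)
  key_spec <- paste(params$resid, params$name)
  key_wild <- paste("*", at$name)
  idx <- match(key_atom, key_spec)
  wild <- match(key_wild, key_spec)
  idx[is.na(idx)] <- wild[is.na(idx)]
  at$charge <- params$charge[idx]
  at$eps <- params$eps[idx]
  at$rmin_half <- params$rmin_half[idx]
  structure$atoms <- at
  structure
}

# ---- Selections ---------------------------------------------------------

#' Select atoms by chain and inclusive residue range
#'
#' Ranges use the author's residue numbering, inclusive at both ends. An
#' empty result is an error: on real structures a silently empty selection
#' almost always means an off-by-one against the author numbering (or a
#' residue that does not exist in a truncated construct).
#'
#' @param structure an \code{md_structure}
#' @param chain single chain identifier
#' @param residue_range inclusive \code{c(lo, hi)} residue-number range
#' @param label optional label; defaults to a description of the query
#' @return An object of class \code{md_selection} holding the atom indices.
#' @export
select_residues <- function(structure, chain, residue_range,
                            label = NULL) {
  if (length(residue_range) != 2L || residue_range[1] > residue_range[2])
    stop("residue_range must be an inclusive c(lo, hi) with lo <= hi",
         call. = FALSE)
  at <- structure$atoms
  idx <- which(at$chain == chain &
               at$resno >= residue_range[1] & at$resno <= residue_range[2])
  if (length(idx) == 0L)
    stop("empty selection: chain ", chain, " residues ", residue_range[1],
         "-", residue_range[2], " (check author numbering / truncations)",
         call. = FALSE)
  if (is.null(label))
    label <- sprintf("chain %s %d-%d", chain, residue_range[1],
                     residue_range[2])
  structure(list(structure = structure, indices = idx, label = label),
            class = "md_selection")
}

#' Select a single named atom
#'
#' @param structure an \code{md_structure}
#' @param chain chain identifier
#' @param resno residue number (author numbering)
#' @param name atom name (e.g. \code{"CA"})
#' @return the atom's row index in the structure.
#' @export
select_atom <- function(structure, chain, resno, name) {
  at <- structure$atoms
  idx <- which(at$chain == chain & at$resno == resno & at$name == name)
  if (length(idx) != 1L)
    stop("atom ", name, " of chain ", chain, " residue ", resno,
         if (length(idx)) " is ambiguous" else " not found", call. = FALSE)
  idx
}

#' @export
print.md_selection <- function(x, ...) {
  cat("md_selection '", x$label, "': ", length(x$indices), " atoms\n",
      sep = "")
  invisible(x)
}

.mb_check_selection <- function(sel, structure = NULL) {
  if (!inherits(sel, "md_selection")) stop("not an md_selection", call. = FALSE)
  n <- nrow(sel$structure$atoms)
  if (length(sel$indices) == 0L || any(sel$indices < 1L | sel$indices > n))
    stop("invalid selection '", sel$label, "'", call. = FALSE)
  invisible(sel)
}

.mb_check_disjoint <- function(selA, selB) {
  if (length(intersect(selA$indices, selB$indices)))
    stop("selections '", selA$label, "' and '", selB$label,
         "' overlap; they must be disjoint", call. = FALSE)
  invisible(TRUE)
}
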