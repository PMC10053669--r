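#' Planted hydrogen-bond specification
#'
#' Describes one donor--acceptor pair of a synthetic complex together with
#' its force-dependent target occupancy curve o(F). Five response modes are
#' supported; each is a Gaussian-bump parametrization of the corresponding
#' occupancy-vs-force shape:
#' \itemize{
#'   \item \code{steady}: o(F) = baseline
#'   \item \code{catch_slip}: baseline + amplitude * bump(center, width)
#'     (unimodal, interior maximum)
#'   \item \code{slip_catch}: baseline - amplitude * bump (interior minimum)
#'   \item \code{catch_slip_catch}: baseline + bump1 + bump2 (two rises;
#'     place the second center at the top of the force range)
#'   \item \code{slip_catch_slip}: baseline - bump1 - bump2
#' }
#' Parameters that drive o(F) outside [0, 1] anywhere on F >= 0 are rejected
#' at construction.
#'
#' @param donor list/vector \code{(chain, resno)} of the donor residue; its
#'   backbone N (with hydrogen H) donates
#' @param acceptor list/vector \code{(chain, resno)}; its backbone O accepts
#' @param mode one of \code{"steady"}, \code{"catch_slip"},
#'   \code{"slip_catch"}, \code{"catch_slip_catch"}, \code{"slip_catch_slip"}
#' @param baseline baseline occupancy fraction
#' @param amplitude bump amplitude(s); length 2 for the triphasic modes
#' @param center bump center force(s), pN
#' @param width bump width(s) (Gaussian sigma), pN
#' @return object of class \code{bond_spec}.
#' @export
bond_spec <- function(donor, acceptor, mode = "steady", baseline = 0.5,
                      amplitude = 0.4, center = 50, width = 20) {
  modes <- c("steady", "catch_slip", "slip_catch", "catch_slip_catch",
             "slip_catch_slip")
  if (!mode %in% modes)
    stop("mode must be one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  n_bump <- if (mode %in% c("catch_slip_catch", "slip_catch_slip")) 2L
  else if (mode == "steady") 0L else 1L
  if (n_bump > 0L) {
    amplitude <- rep_len(amplitude, n_bump)
    center <- rep_len(center, n_bump)
    width <- rep_len(width, n_bump)
    if (any(width <= 0)) stop("width must be positive", call. = FALSE)
  }
  spec <- structure(list(donor = list(chain = as.character(donor[[1]]),
                                      resno = as.integer(donor[[2]])),
                         acceptor = list(chain = as.character(acceptor[[1]]),
                                         resno = as.integer(acceptor[[2]])),
                         mode = mode, baseline = baseline,
                         amplitude = amplitude, center = center,
                         width = width),
                    class = "bond_spec")
  grid <- seq(0, max(200, if (n_bump) max(center) + 8 * max(width) else 0),
              length.out = 512)
  o <- occupancy_curve(spec, grid)
  if (any(o < 0 | o > 1))
    stop("occupancy curve leaves [0, 1] (min ", signif(min(o), 3), ", max ",
         signif(max(o), 3), "); adjust baseline/amplitude", call. = FALSE)
  spec
}

#' Evaluate a bond's target occupancy at given forces
#'
#' @param spec a \code{\link{bond_spec}}
#' @param force non-negative force(s), pN
#' @return occupancy fraction(s) in [0, 1].
#' @export
occupancy_curve <- function(spec, force) {
  if (any(force < 0)) stop("force must be >= 0", call. = FALSE)
  bump <- function(k) spec$amplitude[k] *
    exp(-(force - spec$center[k])^2 / (2 * spec$width[k]^2))
  switch(spec$mode,
         steady = rep(spec$baseline, length(force)),
         catch_slip = spec$baseline + bump(1),
         slip_catch = spec$baseline - bump(1),
         catch_slip_catch = spec$baseline + bump(1) + bump(2),
         slip_catch_slip = spec$baseline - bump(1) - bump(2))
}

#' Demonstration bond set covering the five force-response modes
#'
#' Five planted bonds (chain A donors, chain B acceptors, residues 1-5) whose
#' occupancy curves realize each mode over a 0-100 pN grid, with step-to-step
#' occupancy changes large enough to classify against sampling noise.
#'
#' @return list of five \code{\link{bond_spec}}s named by mode.
#' @export
demo_bond_specs <- function() {
  list(
    steady = bond_spec(c("A", 1), c("B", 1), "steady", baseline = 0.5),
    catch_slip = bond_spec(c("A", 2), c("B", 2), "catch_slip",
                           baseline = 0.3, amplitude = 0.4, center = 50,
                           width = 20),
    slip_catch = bond_spec(c("A", 3), c("B", 3), "slip_catch",
                           baseline = 0.7, amplitude = 0.4, center = 50,
                           width = 20),
    catch_slip_catch = bond_spec(c("A", 4), c("B", 4), "catch_slip_catch",
                                 baseline = 0.2, amplitude = c(0.45, 0.5),
                                 center = c(25, 100), width = c(12, 20)),
    slip_catch_slip = bond_spec(c("A", 5), c("B", 5), "slip_catch_slip",
                                baseline = 0.8, amplitude = c(0.45, 0.5),
                                center = c(25, 100), width = c(12, 20)))
}

#' Generator configuration
#'
#' @param n_residues_per_chain residues in each of the two chains
#' @param bond_specs list of \code{\link{bond_spec}}s
#' @param n_frames frames per generated trajectory
#' @param force_grid ordered tensile forces, pN
#' @param seed base integer seed; each (force, replicate) run perturbs it
#'   deterministically
#' @param bound_distance donor--acceptor distance of the bound template,
#'   Angstrom (inside the detection cutoff)
#' @param bound_deviation D-H...A deviation of the bound template, degrees
#' @param unbound_distance donor--acceptor distance when the bond is absent,
#'   Angstrom (outside the cutoff)
#' @param jitter half-width of the uniform per-coordinate jitter, Angstrom
#'   (keeps every atom within 0.05 A of its template)
#' @param dt_ns frame spacing, ns
#' @param resno_start named vector: first residue number of chains A and B
#'   (author-style numbering offsets)
#' @param markov_rho frame-to-frame bond persistence (0 = independent
#'   Bernoulli frames, the default; > 0 gives a two-state Markov chain with
#'   the same stationary occupancy)
#' @return object of class \code{generator_config}.
#' @export
generator_config <- function(n_residues_per_chain, bond_specs, n_frames,
                             force_grid = c(0, 25, 50, 75, 100),
                             seed = 1L, bound_distance = 2.9,
                             bound_deviation = 10, unbound_distance = 5.0,
                             jitter = 0.025, dt_ns = 0.05,
                             resno_start = c(A = 1L, B = 1L),
                             markov_rho = 0) {
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (any(diff(force_grid) <= 0))
    stop("force_grid must be strictly increasing", call. = FALSE)
  if (unbound_distance <= bound_distance)
    stop("unbound_distance must exceed bound_distance", call. = FALSE)
  for (sp in bond_specs) {
    for (side in list(sp$donor, sp$acceptor)) {
      start <- resno_start[[side$chain]]
      if (is.null(start))
        stop("bond spec references unknown chain ", side$chain, call. = FALSE)
      if (side$resno < start ||
          side$resno >= start + n_residues_per_chain)
        stop("bond spec references residue ", side$resno, " of chain ",
             side$chain, ", outside ", start, "-",
             start + n_residues_per_chain - 1L, call. = FALSE)
    }
  }
  don <- vapply(bond_specs, function(s) paste(s$donor$chain, s$donor$resno),
                "")
  acc <- vapply(bond_specs, function(s)
    paste(s$acceptor$chain, s$acceptor$resno), "")
  if (anyDuplicated(don) || anyDuplicated(acc))
    stop("each residue may donate/accept in at most one bond spec",
         call. = FALSE)
  structure(list(n_residues_per_chain = as.integer(n_residues_per_chain),
                 bond_specs = bond_specs, n_frames = as.integer(n_frames),
                 force_grid = force_grid, seed = as.integer(seed),
                 bound_distance = bound_distance,
                 bound_deviation = bound_deviation,
                 unbound_distance = unbound_distance, jitter = jitter,
                 dt_ns = dt_ns, resno_start = resno_start,
                 markov_rho = markov_rho),
            class = "generator_config")
}

# Tilt angle (radians, at the donor) placing the hydrogen so that the
# D-H...A deviation equals target_dev for the bound-template D-A distance.
.mb_h_tilt <- function(da_distance, target_dev, h_len = 1.0) {
  dev_of <- function(phi) {
    h <- c(h_len * sin(phi), 0, h_len * cos(phi))
    v1 <- -h; v2 <- c(0, 0, da_distance) - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    180 - ang * 180 / pi - target_dev
  }
  if (target_dev == 0) return(0)
  stats::uniroot(dev_of, c(1e-6, pi / 2.5))$root
}

#' Generate the synthetic two-chain complex
#'
#' Builds a glycine-like two-chain structure (chains A and B, five backbone
#' atoms N, H, CA, C, O per residue) laid out so that every planted bond's
#' acceptor can be toggled between a bound template (donor--acceptor
#' geometry inside the detection criteria) and an unbound template (outside
#' them), while no unplanted atom pair ever comes close enough to register a
#' bond. Reference coordinates hold every planted bond in its unbound state.
#' The layout is fully deterministic.
#'
#' @param config a \code{\link{generator_config}}
#' @return an \code{md_structure} (with attached \code{bound}/\code{unbound}
#'   template coordinates used by \code{\link{generate_trajectory}}).
#' @export
generate_complex <- function(config) {
  n <- config$n_residues_per_chain
  spacing <- 9.0; sep <- 12.0
  atoms <- NULL
  serial <- 0L
  for (ch in c("A", "B")) {
    z <- if (ch == "A") 0 else sep
    dirz <- if (ch == "A") 1 else -1  # H points toward the other chain
    start <- config$resno_start[[ch]]
    for (r in seq_len(n)) {
      x0 <- spacing * (r - 1)
      res <- data.frame(
        name = c("N", "H", "CA", "C", "O"),
        element = c("N", "H", "C", "C", "O"),
        x = x0 + c(0, 0, 1.5, 3.0, 3.0),
        y = c(0, 0, 0, 0, 1.2),
        z = z + c(0, dirz * 1.0, 0, 0, 0),
        stringsAsFactors = FALSE)
      res$serial <- serial + seq_len(5L); serial <- serial + 5L
      res$resno <- start + r - 1L
      res$resid <- "GLY"
      res$chain <- ch
      atoms <- rbind(atoms, res)
    }
  }
  s <- md_structure(atoms[, c("serial", "name", "element", "resno", "resid",
                              "chain", "x", "y", "z")])
  # per-spec template coordinates: acceptor O and donor H, bound vs unbound
  xyz <- mb_coords(s)
  tilt <- .mb_h_tilt(config$bound_distance, config$bound_deviation)
  templates <- lapply(config$bond_specs, function(sp) {
    d_idx <- select_atom(s, sp$donor$chain, sp$donor$resno, "N")
    h_idx <- select_atom(s, sp$donor$chain, sp$donor$resno, "H")
    a_idx <- select_atom(s, sp$acceptor$chain, sp$acceptor$resno, "O")
    dN <- xyz[d_idx, ]
    dirz <- if (sp$donor$chain == "A") 1 else -1
    u <- c(0, 0, dirz)
    list(d = d_idx, h = h_idx, a = a_idx,
         a_bound = dN + u * config$bound_distance,
         a_unbound = dN + u * config$unbound_distance,
         h_bound = dN + c(sin(tilt), 0, dirz * cos(tilt)),
         h_unbound = dN + u * 1.0)
  })
  # reference state: all bonds unbound
  for (tp in templates) {
    xyz[tp$a, ] <- tp$a_unbound
    xyz[tp$h, ] <- tp$h_unbound
  }
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  attr(s, "bond_templates") <- templates
  s
}

# Deterministic per-run seed below 2^31.
.mb_run_seed <- function(base, force, replicate) {
  as.integer((as.numeric(base) + 7919 * replicate +
                104729 * round(force)) %% 2147483647)
}

#' Generate a synthetic trajectory at a constant tensile force
#'
#' Per frame and per planted bond, presence is drawn Bernoulli(o(F)) (or
#' from a two-state Markov chain with the same stationary occupancy when
#' \code{markov_rho > 0}); present bonds take the bound geometry template,
#' absent ones the unbound template, and every atom receives sub-0.05 A
#' uniform jitter. Identical (config, force, replicate) always yields an
#' identical trajectory.
#'
#' @param structure the complex from \code{\link{generate_complex}}
#' @param config the \code{\link{generator_config}}
#' @param force tensile force, pN (>= 0)
#' @param replicate replicate index; perturbs the run seed deterministically
#' @return an \code{md_trajectory} with planted per-bond presence recorded in
#'   its \code{"planted"} attribute (a frames x bonds logical matrix).
#' @export
generate_trajectory <- function(structure, config, force, replicate = 1L) {
  if (config$n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (force < 0) stop("force must be >= 0", call. = FALSE)
  templates <- attr(structure, "bond_templates")
  if (is.null(templates))
    stop("structure was not built by generate_complex", call. = FALSE)
  set.seed(.mb_run_seed(config$seed, force, replicate))
  n_frames <- config$n_frames
  n_atoms <- nrow(structure$atoms)
  ref <- mb_coords(structure)
  o <- vapply(config$bond_specs, occupancy_curve, numeric(1), force = force)
  n_bonds <- length(templates)
  present <- matrix(FALSE, n_frames, n_bonds)
  for (b in seq_len(n_bonds)) {
    if (config$markov_rho > 0) {
      rho <- config$markov_rho
      p <- logical(n_frames)
      p[1] <- stats::runif(1) < o[b]
      for (f in seq_len(n_frames - 1L)) {
        stay <- if (p[f]) o[b] + rho * (1 - o[b]) else o[b] * (1 - rho)
        p[f + 1L] <- stats::runif(1) < stay
      }
      present[, b] <- p
    } else {
      present[, b] <- stats::runif(n_frames) < o[b]
    }
  }
  coords <- array(NA_real_, c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    xyz <- ref
    for (b in seq_len(n_bonds)) {
      tp <- templates[[b]]
      if (present[f, b]) {
        xyz[tp$a, ] <- tp$a_bound; xyz[tp$h, ] <- tp$h_bound
      } else {
        xyz[tp$a, ] <- tp$a_unbound; xyz[tp$h, ] <- tp$h_unbound
      }
    }
    coords[f, , ] <- xyz +
      matrix(stats::runif(n_atoms * 3L, -config$jitter, config$jitter),
             n_atoms, 3L)
  }
  tr <- md_trajectory(structure, coords,
                      times = config$dt_ns * seq_len(n_frames),
                      force = force)
  attr(tr, "planted") <- present
  tr
}
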