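#' Pairwise nonbonded interaction energy between two selections
#'
#' Sums, over all cross-selection atom pairs within the cutoff, the Coulomb
#' term k q_i q_j / r (k = 332.0636 kcal A / (mol e^2)) and the 12-6
#' Lennard-Jones term eps_ij [(Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6] with
#' Lorentz-Berthelot combination (eps geometric mean, Rmin_ij the sum of the
#' half-Rmin values). Both terms are scaled by the standard polynomial
#' switching function, which takes the energy smoothly to zero between the
#' switch-on distance and the cutoff, so the energy is continuous at the
#' cutoff boundary. No intra-selection terms are included.
#'
#' This is an interface interaction energy under a plain cutoff -- no Ewald
#' summation or reaction field -- which is well defined for a pair of
#' selections and suitable for ranking and trend analysis; absolute values
#' are force-field- and convention-dependent.
#'
#' @param frame an \code{md_structure} or coordinate matrix
#' @param selA,selB disjoint \code{md_selection}s over a structure whose
#'   atoms carry \code{charge}, \code{eps}, \code{rmin_half} parameters (see
#'   \code{\link{attach_parameters}})
#' @param cutoff interaction cutoff, Angstrom
#' @param switch_on switching-region start, Angstrom (must be < cutoff)
#' @return list of class \code{energy_terms}: \code{electrostatic},
#'   \code{van_der_waals} and \code{total} (their exact sum), kcal/mol.
#' @export
interaction_energy <- function(frame, selA, selB, cutoff = 12,
                               switch_on = 10) {
  .mb_check_selection(selA); .mb_check_selection(selB)
  .mb_check_disjoint(selA, selB)
  if (switch_on >= cutoff) stop("switch_on must be below cutoff", call. = FALSE)
  s <- selA$structure
  at <- s$atoms
  need <- c(selA$indices, selB$indices)
  par_cols <- c("charge", "eps", "rmin_half")
  if (!all(par_cols %in% names(at)) ||
      anyNA(at[need, par_cols])) {
    bad <- if (all(par_cols %in% names(at)))
      need[!stats::complete.cases(at[need, par_cols])] else need
    stop("atoms missing nonbonded parameters: ",
         paste(utils::head(paste0(at$chain[bad], ":", at$resno[bad], "/",
                                  at$name[bad]), 8), collapse = ", "),
         if (length(bad) > 8) ", ..." else "", call. = FALSE)
  }
  xyz <- if (inherits(frame, "md_structure")) mb_coords(frame) else
    as.matrix(frame)
  ia <- selA$indices; ib <- selB$indices
  i <- rep(ia, each = length(ib)); j <- rep.int(ib, length(ia))
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  keep <- d <= cutoff & d > 0
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  if (length(d) == 0L) {
    out <- list(electrostatic = 0, van_der_waals = 0, total = 0)
    class(out) <- "energy_terms"
    return(out)
  }
  sw <- .mb_switching(d, switch_on, cutoff)
  elec <- sum(.mb_coulomb_k * at$charge[i] * at$charge[j] / d * sw)
  eps_ij <- sqrt(at$eps[i] * at$eps[j])
  rmin_ij <- at$rmin_half[i] + at$rmin_half[j]
  sr6 <- (rmin_ij / d)^6
  vdw <- sum(eps_ij * (sr6^2 - 2 * sr6) * sw)
  out <- list(electrostatic = elec, van_der_waals = vdw,
              total = elec + vdw)
  class(out) <- "energy_terms"
  out
}

#' @export
print.energy_terms <- function(x, ...) {
  cat(sprintf("interaction energy: elec %.3f + vdw %.3f = %.3f kcal/mol\n",
              x$electrostatic, x$van_der_waals, x$total))
  invisible(x)
}

# CHARMM-style polynomial switching: 1 below r_on, 0 at/after r_off, C1-
# continuous in between.
.mb_switching <- function(r, r_on, r_off) {
  s <- ifelse(r <= r_on, 1,
              ifelse(r >= r_off, 0,
                     (r_off^2 - r^2)^2 * (r_off^2 + 2 * r^2 - 3 * r_on^2) /
                       (r_off^2 - r_on^2)^3))
  s
}

#' Interaction-energy time series
#'
#' @inheritParams interaction_energy
#' @param trajectory an \code{md_trajectory}
#' @param stride frame stride
#' @return data.frame with \code{frame}, \code{electrostatic},
#'   \code{van_der_waals}, \code{total} columns (kcal/mol).
#' @export
interaction_energy_series <- function(trajectory, selA, selB, cutoff = 12,
                                      switch_on = 10, stride = 1L) {
  frames <- seq(1L, mb_n_frames(trajectory), by = stride)
  rows <- lapply(frames, function(i) {
    e <- interaction_energy(mb_frame(trajectory, i), selA, selB, cutoff,
                            switch_on)
    data.frame(frame = i, electrostatic = e$electrostatic,
               van_der_waals = e$van_der_waals, total = e$total)
  })
  do.call(rbind, rows)
}
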