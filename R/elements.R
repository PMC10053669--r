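#' Element lookup tables
#'
#' Van der Waals radii (Bondi set, Angstrom) and atomic masses (u) keyed by
#' element symbol. These drive Shrake-Rupley surface areas and mass-weighted
#' centers; unknown elements are a hard error rather than a silent default so
#' that mis-typed atom names surface early.
#'
#' @return \code{mb_vdw_radii()} and \code{mb_atomic_masses()} return named
#'   numeric vectors keyed by element symbol.
#' @export
mb_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75,
    MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.94, SE = 1.90)
}

#' @rdname mb_vdw_radii
#' @export
mb_atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
    "F" = 18.998, CL = 35.45, BR = 79.904, I = 126.904, "NA" = 22.990,
    K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38, FE = 55.845,
    SE = 78.971)
}

# Coulomb constant in kcal * Angstrom / (mol * e^2), the MD convention.
.mb_coulomb_k <- 332.0636

.mb_lookup_element <- function(elements, table, what) {
  key <- toupper(elements)
  vals <- table[key]
  if (anyNA(vals)) {
    bad <- unique(elements[is.na(vals)])
    stop("unknown element(s) for ", what, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(vals)
}

# Element symbol from a PDB atom name when the element column is absent:
# strip leading digits, take the leading alphabetic run's first character
# (adequate for protein atoms; two-letter elements must come from the PDB
# element column).
.mb_guess_element <- function(name) {
  nm <- sub("^[0-9']+", "", trimws(name))
  toupper(substr(nm, 1, 1))
}

.mb_stopifnot_scalar <- function(x, what, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop(what, " must be positive", call. = FALSE)
  invisible(x)
}
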