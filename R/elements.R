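# Bondi-type van der Waals radii (Angstrom) and standard atomic masses
# (amu) for the elements that occur in drug-like small molecules.
.VDW_RADII <- c(
  H = 1.20, He = 1.40, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Ne = 1.54, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Te = 2.06, I = 1.98,
  Xe = 2.16
)

.ATOMIC_MASSES <- c(
  H = 1.008, He = 4.003, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.95, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Te = 127.60, I = 126.904, Xe = 131.293
)

#' Van der Waals radii and atomic masses by element symbol
#'
#' Looks up Bondi-type van der Waals radii (used to build the projected
#' molecular silhouette) and standard atomic masses (used for the centre
#' of mass and inertia tensor). A named numeric vector of overrides can
#' replace or extend the bundled radii, e.g. to probe sensitivity of the
#' minimal projection area to the radius set.
#'
#' @param elements Character vector of element symbols (case sensitive,
#'   e.g. `"Cl"`).
#' @param overrides Optional named numeric vector of radii (Angstrom)
#'   taking precedence over the bundled table.
#' @return Numeric vector of radii (Angstrom) or masses (amu).
#' @examples
#' vdw_radius(c("C", "N", "O"))
#' atomic_mass("S")
#' @export
vdw_radius <- function(elements, overrides = NULL) {
  tab <- .VDW_RADII
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    tab[names(overrides)] <- overrides
  }
  out <- tab[elements]
  if (anyNA(out)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(elements[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' @rdname vdw_radius
#' @export
atomic_mass <- function(elements) {
  out <- .ATOMIC_MASSES[elements]
  if (anyNA(out)) {
    abort(paste0("no atomic mass for element(s): ",
                 paste(unique(elements[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}
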