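#' Conformer ensemble container
#'
#' A `conformer_ensemble` bundles everything the descriptor calculations
#' need for one compound: a list of conformer coordinate matrices plus the
#' per-atom partial charges, van der Waals radii and masses shared by all
#' conformers. The ensemble stands in for a sampled trajectory of the
#' molecule in solution: descriptor means and fluctuations are taken
#' across its conformers.
#'
#' @param compound_id Single string identifying the compound.
#' @param conformers A single n x 3 numeric matrix, or a list of them
#'   (Angstrom), one per conformer. All conformers must have the same
#'   atom count.
#' @param charges Numeric vector of per-atom partial charges (elementary
#'   charge e). Their sum must be within 0.01 e of an integer.
#' @param radii Numeric vector of per-atom van der Waals radii
#'   (Angstrom), strictly positive.
#' @param masses Numeric vector of per-atom masses (amu), strictly
#'   positive.
#' @param source Optional string recording where the conformers came
#'   from (e.g. an SDF path); carried into output metadata.
#' @return An object of class `conformer_ensemble`.
#' @examples
#' pos <- rbind(c(0, 0, -1), c(0, 0, 1))
#' ens <- conformer_ensemble("diatomic", pos,
#'   charges = c(-0.5, 0.5), radii = c(1.5, 1.5), masses = c(12, 12)
#' )
#' n_conformers(ens)
#' @export
conformer_ensemble <- function(compound_id, conformers, charges, radii,
                               masses, source = NULL) {
  if (!is.character(compound_id) || length(compound_id) != 1L) {
    abort("compound_id must be a single string")
  }
  if (is.matrix(conformers)) conformers <- list(conformers)
  if (!is.list(conformers) || length(conformers) < 1L) {
    abort("conformers must be a non-empty list of n x 3 matrices")
  }
  conformers <- lapply(conformers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L || !is.numeric(m) || anyNA(m)) {
      abort("each conformer must be a numeric n x 3 coordinate matrix")
    }
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  n_atoms <- nrow(conformers[[1L]])
  if (n_atoms < 1L) abort("conformers must contain at least one atom")
  if (!all(vapply(conformers, nrow, 1L) == n_atoms)) {
    abort("all conformers must have the same atom count")
  }
  for (nm in c("charges", "radii", "masses")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != n_atoms || anyNA(v)) {
      abort(sprintf("%s must be a numeric vector of length %d", nm, n_atoms))
    }
  }
  if (any(radii <= 0)) abort("radii must be strictly positive")
  if (any(masses <= 0)) abort("masses must be strictly positive")
  total <- sum(charges)
  if (abs(total - round(total)) > 0.01) {
    abort(sprintf(
      "partial charges sum to %.4f e: %.4f e away from an integer (tolerance 0.01 e)",
      total, total - round(total)
    ))
  }
  structure(
    list(
      compound_id = compound_id,
      conformers = conformers,
      charges = as.double(charges),
      radii = as.double(radii),
      masses = as.double(masses),
      source = source
    ),
    class = "conformer_ensemble"
  )
}

#' @rdname conformer_ensemble
#' @param x A `conformer_ensemble`.
#' @export
n_conformers <- function(x) {
  stopifnot(inherits(x, "conformer_ensemble"))
  length(x$conformers)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %s: %d atoms, %d conformer(s), net charge %+d e\n",
    x$compound_id, nrow(x$conformers[[1L]]), length(x$conformers),
    as.integer(round(sum(x$charges)))
  ))
  invisible(x)
}
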