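#' Read multi-conformer ensembles from an SDF file
#'
#' Parses a V2000/V3000 SDF (via ChemmineR) in which conformers of the
#' same compound appear as consecutive records sharing a molecule name.
#' Per-atom partial charges are taken from an `ATOM_PARTIAL_CHARGES`
#' data field (whitespace-separated values in atom order) or from a
#' sidecar charge table with columns `id` and `charge` (rows in atom
#' order within each compound). Van der Waals radii and masses are
#' assigned from the element symbols via [vdw_radius()] and
#' [atomic_mass()].
#'
#' @param path SDF file path.
#' @param charges `NULL` (use the SDF data field), a data frame with
#'   columns `id` and `charge`, or the path of a CSV holding one.
#' @param radii_overrides Optional named radii overrides, see
#'   [vdw_radius()].
#' @return A named list of [conformer_ensemble()] objects, one per
#'   distinct molecule name.
#' @export
read_conformer_sdf <- function(path, charges = NULL,
                               radii_overrides = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  sdfset <- ChemmineR::read.SDFset(path)
  if (length(sdfset) == 0L) abort("SDF file contains no molecules")
  if (is.character(charges) && length(charges) == 1L) {
    charges <- readr::read_csv(charges, show_col_types = FALSE,
                               progress = FALSE)
  }
  if (!is.null(charges) &&
      !all(c("id", "charge") %in% names(charges))) {
    abort("charge table must have columns id and charge")
  }
  ids <- vapply(seq_along(sdfset),
                function(i) ChemmineR::header(sdfset[[i]])[[1L]],
                character(1))
  out <- list()
  for (id in unique(ids)) {
    recs <- which(ids == id)
    conformers <- list()
    q <- NULL
    elements <- NULL
    for (i in recs) {
      sdf <- sdfset[[i]]
      ab <- ChemmineR::atomblock(sdf)
      pos <- unname(ab[, 1:3, drop = FALSE])
      el <- sub("_\\d+$", "", rownames(ab))
      if (is.null(elements)) elements <- el
      else if (!identical(el, elements)) {
        abort(paste0("conformers of '", id, "' differ in atoms"))
      }
      conformers[[length(conformers) + 1L]] <- pos
      if (is.null(q)) {
        db <- ChemmineR::datablock(sdf)
        if ("ATOM_PARTIAL_CHARGES" %in% names(db)) {
          q <- as.numeric(strsplit(trimws(db[["ATOM_PARTIAL_CHARGES"]]),
                                   "[[:space:]]+")[[1L]])
        }
      }
    }
    if (!is.null(charges)) {
      q <- charges$charge[charges$id == id]
    }
    if (is.null(q)) {
      abort(paste0("no partial charges for '", id,
                   "': supply a charge table or an ",
                   "ATOM_PARTIAL_CHARGES data field"))
    }
    if (length(q) != length(elements)) {
      abort(sprintf("'%s': %d charges for %d atoms", id, length(q),
                    length(elements)))
    }
    out[[id]] <- conformer_ensemble(
      id, conformers, charges = q,
      radii = vdw_radius(elements, overrides = radii_overrides),
      masses = atomic_mass(elements),
      source = path
    )
  }
  out
}

# cache so repeated glycine calibrations don't recompute the MPA
.porinperm_cache <- new.env(parent = emptyenv())

#' Glycine reference descriptors
#'
#' Descriptors of the bundled synthetic glycine conformer fixture
#' (`inst/extdata/glycine_synthetic.sdf`: three conformers with
#' Gasteiger-type partial charges; coordinates are a synthetic
#' stand-in, not experimental data). Glycine anchors the
#' percent-of-glycine permeability scale at 100%. The alogP default is
#' a literature-style value for glycine; like the geometry it is
#' illustrative.
#'
#' @param alogp alogP value to attach.
#' @param n_directions,resolution Passed to [ensemble_descriptors()].
#' @return One-row descriptor tibble.
#' @export
glycine_descriptors <- function(alogp = -3.2, n_directions = 256,
                                resolution = 0.1) {
  key <- sprintf("glycine_%d_%g", n_directions, resolution)
  hit <- .porinperm_cache[[key]]
  if (!is.null(hit)) return(dplyr::mutate(hit, alogp = alogp))
  path <- system.file("extdata", "glycine_synthetic.sdf",
                      package = "porinperm", mustWork = TRUE)
  ens <- read_conformer_sdf(path)[["glycine_synthetic"]]
  d <- ensemble_descriptors(ens, alogp = alogp,
                            n_directions = n_directions,
                            resolution = resolution)
  .porinperm_cache[[key]] <- d
  d
}
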