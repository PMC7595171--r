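#' Structure ensembles
#'
#' A `structure_ensemble` holds frames x atoms x 3 coordinates (nm) together
#' with per-atom labels (residue number, residue name, atom name). It is the
#' container consumed by superposition, PCA, order-parameter and clustering
#' analyses, and is what the PDB/frame-table readers produce.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, nm.
#' @param atoms Data frame with columns `resno`, `resname`, `atom`.
#' @param provenance Free-text provenance string.
#' @return An object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(coords, atoms, provenance = "") {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resname", "atom") %in% names(atoms)))
  if (dim(coords)[2] != nrow(atoms)) {
    stop("coordinate array and atom table disagree on atom count",
         call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  structure(list(coords = coords, atoms = atoms, provenance = provenance),
            class = "structure_ensemble")
}

#' @rdname structure_ensemble
#' @param x A `structure_ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d frames, %d atoms, residues %d-%d\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$atoms$resno), max(x$atoms$resno)))
  if (nzchar(x$provenance)) cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

# Extract one frame as an atoms x 3 matrix.
frame_coords <- function(ensemble, i) {
  matrix(ensemble$coords[i, , ], ncol = 3L)
}

#' Atom selections
#'
#' A `selection_spec` names residue ranges plus an atom-name filter and
#' resolves to a duplicate-free atom index list on a given ensemble.
#'
#' @param ranges List of length-2 integer vectors `c(first, last)` (residue
#'   numbers, inclusive) or a single such vector.
#' @param atoms Character vector of atom names to keep (e.g. backbone
#'   `c("N","CA","C")`), or NULL for all atoms.
#' @param name Label used in messages and provenance records.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(ranges, atoms = c("N", "CA", "C"), name = "") {
  if (is.numeric(ranges)) ranges <- list(ranges)
  stopifnot(all(vapply(ranges, length, 1L) == 2L))
  structure(list(ranges = ranges, atoms = atoms, name = name),
            class = "selection_spec")
}

#' @rdname selection_spec
#' @param ensemble A [structure_ensemble()].
#' @param spec A `selection_spec`.
#' @return Integer vector of atom indices, in ensemble order.
#' @export
resolve_selection <- function(ensemble, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  at <- ensemble$atoms
  in_range <- rep(FALSE, nrow(at))
  for (r in spec$ranges) {
    in_range <- in_range | (at$resno >= r[1] & at$resno <= r[2])
  }
  keep <- in_range
  if (!is.null(spec$atoms)) keep <- keep & at$atom %in% spec$atoms
  idx <- which(keep)
  if (length(idx) == 0) {
    stop(sprintf("selection '%s' resolves to no atoms", spec$name),
         call. = FALSE)
  }
  idx
}

# Backbone atom-name set used for PCA: {N, CA, C, O} when O atoms are
# present in the ensemble, {N, CA, C} otherwise.
backbone_atoms <- function(ensemble) {
  if ("O" %in% ensemble$atoms$atom) c("N", "CA", "C", "O") else c("N", "CA", "C")
}

#' Standard N-SH2 selections
#'
#' Presets for the SH2-domain analyses (SHP2 residue numbering):
#' * `core`: the relatively rigid core used for least-squares fitting
#'   (Phe7-Pro33, Asp40-Arg47, Ala50-Asn58, Asp61-Leu65, Phe71-Tyr81,
#'   Leu88-Glu90, Val95-Pro101).
#' * `analysis`: backbone Trp6-Pro101, over which the PCA covariance matrix
#'   is built.
#' * `py_loop`: Ser34-Phe41, the pY (BC) loop subvector region.
#' * `plus5_site`: Gln57-Glu97, the +5 site subvector region (end of the
#'   betaD strand, blocking loop, EF loop, alphaB helix, BG loop).
#'
#' @param which One of `"core"`, `"analysis"`, `"py_loop"`, `"plus5_site"`.
#' @param atoms Atom-name filter; default backbone `c("N","CA","C")`.
#' @return A [selection_spec()].
#' @export
nsh2_selection <- function(which = c("core", "analysis", "py_loop",
                                     "plus5_site"),
                           atoms = c("N", "CA", "C")) {
  which <- match.arg(which)
  ranges <- switch(which,
    core = list(c(7, 33), c(40, 47), c(50, 58), c(61, 65), c(71, 81),
                c(88, 90), c(95, 101)),
    analysis = list(c(6, 101)),
    py_loop = list(c(34, 41)),
    plus5_site = list(c(57, 97))
  )
  selection_spec(ranges, atoms = atoms, name = which)
}
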