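# Optimal least-squares (Kabsch) rotation aligning moving points P onto
# reference Q (both n x 3, already centred). Returns the 3x3 rotation R
# minimising ||P %*% R - Q||, proper (det = +1).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Least-squares superposition of an ensemble onto a reference
#'
#' Each frame is translated and rotated by the optimal least-squares
#' (Kabsch) transform computed on the fit selection; the transform is then
#' applied to all atoms of the frame. The per-frame RMSD is reported on the
#' fit selection, in Angstrom.
#'
#' @param ensemble A [structure_ensemble()].
#' @param reference Reference frame: an index into `ensemble` (default 1) or
#'   an atoms x 3 coordinate matrix in nm matching the ensemble atom list.
#' @param fit_selection A [selection_spec()] resolving identically on the
#'   ensemble and the reference.
#' @return List with `ensemble` (superposed copy) and `rmsd` (numeric,
#'   Angstrom, one value per frame).
#' @export
superpose <- function(ensemble, reference = 1L,
                      fit_selection = nsh2_selection("analysis")) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  idx <- resolve_selection(ensemble, fit_selection)
  if (length(idx) < 3L) {
    stop("fit selection needs at least 3 atoms", call. = FALSE)
  }
  ref <- if (is.matrix(reference)) reference else frame_coords(ensemble, reference)
  stopifnot(nrow(ref) == nrow(ensemble$atoms))
  Qs <- ref[idx, , drop = FALSE]
  # degenerate (collinear) fit selections give a rank-deficient cross-
  # covariance and no unique rotation
  if (qr(sweep(Qs, 2, colMeans(Qs)))$rank < 2L) {
    stop("degenerate fit selection: atoms are collinear", call. = FALSE)
  }
  cq <- colMeans(Qs)
  Qc <- sweep(Qs, 2, cq)
  nf <- n_frames(ensemble)
  out <- ensemble$coords
  rmsd <- numeric(nf)
  for (i in seq_len(nf)) {
    X <- frame_coords(ensemble, i)
    Ps <- X[idx, , drop = FALSE]
    cp <- colMeans(Ps)
    R <- kabsch_rotation(sweep(Ps, 2, cp), Qc)
    Xn <- sweep(X, 2, cp) %*% R
    Xn <- sweep(Xn, 2, cq, `+`)
    out[i, , ] <- Xn
    dif <- Xn[idx, , drop = FALSE] - Qs
    rmsd[i] <- nm_to_angstrom(sqrt(mean(rowSums(dif^2))))
  }
  list(
    ensemble = structure_ensemble(out, ensemble$atoms,
                                  provenance = paste0(ensemble$provenance,
                                                      " | superposed")),
    rmsd = rmsd
  )
}

#' Pairwise RMSD between two coordinate sets after optimal superposition
#'
#' @param a,b Coordinate matrices n x 3, nm.
#' @return RMSD in Angstrom.
#' @keywords internal
pair_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  R <- kabsch_rotation(ac, bc)
  nm_to_angstrom(sqrt(mean(rowSums((ac %*% R - bc)^2))))
}
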