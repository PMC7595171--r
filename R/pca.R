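#' Collective vectors (PCA modes)
#'
#' A `collective_vector` couples a mean structure over an analysis selection
#' with a unit-norm displacement vector, its eigenvalue (nm^2) and the
#' fraction of the total positional variance it explains. Frame projections
#' eta_t = dot(frame_t - mean, vector) are in nm.
#'
#' @param mean_structure Atoms x 3 matrix (nm) over the analysis selection.
#' @param vector Unit-norm numeric vector of length 3 * n_atoms.
#' @param eigenvalue Mode variance, nm^2, >= 0.
#' @param variance_fraction Fraction of total variance, in `[0, 1]`.
#' @param selection Atom labels (`resno`, `resname`, `atom` data frame) the
#'   vector is defined over, used to re-resolve it on other ensembles.
#' @return Object of class `collective_vector`.
#' @export
collective_vector <- function(mean_structure, vector, eigenvalue,
                              variance_fraction, selection) {
  stopifnot(abs(sqrt(sum(vector^2)) - 1) < 1e-10, eigenvalue >= -1e-12,
            variance_fraction <= 1 + 1e-12)
  structure(list(mean_structure = mean_structure, vector = as.numeric(vector),
                 eigenvalue = max(eigenvalue, 0),
                 variance_fraction = min(max(variance_fraction, 0), 1),
                 selection = selection),
            class = "collective_vector")
}

#' @export
print.collective_vector <- function(x, ...) {
  cat(sprintf(
    "collective_vector over %d atoms: eigenvalue %.4g nm^2 (%.1f%% of variance)\n",
    nrow(x$mean_structure), x$eigenvalue, 100 * x$variance_fraction))
  invisible(x)
}

# Match a collective vector's atom labels on an ensemble; error on mismatch.
cv_atom_indices <- function(ensemble, cv) {
  key_e <- paste(ensemble$atoms$resno, ensemble$atoms$atom)
  key_c <- paste(cv$selection$resno, cv$selection$atom)
  idx <- match(key_c, key_e)
  if (any(is.na(idx))) {
    stop("collective vector selection does not resolve on this ensemble",
         call. = FALSE)
  }
  idx
}

#' Principal component analysis of an ensemble
#'
#' Eigendecomposition of the atom-coordinate covariance matrix over the
#' analysis selection, computed via SVD of the centred frame matrix. Vectors
#' are sorted by descending eigenvalue and `variance_fraction` is eigenvalue
#' over the covariance trace.
#'
#' Frames are assumed to be superposed already (see [superpose()]); when
#' `fit_selection` is supplied the ensemble is first superposed internally
#' onto its first frame on that selection.
#'
#' Sign convention: when the ensemble carries the sheet anchor atoms
#' (Gly39 C, Asn58 N) inside the analysis selection, each vector is oriented
#' so that increasing eta increases the sheet distance, i.e. +eta points
#' toward the alpha state. Eigenvector signs are otherwise arbitrary.
#'
#' @param ensemble A [structure_ensemble()] with >= 2 frames.
#' @param analysis_selection [selection_spec()] defining the covariance atoms.
#' @param fit_selection Optional [selection_spec()] for internal superposition.
#' @param n_vectors Number of leading vectors to return.
#' @return List of [collective_vector()]s.
#' @export
pca <- function(ensemble, analysis_selection = nsh2_selection("analysis"),
                fit_selection = NULL, n_vectors = 5L) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("PCA needs at least 2 frames", call. = FALSE)
  if (!is.null(fit_selection)) {
    ensemble <- superpose(ensemble, 1L, fit_selection)$ensemble
  }
  idx <- resolve_selection(ensemble, analysis_selection)
  m <- length(idx)
  X <- matrix(ensemble$coords[, idx, , drop = FALSE], nrow = nf)  # nf x 3m
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  eig <- sv$d^2 / (nf - 1)
  total <- sum(eig)
  n_out <- min(n_vectors, ncol(sv$v))
  mean_structure <- matrix(mu, ncol = 3L)
  sel <- ensemble$atoms[idx, c("resno", "resname", "atom")]
  lapply(seq_len(n_out), function(k) {
    v <- sv$v[, k]
    v <- orient_toward_alpha(v, mean_structure, sel)
    collective_vector(mean_structure, v, eig[k],
                      if (total > 0) eig[k] / total else 0, sel)
  })
}

# Fix eigenvector sign so +eta increases the Gly39 C - Asn58 N distance
# (toward the alpha state's spread sheet); no-op when anchors are absent.
orient_toward_alpha <- function(v, mean_structure, sel) {
  i1 <- which(sel$resno == 39L & sel$atom == "C")
  i2 <- which(sel$resno == 58L & sel$atom == "N")
  if (length(i1) != 1L || length(i2) != 1L) return(v)
  vm <- matrix(v, ncol = 3L)
  d0 <- mean_structure[i1, ] - mean_structure[i2, ]
  d_eps <- d0 + 1e-3 * (vm[i1, ] - vm[i2, ])
  if (sqrt(sum(d_eps^2)) < sqrt(sum(d0^2))) -v else v
}

#' Project frames onto a collective vector
#'
#' eta_t = dot(frame_t - mean_structure, vector), in nm. The variance of eta
#' over the generating ensemble equals the vector's eigenvalue.
#'
#' @param ensemble A [structure_ensemble()].
#' @param cv A [collective_vector()] whose selection resolves on `ensemble`.
#' @return Numeric vector of projections, one per frame.
#' @export
project <- function(ensemble, cv) {
  stopifnot(inherits(cv, "collective_vector"))
  idx <- cv_atom_indices(ensemble, cv)
  nf <- n_frames(ensemble)
  X <- matrix(ensemble$coords[, idx, , drop = FALSE], nrow = nf)
  drop(sweep(X, 2, as.numeric(cv$mean_structure)) %*% cv$vector)
}

#' Subvector of a collective vector on an atom subset
#'
#' Implements the two-step loop-subvector recipe: (1) reconstruct a rank-1
#' trajectory mean + eta1 * vector from the parent mode, (2) run PCA
#' restricted to the subset atoms on that reconstruction and keep the first
#' vector. Mathematically the result equals the restriction of the parent
#' vector to the subset, re-normalised to unit length, up to sign; the
#' implementation computes both routes and errors out if they disagree
#' (|dot| < 0.999), then orients the result along the restriction.
#'
#' @param cv Parent [collective_vector()].
#' @param ensemble Ensemble used for the rank-1 reconstruction.
#' @param subset [selection_spec()]; must select a subset of `cv`'s atoms
#'   with non-negligible weight in the parent vector.
#' @return A [collective_vector()] over the subset atoms.
#' @export
subvector <- function(cv, ensemble, subset) {
  stopifnot(inherits(cv, "collective_vector"))
  idx_full <- cv_atom_indices(ensemble, cv)
  idx_sub_ens <- resolve_selection(ensemble, subset)
  if (!all(idx_sub_ens %in% idx_full)) {
    stop("subset must select a subset of the parent vector's atoms",
         call. = FALSE)
  }
  pos <- match(idx_sub_ens, idx_full)            # rows within cv selection
  m <- nrow(cv$mean_structure)
  comp <- c(pos, pos + m, pos + 2L * m)          # column-major (x..., y..., z...)
  restriction <- cv$vector[comp]
  rnorm_ <- sqrt(sum(restriction^2))
  if (rnorm_ < 1e-8) {
    stop("subset has zero weight in the parent vector", call. = FALSE)
  }

  # route 1: rank-1 reconstruction + restricted PCA
  eta <- project(ensemble, cv)
  nf <- length(eta)
  recon <- outer(eta, cv$vector[comp]) # nf x 3s, centred by construction
  mu_sub <- as.numeric(cv$mean_structure[pos, , drop = FALSE])
  sv <- svd(recon, nu = 0, nv = 1L)
  v1 <- sv$v[, 1]
  # route 2: normalised restriction
  v2 <- restriction / rnorm_
  agreement <- abs(sum(v1 * v2))
  if (agreement < 0.999) {
    stop(sprintf(
      "subvector self-check failed: |dot| = %.6f between restricted-PCA and normalised-restriction routes",
      agreement), call. = FALSE)
  }
  if (sum(v1 * v2) < 0) v1 <- -v1
  eig <- sv$d[1]^2 / (nf - 1)
  tot <- sum(recon^2) / (nf - 1)
  collective_vector(matrix(mu_sub, ncol = 3L), v1, eig,
                    if (tot > 0) eig / tot else 0,
                    cv$selection[pos, , drop = FALSE])
}

#' Agreement between a subvector and its closed-form equivalent
#'
#' |dot| between the [subvector()] computed by the two-step rank-1
#' reconstruction recipe and the normalised restriction of the parent
#' vector to the subset atoms — the closed-form consequence of the recipe.
#' Values should be >= 0.999 on any valid input.
#'
#' @inheritParams subvector
#' @return Scalar in `[0, 1]`.
#' @export
subvector_agreement <- function(cv, ensemble, subset) {
  sub <- subvector(cv, ensemble, subset)
  idx_full <- cv_atom_indices(ensemble, cv)
  idx_sub <- resolve_selection(ensemble, subset)
  pos <- match(idx_sub, idx_full)
  m <- nrow(cv$mean_structure)
  restriction <- cv$vector[c(pos, pos + m, pos + 2L * m)]
  abs(sum(sub$vector * restriction / sqrt(sum(restriction^2))))
}
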