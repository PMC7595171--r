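make_rotation <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(ay), 0, sin(ay), 0, 1, 0, -sin(ay), 0, cos(ay)), 3, 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}

test_that("superposition removes rigid-body motion exactly", {
  gen <- build_two_state_ensemble(1, 1, noise_sd = 0, seed = 1)
  ref <- gen$ensemble$coords[1, , ]
  R <- make_rotation(0.4, -0.9, 1.7)
  moved <- ref %*% t(R)
  moved <- sweep(moved, 2, c(1.5, -2, 0.7), `+`)
  ens <- structure_ensemble(
    aperm(array(c(t(ref), t(moved)), dim = c(3, nrow(ref), 2)), c(3, 2, 1)),
    gen$ensemble$atoms)
  fit <- superpose(ens, 1L, nsh2_selection("analysis"))
  expect_equal(fit$rmsd[1], 0, tolerance = 1e-8)
  expect_equal(fit$rmsd[2], 0, tolerance = 1e-8)
  expect_equal(fit$ensemble$coords[2, , ], ref, tolerance = 1e-10)
})

test_that("superposition RMSD matches the brute-force rotation search", {
  set.seed(11)
  n_atoms <- 100
  ref <- matrix(rnorm(n_atoms * 3, sd = 1), ncol = 3)
  noisy <- ref + matrix(rnorm(n_atoms * 3, sd = 0.05), ncol = 3)  # 0.5 A
  atoms <- data.frame(resno = seq_len(n_atoms), resname = "ALA", atom = "CA")
  coords <- aperm(array(c(t(ref), t(noisy)), dim = c(3, n_atoms, 2)),
                  c(3, 2, 1))
  ens <- structure_ensemble(coords, atoms)
  fit <- superpose(ens, 1L, selection_spec(c(1, n_atoms), atoms = "CA"))
  expect_equal(fit$rmsd[2], oracle_rmsd(noisy, ref), tolerance = 1e-6)
})

test_that("superposition is idempotent and rejects degenerate selections", {
  gen <- build_two_state_ensemble(10, 0.5, noise_sd = 0.3, seed = 2)
  s1 <- superpose(gen$ensemble, 1L, nsh2_selection("core"))
  s2 <- superpose(s1$ensemble, 1L, nsh2_selection("core"))
  expect_lt(max(abs(s1$ensemble$coords - s2$ensemble$coords)), 1e-9)

  # collinear atoms: build a 3-atom straight chain
  atoms <- data.frame(resno = 1:3, resname = "GLY", atom = "CA")
  line <- cbind(0:2, 0, 0)
  ens <- structure_ensemble(aperm(array(c(t(line), t(line)),
                                        dim = c(3, 3, 2)), c(3, 2, 1)), atoms)
  expect_error(superpose(ens, 1L, selection_spec(c(1, 3), atoms = "CA")),
               "degenerate|collinear")
})

test_that("PCA recovers the generating mode and satisfies its identities", {
  gen <- build_two_state_ensemble(500, 0.5, noise_sd = 0.3, seed = 3)
  cvs <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 10)
  idx <- resolve_selection(gen$ensemble, nsh2_selection("analysis"))
  true_mode <- as.numeric(gen$mode[idx, ])
  true_mode <- true_mode / sqrt(sum(true_mode^2))
  expect_gt(abs(sum(cvs[[1]]$vector * true_mode)), 0.99)

  # orthonormality and ordering
  for (k in seq_along(cvs)) {
    expect_equal(sqrt(sum(cvs[[k]]$vector^2)), 1, tolerance = 1e-10)
  }
  for (k in seq_len(length(cvs) - 1)) {
    expect_lt(abs(sum(cvs[[k]]$vector * cvs[[k + 1]]$vector)), 1e-8)
    expect_gte(cvs[[k]]$eigenvalue, cvs[[k + 1]]$eigenvalue)
  }
  # projection variance equals the eigenvalue
  eta <- project(gen$ensemble, cvs[[1]])
  expect_equal(var(eta), cvs[[1]]$eigenvalue, tolerance = 1e-8)
  # projecting the mean structure gives 0; mean + 0.1 v gives 0.1
  mean_ens <- structure_ensemble(
    array(rep(cvs[[1]]$mean_structure, each = 2),
          dim = c(2, nrow(cvs[[1]]$mean_structure), 3)),
    gen$ensemble$atoms[idx, ])
  expect_equal(project(mean_ens, cvs[[1]]), c(0, 0), tolerance = 1e-10)
  shifted <- mean_ens
  shifted$coords[1, , ] <- shifted$coords[1, , ] +
    0.1 * matrix(cvs[[1]]$vector, ncol = 3)
  expect_equal(project(shifted, cvs[[1]])[1], 0.1, tolerance = 1e-10)
})

test_that("two distinct frames give exactly one nonzero eigenvalue", {
  gen <- build_two_state_ensemble(2, 0.5, noise_sd = 0.1, seed = 8)
  # force the two frames to differ
  gen$ensemble$coords[2, 1, 1] <- gen$ensemble$coords[2, 1, 1] + 0.5
  cvs <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 5)
  expect_gt(cvs[[1]]$eigenvalue, 0)
  expect_equal(cvs[[1]]$variance_fraction, 1, tolerance = 1e-10)
  idx <- resolve_selection(gen$ensemble, nsh2_selection("analysis"))
  d <- as.numeric(gen$ensemble$coords[2, idx, ] - gen$ensemble$coords[1, idx, ])
  d <- d / sqrt(sum(d^2))
  expect_equal(abs(sum(cvs[[1]]$vector * d)), 1, tolerance = 1e-10)
})

test_that("variance fractions sum to one over all vectors", {
  gen <- build_two_state_ensemble(30, 0.5, noise_sd = 0.2, seed = 4)
  cvs <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 29)
  expect_equal(sum(vapply(cvs, function(v) v$variance_fraction, numeric(1))),
               1, tolerance = 1e-8)
})

test_that("PCA orients +eta toward the alpha state (sheet opening up)", {
  gen <- build_two_state_ensemble(400, 0.5, noise_sd = 0.2, seed = 5)
  cvs <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 1)
  eta <- project(gen$ensemble, cvs[[1]])
  ops <- order_parameters(gen$ensemble)
  expect_gt(pearson(eta, ops$sheet), 0)
})

test_that("subvectors equal the normalised restriction of the parent vector", {
  gen <- build_two_state_ensemble(500, 0.5, noise_sd = 0.3, seed = 6)
  cvs <- pca(gen$ensemble, nsh2_selection("analysis"), n_vectors = 1)
  for (subset in c("py_loop", "plus5_site")) {
    agreement <- subvector_agreement(cvs[[1]], gen$ensemble,
                                     nsh2_selection(subset))
    expect_gte(agreement, 0.999)
  }
  # full selection returns the parent vector up to sign
  full <- subvector(cvs[[1]], gen$ensemble, nsh2_selection("analysis"))
  expect_gte(abs(sum(full$vector * cvs[[1]]$vector)), 1 - 1e-8)
})

test_that("subvector on a zero-weight subset errors out", {
  # mode confined to the +5 anchors: construct frames differing only there
  gen <- build_two_state_ensemble(2, 1, noise_sd = 0, seed = 7)
  at <- gen$ensemble$atoms
  i66 <- which(at$resno == 66 & at$atom == "CA")
  gen$ensemble$coords[2, i66, 3] <- gen$ensemble$coords[2, i66, 3] + 0.4
  cvs <- pca(gen$ensemble, nsh2_selection("plus5_site"), n_vectors = 1)
  expect_error(subvector(cvs[[1]], gen$ensemble,
                         selection_spec(c(70, 75), atoms = c("N", "CA", "C"))),
               "zero weight")
})

test_that("PCA requires at least two frames", {
  gen <- build_two_state_ensemble(1, 1, noise_sd = 0, seed = 9)
  expect_error(pca(gen$ensemble), "at least 2 frames")
})
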