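# Small ensembles with hand-placed coordinates for clustering tests.
make_toy_ensemble <- function(frames_list) {
  n_atoms <- nrow(frames_list[[1]])
  atoms <- data.frame(resno = seq_len(n_atoms), resname = "GLY", atom = "CA")
  coords <- aperm(array(unlist(lapply(frames_list, t)),
                        dim = c(3, n_atoms, length(frames_list))), c(3, 2, 1))
  structure_ensemble(coords, atoms)
}

toy_selection <- function(n_atoms) selection_spec(c(1, n_atoms), atoms = "CA")

test_that("rmsd_matrix is zero for identical and rigidly moved frames", {
  set.seed(1)
  base <- matrix(rnorm(30), ncol = 3)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  ens <- make_toy_ensemble(list(base, base, base %*% t(R) + 5))
  m <- rmsd_matrix(ens, toy_selection(10))
  expect_equal(m[1, 2], 0, tolerance = 1e-8)
  expect_equal(m[1, 3], 0, tolerance = 1e-8)
  expect_equal(diag(m), rep(0, 3))
  expect_equal(m, t(m))
})

test_that("rmsd_matrix entries match the per-pair brute-force oracle", {
  set.seed(2)
  frames <- lapply(1:3, function(i) matrix(rnorm(24, sd = 0.3), ncol = 3))
  ens <- make_toy_ensemble(frames)
  m <- rmsd_matrix(ens, toy_selection(8))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(m[i, j], oracle_rmsd(frames[[j]], frames[[i]]),
                   tolerance = 1e-6)
    }
  }
})

test_that("gromos_cluster handles singleton and two-group geometries", {
  # all pairwise distances above cutoff: every frame its own cluster
  m <- matrix(10, 5, 5); diag(m) <- 0
  cl <- gromos_cluster(m, 1)
  expect_length(cl$clusters, 5)
  expect_true(all(vapply(cl$clusters, function(x) length(x$members), 1L) == 1))

  # two tight groups: two unrelated configurations, each with tiny
  # within-group noise, so between-group RMSD >> within-group RMSD
  set.seed(3)
  g1 <- matrix(rnorm(30, sd = 1), ncol = 3)
  g2 <- matrix(rnorm(30, sd = 1), ncol = 3)
  frames <- c(lapply(1:4, function(i) g1 + rnorm(30, sd = 0.01)),
              lapply(1:3, function(i) g2 + rnorm(30, sd = 0.01)))
  m2 <- rmsd_matrix(make_toy_ensemble(frames), toy_selection(10))
  cl2 <- gromos_cluster(m2, 2)
  expect_length(cl2$clusters, 2)
  expect_setequal(cl2$clusters[[1]]$members, 1:4)
  expect_setequal(cl2$clusters[[2]]$members, 5:7)
})

test_that("gromos_cluster agrees with the exhaustive oracle on random matrices", {
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    d <- matrix(runif(n * n, 0, 3), n, n)
    m <- (d + t(d)) / 2; diag(m) <- 0
    cutoff <- runif(1, 0.5, 2.5)
    got <- gromos_cluster(m, cutoff)$clusters
    want <- oracle_gromos(m, cutoff)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$center, want[[k]]$center)
      expect_setequal(got[[k]]$members, want[[k]]$members)
    }
  }
})

test_that("cluster membership radius never exceeds the cutoff", {
  set.seed(5)
  d <- matrix(runif(400, 0, 3), 20, 20)
  m <- (d + t(d)) / 2; diag(m) <- 0
  cl <- gromos_cluster(m, 1.2)
  for (c_ in cl$clusters) {
    expect_true(all(m[c_$center, c_$members] <= 1.2))
  }
  # disjoint cover
  all_members <- unlist(lapply(cl$clusters, `[[`, "members"))
  expect_setequal(all_members, 1:20)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("clustering is invariant under frame relabeling", {
  set.seed(6)
  d <- matrix(runif(64, 0, 2), 8, 8)
  m <- (d + t(d)) / 2; diag(m) <- 0
  perm <- sample(8)
  mp <- m[perm, perm]
  cl <- gromos_cluster(m, 1)$clusters
  clp <- gromos_cluster(mp, 1)$clusters
  # map permuted result back to original labels; sizes and memberships match
  back <- lapply(clp, function(x) sort(perm[x$members]))
  orig <- lapply(cl, function(x) sort(x$members))
  expect_setequal(vapply(back, paste, "", collapse = ","),
                  vapply(orig, paste, "", collapse = ","))
})

test_that("choose_cutoff finds the first mode of the RMSD distribution", {
  # bimodal: pairwise values near 1 A and near 4 A
  set.seed(7)
  vals <- c(rnorm(300, 1, 0.1), rnorm(300, 4, 0.1))
  n <- 35 # 35*34/2 = 595 pairs
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals[seq_len(n * (n - 1) / 2)]
  m <- m + t(m)
  cc <- as.numeric(choose_cutoff(m))
  expect_lt(abs(cc - 1), 0.5)

  # single mode at 2 A
  vals1 <- rnorm(595, 2, 0.2)
  m1 <- matrix(0, n, n)
  m1[upper.tri(m1)] <- vals1
  m1 <- m1 + t(m1)
  expect_lt(abs(as.numeric(choose_cutoff(m1)) - 2), 0.5)

  # too few values
  m2 <- matrix(1, 4, 4); diag(m2) <- 0
  expect_error(choose_cutoff(m2), "at least 10")
})

test_that("seed_windows partitions the trace and picks dominant clusters", {
  set.seed(8)
  # trace spanning [0, 1] uniformly, toy ensemble of near-identical frames
  n <- 60
  base <- matrix(rnorm(30), ncol = 3)
  frames <- lapply(1:n, function(i) base + rnorm(30, sd = 0.005))
  ens <- make_toy_ensemble(frames)
  trace <- data.frame(value = seq(0, 1, length.out = n), frame = 1:n)
  seeds <- seed_windows(trace, ens, 10, c(0, 1), toy_selection(10))
  expect_equal(nrow(seeds), 10)
  for (w in 1:10) {
    v <- trace$value[trace$frame == seeds$seed_frame[w]]
    expect_gte(v, seeds$lo[w])
    expect_lte(v, seeds$hi[w] + 1e-12)
  }

  # single-frame interval seeds with that frame
  trace1 <- data.frame(value = c(0.2, 0.6, 0.7, 0.8, 0.9, 1.0),
                       frame = 1:6)
  s1 <- seed_windows(trace1, ens, 2, c(0.2, 1), toy_selection(10))
  expect_equal(s1$seed_frame[1], 1L)

  # 7-vs-3 cluster structure inside one interval: seed is the 7-cluster centre
  g1 <- base
  g2 <- base + 3
  frames2 <- c(lapply(1:7, function(i) g1 + rnorm(30, sd = 0.01)),
               lapply(1:3, function(i) g2 + rnorm(30, sd = 0.01)))
  ens2 <- make_toy_ensemble(frames2)
  trace2 <- data.frame(value = seq(0, 1, length.out = 10), frame = 1:10)
  s2 <- seed_windows(trace2, ens2, 1, c(0, 1), toy_selection(10))
  expect_true(s2$seed_frame[1] %in% 1:7)

  # empty interval errors with the interval named
  trace3 <- data.frame(value = c(0, 0.45, 1), frame = 1:3)
  expect_error(seed_windows(trace3, ens, 5, c(0, 1), toy_selection(10)),
               "interval")
})
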