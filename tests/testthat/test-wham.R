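test_that("single biased window on a flat landscape recovers a flat profile", {
  # near-zero stiffness potential ~ flat landscape; the umbrella bias is
  # divided out so G should be constant where sampled
  flat <- potential_1d("harmonic", K = 1e-8)
  uws <- sample_umbrella_windows(flat, 0, 1000, 1e5, seed = 1)
  prof <- wham_solve(uws, bins = 50)
  inner <- prof$center > quantile(unlist(uws$samples), 0.02) &
    prof$center < quantile(unlist(uws$samples), 0.98)
  expect_lt(diff(range(prof$G[inner])), 0.3)
})

test_that("24 windows recover the harmonic free-energy profile", {
  pot <- potential_1d("harmonic", K = 50)
  refs <- seq(-0.6, 0.6, length.out = 24)
  uws <- sample_umbrella_windows(pot, refs, 1000, 5000, seed = 2)
  prof <- wham_solve(uws)
  truth <- 0.5 * 50 * prof$center^2
  inside <- prof$center >= min(refs) & prof$center <= max(refs)
  dev <- prof$G[inside] - truth[inside]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.5)
  # min-zero convention
  expect_equal(min(prof$G), 0)
  expect_identical(attr(prof, "offset_convention"), "min-zero")
})

test_that("window replication leaves the WHAM profile unchanged", {
  pot <- potential_1d("harmonic", K = 50)
  refs <- seq(-0.3, 0.3, length.out = 6)
  uws <- sample_umbrella_windows(pot, refs, 800, 2000, seed = 3)
  dup <- umbrella_window_set(c(uws$references, uws$references),
                             c(uws$force_constants, uws$force_constants),
                             c(uws$samples, uws$samples))
  edges <- attr(wham_solve(uws, bins = 100, tolerance = 1e-10), "edges")
  p1 <- wham_solve(uws, bins = edges, tolerance = 1e-10)
  p2 <- wham_solve(dup, bins = edges, tolerance = 1e-10)
  expect_equal(p1$G, p2$G, tolerance = 1e-8)
})

test_that("a single unbiased window reduces WHAM to -kT log(histogram)", {
  pot <- potential_1d("double_well", h = 5, a = 0.4)
  s <- sample_boltzmann_1d(pot, n = 2e4, seed = 4)
  uws <- umbrella_window_set(0, 0, list(s))
  prof <- wham_solve(uws, bins = 40)
  h <- hist(s, breaks = attr(prof, "edges"), plot = FALSE)
  ref <- -kB * 300 * log(h$counts[h$counts > 0])
  ref <- ref - min(ref)
  expect_equal(prof$G, ref, tolerance = 1e-6)
})

test_that("profiles are stable under bin-count doubling", {
  pot <- potential_1d("harmonic", K = 50)
  refs <- seq(-0.4, 0.4, length.out = 12)
  uws <- sample_umbrella_windows(pot, refs, 1000, 1e4, seed = 5)
  p200 <- wham_solve(uws, bins = 200)
  p400 <- wham_solve(uws, bins = 400)
  # compare on the coarse grid via interpolation, well-sampled region only
  inside <- p200$center >= min(refs) & p200$center <= max(refs)
  g400 <- approx(p400$center, p400$G, xout = p200$center[inside])$y
  dev <- g400 - p200$G[inside]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("reported F_i satisfy the self-consistency equations", {
  pot <- potential_1d("harmonic", K = 50)
  refs <- seq(-0.3, 0.3, length.out = 8)
  uws <- sample_umbrella_windows(pot, refs, 1000, 3000, seed = 6)
  tol <- 1e-6
  prof <- wham_solve(uws, bins = 150, tolerance = tol)
  Fi <- attr(prof, "F_i")
  beta <- 1 / (kB * 300)
  edges <- attr(prof, "edges")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- t(vapply(uws$samples, function(s) {
    idx <- cut(s, breaks = edges, include.lowest = TRUE, labels = FALSE)
    tabulate(idx[!is.na(idx)], nbins = length(centers))
  }, numeric(length(centers))))
  Ni <- rowSums(counts)
  bias <- outer(seq_along(refs), seq_along(centers), function(i, j) {
    0.5 * 1000 * (centers[j] - refs[i])^2
  })
  p <- colSums(counts) / colSums(Ni * exp(beta * (Fi - bias)))
  Fi_new <- -log(exp(-beta * bias) %*% p) / beta
  Fi_new <- Fi_new - Fi_new[1]
  expect_lt(max(abs(Fi_new - Fi)), 10 * tol)
})

test_that("non-overlapping windows produce an error naming the gap", {
  pot <- potential_1d("harmonic", K = 50)
  uws <- sample_umbrella_windows(pot, c(-1.0, 1.0), 4000, 500, seed = 7)
  expect_error(wham_solve(uws, bins = 200), "do not overlap")
})

test_that("bootstrap errors vanish for identical windows and shrink with n", {
  pot <- potential_1d("harmonic", K = 50)
  s <- sample_boltzmann_1d(pot, bias = harmonic_bias(200, 0), n = 5000,
                           seed = 8)
  same <- umbrella_window_set(rep(0, 4), 200,
                              list(s, s, s, s))
  prof_same <- bayesian_bootstrap(same, bins = 60, n_boot = 50, seed = 9)
  expect_lt(max(prof_same$error, na.rm = TRUE), 0.05)

  refs <- seq(-0.4, 0.4, length.out = 8)
  small <- sample_umbrella_windows(pot, refs, 1000, 500, seed = 10)
  large <- sample_umbrella_windows(pot, refs, 1000, 2000, seed = 11)
  es <- bayesian_bootstrap(small, bins = 80, n_boot = 60, seed = 12)
  el <- bayesian_bootstrap(large, bins = 80, n_boot = 60, seed = 13)
  expect_lt(mean(el$error, na.rm = TRUE), mean(es$error, na.rm = TRUE))
})

test_that("bootstrap errors are stable across replicate counts and seeds", {
  pot <- potential_1d("harmonic", K = 50)
  refs <- seq(-0.3, 0.3, length.out = 6)
  uws <- sample_umbrella_windows(pot, refs, 1000, 1500, seed = 14)
  e1 <- bayesian_bootstrap(uws, bins = 60, n_boot = 100, seed = 15)
  e2 <- bayesian_bootstrap(uws, bins = 60, n_boot = 200, seed = 16)
  inside <- e1$center >= -0.3 & e1$center <= 0.3
  ratio <- e1$error[inside] / e2$error[inside]
  expect_lt(median(abs(ratio - 1)), 0.3)
})

test_that("bayesian bootstrap refuses a single window", {
  pot <- potential_1d("harmonic", K = 50)
  uws <- sample_umbrella_windows(pot, 0, 1000, 500, seed = 17)
  expect_error(bayesian_bootstrap(uws, n_boot = 50, seed = 1),
               ">= 2 windows")
})

test_that("align_profiles recovers additive shifts exactly", {
  pot <- potential_1d("harmonic", K = 50)
  uws <- sample_umbrella_windows(pot, seq(-0.3, 0.3, length.out = 6), 1000,
                                 2000, seed = 18)
  a <- wham_solve(uws, bins = 80)
  b <- a
  b$G <- b$G + 7
  aligned <- align_profiles(a, b)
  expect_equal(attr(aligned, "shift"), -7, tolerance = 1e-12)
  expect_equal(aligned$G, a$G, tolerance = 1e-12)
  # a = b gives zero shift
  expect_equal(attr(align_profiles(a, a), "shift"), 0, tolerance = 1e-12)
  # noisy copies: shift equals the difference of region means
  set.seed(19)
  c_ <- a
  c_$G <- c_$G + rnorm(length(c_$G), sd = 0.05) + 3
  region <- c(-0.2, 0.2)
  aligned_c <- align_profiles(a, c_, region)
  sel <- a$center >= region[1] & a$center <= region[2]
  expect_equal(attr(aligned_c, "shift"), -mean(c_$G[sel] - a$G[sel]),
               tolerance = 1e-10)
})
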