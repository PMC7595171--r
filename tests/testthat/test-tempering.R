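test_that("Park-Pande weights match hand evaluation on the harmonic oscillator", {
  # 1-D harmonic: mean potential energy kB T / 2 at each temperature
  lad <- temperature_ladder(c(300, 350))
  e_mean <- kB * c(300, 350) / 2
  lad2 <- park_pande_weights(e_mean, lad)
  b1 <- 1 / (kB * 300); b2 <- 1 / (kB * 350)
  f2_hand <- (b2 - b1) * (e_mean[1] + e_mean[2]) / 2
  expect_equal(lad2$weights, c(0, f2_hand), tolerance = 1e-12)

  # missing rung energy errors
  expect_error(park_pande_weights(c(1, NA), lad), "every rung")
  # zero beta step gives equal weights
  lad_eq <- temperature_ladder(c(300, 300 + 1e-9))
  expect_equal(diff(park_pande_weights(c(5, 5), lad_eq)$weights), 0,
               tolerance = 1e-10)
})

test_that("Park-Pande weights shift but acceptance ratios do not under energy offsets", {
  lad <- temperature_ladder(seq(300, 340, by = 20))
  e <- c(2, 2.4, 2.9)
  la <- park_pande_weights(e, lad)
  lb <- park_pande_weights(e + 100, lad)
  # acceptance log-ratio between rungs i,j at energy U: the offset in U and
  # in the weights cancel
  U <- 5
  for (i in 1:2) {
    j <- i + 1
    log_a <- -(la$betas[j] - la$betas[i]) * U + (la$weights[j] - la$weights[i])
    log_b <- -(lb$betas[j] - lb$betas[i]) * (U + 100) +
      (lb$weights[j] - lb$weights[i])
    expect_equal(log_a, log_b, tolerance = 1e-9)
  }
})

test_that("st_attempt implements the Metropolis rule", {
  lad <- temperature_ladder(c(300, 350), weights = c(0, 0))
  # equal beta and weights: always accepted
  lad_eq <- temperature_ladder(c(300, 300 + 1e-12))
  expect_equal(st_attempt(1, 2, 10, lad_eq, 0.999999), 2)
  # huge positive energy moving to colder->hotter... beta_j < beta_i is
  # favourable; the unfavourable direction (hotter->colder, beta_j > beta_i)
  # with huge U is always rejected
  expect_equal(st_attempt(2, 1, 1e6, lad, 0.001), 2)
  # out-of-range and non-adjacent proposals rejected with errors
  expect_error(st_attempt(1, 3, 1, lad, 0.5), "out of range")
  lad3 <- temperature_ladder(c(300, 320, 340))
  expect_error(st_attempt(1, 3, 1, lad3, 0.5), "nearest-neighbour")

  # acceptance frequency matches the Metropolis average under the rung-1
  # Boltzmann distribution (quadrature oracle)
  pot <- potential_1d("harmonic", K = 100)
  x <- sample_boltzmann_1d(pot, temperature = 300, n = 20000, seed = 1)
  U <- potential_energy(pot, x)
  set.seed(2)
  u <- runif(length(U))
  acc <- mean(vapply(seq_along(U), function(t) {
    st_attempt(1, 2, U[t], lad, u[t]) == 2
  }, logical(1)))
  d <- oracle_biased_density(pot, NULL, 300, -0.8, 0.8)
  du <- 0.5 * 100 * d$x^2
  p_acc <- pmin(1, exp(-(1 / (kB * 350) - 1 / (kB * 300)) * du))
  acc_oracle <- sum(d$density * p_acc) / sum(d$density)
  expect_lt(abs(acc - acc_oracle), 3 * sqrt(0.25 / length(U)) + 0.01)
})

test_that("Wang-Landau updates, flatness resets, and degenerate ladders behave", {
  lad1 <- temperature_ladder(300)
  lad1b <- wl_update(lad1, 1)
  # single rung: only a global constant changes
  expect_equal(diff(lad1b$weights), numeric(0))

  lad <- temperature_ladder(c(300, 320), weights = c(0, 0))
  lad$flatness <- 2  # never reset in this test
  # alternating visits: weights oscillate with amplitude delta around equality
  l <- lad
  diffs <- numeric(6)
  for (k in 1:6) {
    l <- wl_update(l, 1 + (k %% 2))
    diffs[k] <- l$weights[1] - l$weights[2]
  }
  expect_true(all(abs(diffs) <= l$delta + 1e-12))

  # flatness reset shrinks delta and clears the histogram
  l2 <- temperature_ladder(c(300, 320))
  l2$flatness <- 0.5
  l2$min_stage_visits <- 1L
  l2 <- wl_update(l2, 1)
  l2 <- wl_update(l2, 2)   # histogram (1,1): flat, reset triggers
  expect_equal(l2$delta, 0.5)
  expect_equal(l2$histogram, c(0L, 0L))

  expect_error(wl_update(lad, 1, delta = -1), "delta")
})

test_that("exact weights give flat rung occupancy (autocorrelation-aware)", {
  pot <- potential_1d("harmonic", K = 100)
  lad <- ladder_preset("shp2_opening")
  expect_equal(lad$temperatures, seq(300, 400, by = 5))
  lad$weights <- exact_tempering_weights(pot, lad)
  run <- run_simulated_tempering(pot, lad, 1e5, seed = 3)
  # the rung sequence is a nearest-neighbour chain with relaxation time
  # ~ 2 K^2 / pi^2 = 90 attempts; thin far beyond that and test uniformity
  # of the effectively independent samples at the 3-sigma level
  thin <- run$rungs[seq(1000, 1e5, by = 500)]
  tab <- tabulate(thin, nbins = 21)
  p <- chisq.test(tab, p = rep(1 / 21, 21))$p.value
  expect_gt(p, 0.0027)
})

test_that("Wang-Landau converges to the exact betaF ladder", {
  pot <- potential_1d("harmonic", K = 100)
  lad <- ladder_preset("shp2_opening")
  f_exact <- exact_tempering_weights(pot, lad)
  run <- run_simulated_tempering(pot, lad, 2e5, seed = 4, wang_landau = TRUE)
  expect_lt(run$ladder$delta, 1e-3)
  w <- run$ladder$weights
  dev <- (w - f_exact) - mean(w - f_exact)  # additive constant removed
  expect_lt(max(abs(dev)), 0.2)
})

test_that("base-temperature marginal of a tempered run is Boltzmann", {
  pot <- potential_1d("harmonic", K = 100)
  lad <- temperature_ladder(c(300, 330, 360))
  lad$weights <- exact_tempering_weights(pot, lad)
  run <- run_simulated_tempering(pot, lad, 5e4, seed = 5)
  base_x <- run$positions[run$rungs_sampled == 1]
  oracle <- oracle_biased_density(pot, NULL, 300, -0.8, 0.8)
  expect_lt(oracle_ks_distance(base_x, oracle), 0.02)
})

test_that("ladder presets reproduce the two tempering protocols", {
  expect_equal(ladder_preset("shp2_opening")$temperatures,
               seq(300, 400, by = 5))
  expect_equal(ladder_preset("sheet_opening")$temperatures,
               seq(300, 380, by = 10))
  expect_error(temperature_ladder(c(300, 300)), "ascending")
})
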