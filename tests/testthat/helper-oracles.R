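# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths wherever the package result is under test.

# Boltzmann density of potential + optional harmonic bias on a fixed grid,
# by direct quadrature (trapezoid) on n_grid points.
oracle_biased_density <- function(potential, bias = NULL, temperature = 300,
                                  lo, hi, n_grid = 10000L) {
  beta <- 1 / (0.0083145 * temperature)
  xs <- seq(lo, hi, length.out = n_grid)
  u <- switch(potential$kind,
    harmonic = 0.5 * potential$K * (xs - potential$x0)^2,
    double_well = potential$h * ((xs / potential$a)^2 - 1)^2
  )
  if (!is.null(bias)) u <- u + 0.5 * bias$k * (xs - bias$ref)^2
  d <- exp(-beta * (u - min(u)))
  dx <- xs[2] - xs[1]
  z <- sum((d[-1] + d[-n_grid]) / 2) * dx
  list(x = xs, density = d / z,
       cdf = c(0, cumsum((d[-1] + d[-n_grid]) / 2) * dx / z))
}

# Kolmogorov-Smirnov distance between samples and an oracle CDF.
oracle_ks_distance <- function(samples, oracle) {
  ec <- stats::ecdf(samples)
  max(abs(ec(oracle$x) - oracle$cdf))
}

# Brute-force optimal-superposition RMSD: random-quaternion search plus
# Nelder-Mead refinement, independent of the Kabsch SVD route.
oracle_rmsd <- function(P, Q, n_grid = 4000L, seed = 42) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  fval <- function(q) sqrt(mean(rowSums((Pc %*% t(quat_rot(q)) - Qc)^2)))
  set.seed(seed)
  qs <- matrix(stats::rnorm(4L * n_grid), ncol = 4L)
  vals <- apply(qs, 1, fval)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, fval, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- stats::optim(opt$par, fval, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  10 * opt2$value  # Angstrom
}

# Exhaustive re-implementation of greedy neighbour-count clustering that
# recomputes neighbour counts from scratch each round, with explicit loops.
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  pool <- seq_len(n)
  clusters <- list()
  while (length(pool) > 0L) {
    best_count <- -1L
    best_frame <- NA_integer_
    for (f in pool) {
      cnt <- 0L
      for (g in pool) if (m[f, g] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) {
        best_count <- cnt
        best_frame <- f
      }
    }
    members <- integer(0)
    for (g in pool) if (m[best_frame, g] <= cutoff) members <- c(members, g)
    clusters[[length(clusters) + 1L]] <- list(center = best_frame,
                                              members = members)
    pool <- setdiff(pool, members)
  }
  clusters
}

# Crooks-consistent normal densities, analytic log-ratio.
oracle_crooks_log_ratio <- function(w, dg, sigma, temperature = 300) {
  beta <- 1 / (0.0083145 * temperature)
  mf <- dg + beta * sigma^2 / 2
  mr <- -dg + beta * sigma^2 / 2
  stats::dnorm(w, mf, sigma, log = TRUE) -
    stats::dnorm(-w, mr, sigma, log = TRUE)
}

kB <- 0.0083145
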