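#' Exact Boltzmann sampling of a (biased) 1-D potential
#'
#' Draws i.i.d. samples from the density proportional to
#' exp(-beta [U(x) + k/2 (x - ref)^2]) by inverse-CDF sampling on a fine
#' grid. Sampling is exact (up to grid resolution), not a Markov chain, so
#' umbrella-window inputs carry no equilibration artefacts.
#'
#' @param potential A [potential_1d()].
#' @param bias Optional [harmonic_bias()] (umbrella restraint).
#' @param temperature Temperature in K.
#' @param n Number of samples, >= 1.
#' @param seed Integer seed; samples are reproducible bit-for-bit.
#' @param n_grid Inverse-CDF grid size (default 2^15 + 1).
#' @return Numeric vector of `n` positions in nm.
#' @examples
#' x <- sample_boltzmann_1d(potential_1d("harmonic", K = 1000), n = 1000, seed = 1)
#' var(x) # ~ kB T / K
#' @export
sample_boltzmann_1d <- function(potential, bias = NULL, temperature = 300,
                                n, seed, n_grid = 32769L) {
  stopifnot(inherits(potential, "potential_1d"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  beta <- beta_of(temperature)
  biases <- if (is.null(bias)) list() else list(bias)
  dom <- sampling_domain(potential, biases, temperature)
  xs <- seq(dom[1], dom[2], length.out = n_grid)
  u <- total_energy(potential, xs, biases)
  if (any(!is.finite(u))) {
    stop("potential is non-finite on the sampling domain", call. = FALSE)
  }
  dens <- exp(-beta * (u - min(u)))
  # trapezoidal cumulative integral -> CDF
  dx <- xs[2] - xs[1]
  cdf <- c(0, cumsum((dens[-1] + dens[-n_grid]) / 2) * dx)
  cdf <- cdf / cdf[n_grid]
  # strictly increasing knots for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  with_seed(seed, {
    stats::approx(cdf[keep], xs[keep], xout = stats::runif(n),
                  rule = 2, ties = "ordered")$y
  })
}

#' Overdamped Langevin trajectory on a 1-D potential
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' dx = -U'(x)/gamma dt + sqrt(2 kB T dt / gamma) N(0,1). The long-run
#' histogram converges to the Boltzmann density of the total potential.
#'
#' Stability bound: the deterministic part of the update is a contraction only
#' when dt * Kmax / gamma < 2, with Kmax the maximum curvature of the total
#' potential over the sampled domain; the integrator refuses to run when
#' dt * Kmax / gamma >= 2 and additionally aborts if the trajectory diverges.
#'
#' @param potential A [potential_1d()].
#' @param biases List of [harmonic_bias()] terms (may be empty).
#' @param temperature Temperature in K (>= 0; 0 gives deterministic descent).
#' @param friction Friction coefficient gamma, kJ mol^-1 ps nm^-2 (> 0).
#' @param dt Time step, ps.
#' @param n_steps Number of steps, >= 1.
#' @param seed Integer seed.
#' @param x0 Initial position, nm.
#' @return Numeric vector of length `n_steps + 1` (includes `x0`).
#' @export
langevin_trajectory <- function(potential, biases = list(), temperature = 300,
                                friction = 10, dt = 0.002, n_steps, seed,
                                x0 = NULL) {
  stopifnot(inherits(potential, "potential_1d"))
  if (temperature < 0) stop("temperature must be >= 0 K", call. = FALSE)
  stopifnot(friction > 0, dt > 0, n_steps >= 1)
  if (is.null(x0)) {
    x0 <- switch(potential$kind, harmonic = potential$x0,
                 double_well = -potential$a)
  }
  dom <- sampling_domain(potential, biases, max(temperature, 1))
  kmax <- potential_max_curvature(potential, dom[1], dom[2]) +
    sum(vapply(biases, function(b) b$k, numeric(1)))
  if (dt * kmax / friction >= 2) {
    stop(sprintf(
      "unstable integrator parameters: dt * Kmax / friction = %.3g >= 2",
      dt * kmax / friction
    ), call. = FALSE)
  }
  sigma <- sqrt(2 * KB_KJ_MOL_K * temperature * dt / friction)
  bound <- max(abs(dom)) * 10 + 10
  with_seed(seed, {
    noise <- if (sigma > 0) stats::rnorm(n_steps, sd = sigma) else numeric(n_steps)
    x <- numeric(n_steps + 1)
    x[1] <- x0
    for (i in seq_len(n_steps)) {
      xi <- x[i]
      g <- total_gradient(potential, xi, biases)
      xn <- xi - g * dt / friction + noise[i]
      if (!is.finite(xn) || abs(xn) > bound) {
        stop(sprintf("trajectory diverged at step %d", i), call. = FALSE)
      }
      x[i + 1] <- xn
    }
    x
  })
}
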