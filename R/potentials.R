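#' One-dimensional model potentials
#'
#' Analytic 1-D potentials stand in for molecular free-energy landscapes when
#' exercising the umbrella-sampling, nonequilibrium-work and tempering
#' machinery on systems with known ground truth. Two functional forms are
#' provided:
#' \describe{
#'   \item{harmonic}{U(x) = K/2 (x - x0)^2, stiffness `K` in kJ/mol/nm^2,
#'     centre `x0` in nm.}
#'   \item{double_well}{U(x) = h ((x/a)^2 - 1)^2, barrier height `h` in
#'     kJ/mol, well half-separation `a` in nm; minima at x = -a, +a.}
#' }
#' The analytic free-energy profile of a 1-D system equals U(x) up to an
#' additive constant, which is what makes these potentials exact oracles.
#'
#' @param kind `"harmonic"` or `"double_well"`.
#' @param K,x0 Harmonic stiffness (kJ/mol/nm^2) and centre (nm).
#' @param h,a Double-well barrier height (kJ/mol) and half-separation (nm).
#' @return An object of class `potential_1d`.
#' @examples
#' u <- potential_1d("double_well", h = 10, a = 0.5)
#' potential_energy(u, c(-0.5, 0, 0.5))
#' @export
potential_1d <- function(kind = c("harmonic", "double_well"),
                         K = 1000, x0 = 0, h = 10, a = 0.5) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    stopifnot(is.finite(K), K > 0, is.finite(x0))
    p <- list(kind = kind, K = K, x0 = x0)
  } else {
    stopifnot(is.finite(h), h > 0, is.finite(a), a > 0)
    p <- list(kind = kind, h = h, a = a)
  }
  structure(p, class = "potential_1d")
}

#' @rdname potential_1d
#' @param potential A `potential_1d`.
#' @param x Positions, nm.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "potential_1d"))
  u <- switch(potential$kind,
    harmonic = 0.5 * potential$K * (x - potential$x0)^2,
    double_well = potential$h * ((x / potential$a)^2 - 1)^2
  )
  if (any(!is.finite(u[is.finite(x)]))) {
    stop("potential is non-finite on the requested domain", call. = FALSE)
  }
  u
}

#' @rdname potential_1d
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "potential_1d"))
  switch(potential$kind,
    harmonic = potential$K * (x - potential$x0),
    double_well = 4 * potential$h * x * ((x / potential$a)^2 - 1) / potential$a^2
  )
}

# Maximum curvature of the potential over an interval; used for the
# Euler-Maruyama stability bound.
potential_max_curvature <- function(potential, lo, hi) {
  switch(potential$kind,
    harmonic = potential$K,
    double_well = {
      xs <- c(lo, hi, 0)
      max(abs(4 * potential$h * (3 * xs^2 / potential$a^2 - 1) / potential$a^2))
    }
  )
}

#' Harmonic bias term
#'
#' Umbrella/pulling bias w(x) = k/2 (x - ref)^2 added on top of a
#' [potential_1d()].
#'
#' @param k Force constant, kJ/mol/nm^2, >= 0.
#' @param ref Reference position, nm.
#' @return An object of class `harmonic_bias`.
#' @export
harmonic_bias <- function(k, ref) {
  stopifnot(is.finite(k), k >= 0, is.finite(ref))
  structure(list(k = k, ref = ref), class = "harmonic_bias")
}

# Total energy / gradient of potential plus a list of harmonic bias terms.
total_energy <- function(potential, x, biases = list()) {
  u <- potential_energy(potential, x)
  for (b in biases) u <- u + 0.5 * b$k * (x - b$ref)^2
  u
}

total_gradient <- function(potential, x, biases = list()) {
  g <- potential_gradient(potential, x)
  for (b in biases) g <- g + b$k * (x - b$ref)
  g
}

# Default sampling domain for a (possibly biased) potential at temperature T:
# the interval where the Boltzmann density exceeds ~exp(-40) of its maximum,
# found by scanning outward from the energy minima.
sampling_domain <- function(potential, biases = list(), temperature = 300,
                            n_scan = 4096L) {
  centers <- switch(potential$kind,
    harmonic = potential$x0,
    double_well = c(-potential$a, potential$a)
  )
  for (b in biases) if (b$k > 0) centers <- c(centers, b$ref)
  span <- max(1, diff(range(centers)))
  lo <- min(centers) - 5 * span
  hi <- max(centers) + 5 * span
  xs <- seq(lo, hi, length.out = n_scan)
  u <- total_energy(potential, xs, biases)
  cut <- min(u) + 40 * KB_KJ_MOL_K * temperature
  keep <- which(u <= cut)
  c(xs[max(1L, min(keep) - 1L)], xs[min(n_scan, max(keep) + 1L)])
}

#' Free energy of a biased 1-D system by quadrature
#'
#' F = -kB T log Z with Z = int exp(-beta [U(x) + biases]) dx, evaluated by
#' trapezoidal quadrature on a fine grid. Serves as the analytic oracle for
#' pulled end-state free-energy differences.
#'
#' @param potential A [potential_1d()].
#' @param biases List of [harmonic_bias()] terms.
#' @param temperature Temperature, K.
#' @param n_grid Quadrature grid size.
#' @return Free energy in kJ/mol (additive constant fixed by the measure dx).
#' @export
free_energy_quadrature <- function(potential, biases = list(),
                                   temperature = 300, n_grid = 20000L) {
  beta <- beta_of(temperature)
  dom <- sampling_domain(potential, biases, temperature)
  xs <- seq(dom[1], dom[2], length.out = n_grid)
  u <- total_energy(potential, xs, biases)
  u0 <- min(u)
  w <- exp(-beta * (u - u0))
  z <- sum((w[-1] + w[-n_grid]) / 2) * (xs[2] - xs[1])
  u0 - log(z) / beta
}
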