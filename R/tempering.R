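#' Temperature ladders for simulated tempering
#'
#' A strictly ascending set of temperatures with per-rung dimensionless
#' weights f_i and a visit histogram. Two named presets reproduce the
#' protocols used for the two pulling problems: `"shp2_opening"` (300-400 K
#' in steps of 5 K) and `"sheet_opening"` (300-380 K in steps of 10 K).
#'
#' @param temperatures Ascending numeric vector, K.
#' @param weights Initial weights f_i (default all 0).
#' @return Object of class `temperature_ladder` with fields `temperatures`,
#'   `betas`, `weights`, `histogram`, and Wang-Landau state (`delta`,
#'   `flatness`, `scale`).
#' @export
temperature_ladder <- function(temperatures, weights = NULL) {
  stopifnot(is.numeric(temperatures), length(temperatures) >= 1L)
  if (any(diff(temperatures) <= 0)) {
    stop("temperatures must be strictly ascending", call. = FALSE)
  }
  if (is.null(weights)) weights <- numeric(length(temperatures))
  stopifnot(length(weights) == length(temperatures), all(is.finite(weights)))
  structure(list(temperatures = temperatures,
                 betas = beta_of(temperatures),
                 weights = weights,
                 histogram = integer(length(temperatures)),
                 delta = 1, flatness = 0.8, scale = 0.5,
                 min_stage_visits = 20L),
            class = "temperature_ladder")
}

#' @rdname temperature_ladder
#' @param preset `"shp2_opening"` or `"sheet_opening"`.
#' @export
ladder_preset <- function(preset = c("shp2_opening", "sheet_opening")) {
  preset <- match.arg(preset)
  switch(preset,
    shp2_opening = temperature_ladder(seq(300, 400, by = 5)),
    sheet_opening = temperature_ladder(seq(300, 380, by = 10))
  )
}

#' Park-Pande initial tempering weights
#'
#' Trapezoidal thermodynamic-integration estimate of the dimensionless free
#' energies beta_i F_i from per-rung mean potential energies:
#' f_1 = 0, f_(i+1) = f_i + (beta_(i+1) - beta_i)(Ebar_i + Ebar_(i+1)) / 2.
#' Acceptance ratios depend only on weight differences, so the weights are
#' defined up to an additive constant.
#'
#' @param mean_energies Mean potential energy at each rung, kJ/mol (from
#'   short unweighted pre-runs).
#' @param ladder A [temperature_ladder()].
#' @return The ladder with `weights` replaced.
#' @export
park_pande_weights <- function(mean_energies, ladder) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  n <- length(ladder$temperatures)
  if (length(mean_energies) != n || any(!is.finite(mean_energies))) {
    stop("a finite mean energy is required for every rung", call. = FALSE)
  }
  f <- numeric(n)
  for (i in seq_len(n - 1L)) {
    f[i + 1L] <- f[i] + (ladder$betas[i + 1L] - ladder$betas[i]) *
      (mean_energies[i] + mean_energies[i + 1L]) / 2
  }
  ladder$weights <- f
  ladder
}

#' Metropolis rung-exchange attempt
#'
#' Proposes moving the tempering chain from rung `i` to an adjacent rung `j`
#' and accepts with probability
#' min(1, exp[-(beta_j - beta_i) U + (f_j - f_i)]), which yields canonical
#' ensembles at every rung for fixed weights.
#'
#' @param i Current rung index.
#' @param j Proposed rung index, adjacent to `i`.
#' @param U Current potential energy, kJ/mol.
#' @param ladder A [temperature_ladder()].
#' @param u Uniform(0,1) random number driving the decision (pass
#'   `runif(1)`; explicit so callers own the RNG stream).
#' @return Accepted rung index (`j` on acceptance, `i` otherwise).
#' @export
st_attempt <- function(i, j, U, ladder, u) {
  n <- length(ladder$temperatures)
  if (j < 1L || j > n) stop("proposed rung out of range", call. = FALSE)
  if (abs(j - i) > 1L) {
    stop("only nearest-neighbour rung proposals are allowed", call. = FALSE)
  }
  log_acc <- -(ladder$betas[j] - ladder$betas[i]) * U +
    (ladder$weights[j] - ladder$weights[i])
  if (log(u) < log_acc) j else i
}

#' Wang-Landau weight update
#'
#' After a visit to rung `visited`: the visited weight is decreased by the
#' increment delta (convention: lowering f_i makes the rung less likely to
#' be re-entered, pushing occupancy toward flatness; only weight differences
#' matter), the visit histogram is incremented, and whenever the histogram
#' flatness min/mean exceeds the threshold the increment is scaled down and
#' the histogram reset. A stage only completes once every rung has collected
#' at least `min_stage_visits` counts: a single sweep of a nearest-neighbour
#' rung walk already produces a deceptively flat residence histogram, and
#' halving on such sweeps freezes the increment long before the weights have
#' equilibrated.
#'
#' @param ladder A [temperature_ladder()].
#' @param visited Rung index just visited.
#' @param delta Optional override of the current increment (> 0).
#' @return Updated ladder.
#' @export
wl_update <- function(ladder, visited, delta = NULL) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  if (!is.null(delta)) {
    if (delta <= 0) stop("delta must be > 0", call. = FALSE)
    ladder$delta <- delta
  }
  ladder$weights[visited] <- ladder$weights[visited] - ladder$delta
  ladder$histogram[visited] <- ladder$histogram[visited] + 1L
  h <- ladder$histogram
  if (min(h) >= ladder$min_stage_visits &&
        min(h) / mean(h) > ladder$flatness) {
    ladder$delta <- ladder$delta * ladder$scale
    ladder$histogram <- integer(length(h))
  }
  ladder
}

#' Simulated-tempering run on a 1-D potential
#'
#' Driver exercising [st_attempt()] and [wl_update()] with exact
#' configurational sampling: at every attempt the position is drawn from the
#' Boltzmann distribution at the current rung temperature (removing
#' within-rung correlation as a confounder), the potential energy is
#' evaluated, a nearest-neighbour rung move is proposed with uniformly
#' chosen direction, and — when Wang-Landau adaptation is on — the weights
#' are updated after every attempt.
#'
#' @param potential A [potential_1d()].
#' @param ladder A [temperature_ladder()].
#' @param n_attempts Number of exchange attempts.
#' @param seed Integer seed.
#' @param wang_landau Adapt weights on the fly (default FALSE: fixed
#'   weights). Adaptation uses the flatness/halving schedule with the 1/t
#'   refinement: the increment is never allowed below n_rungs / t, so it
#'   decays like 1/t instead of freezing at an unconverged weight profile
#'   (the error-saturation pathology of plain flatness-halving).
#' @param wl_until_delta With `wang_landau = TRUE`, stop adapting once the
#'   increment has shrunk below this value (default 0: adapt throughout the
#'   whole run).
#' @return List with `rungs` (rung after each attempt), `rungs_sampled` and
#'   `positions` (the rung and position actually sampled at each attempt,
#'   before the exchange — the pairing to use for marginal-distribution
#'   checks), `ladder` (final state), `occupancy` (counts per rung) and
#'   `acceptance_rate`.
#' @export
run_simulated_tempering <- function(potential, ladder, n_attempts, seed,
                                    wang_landau = FALSE, wl_until_delta = 0) {
  stopifnot(inherits(potential, "potential_1d"),
            inherits(ladder, "temperature_ladder"))
  n <- length(ladder$temperatures)
  # exact per-rung samplers, one RNG sub-stream per rung
  seeds <- derive_seeds(seed, n + 1L)
  xs <- lapply(seq_len(n), function(r) {
    sample_boltzmann_1d(potential, temperature = ladder$temperatures[r],
                        n = n_attempts, seed = seeds[r])
  })
  rungs <- integer(n_attempts)
  rungs_sampled <- integer(n_attempts)
  positions <- numeric(n_attempts)
  accepted <- 0L
  with_seed(seeds[n + 1L], {
    u_dir <- stats::runif(n_attempts)
    u_acc <- stats::runif(n_attempts)
    r <- 1L
    for (t in seq_len(n_attempts)) {
      x <- xs[[r]][t]
      rungs_sampled[t] <- r
      positions[t] <- x
      U <- potential_energy(potential, x)
      j <- if (u_dir[t] < 0.5) r - 1L else r + 1L
      if (j >= 1L && j <= n) {
        r_new <- st_attempt(r, j, U, ladder, u_acc[t])
        if (r_new != r) accepted <- accepted + 1L
        r <- r_new
      }
      if (wang_landau && ladder$delta > wl_until_delta) {
        ladder <- wl_update(ladder, r)
        if (ladder$delta < n / t) ladder$delta <- n / t  # 1/t refinement
      }
      rungs[t] <- r
    }
  })
  list(rungs = rungs, rungs_sampled = rungs_sampled, positions = positions,
       ladder = ladder,
       occupancy = tabulate(rungs, nbins = n),
       acceptance_rate = accepted / n_attempts)
}

#' Exact tempering weights for a 1-D potential
#'
#' beta_i F_i computed by quadrature of the configurational partition
#' function at each rung temperature; with these weights rung occupancy is
#' exactly flat in the long run.
#'
#' @param potential A [potential_1d()].
#' @param ladder A [temperature_ladder()].
#' @return Numeric vector of weights (first entry 0).
#' @export
exact_tempering_weights <- function(potential, ladder) {
  f <- vapply(ladder$temperatures, function(temp) {
    beta_of(temp) * free_energy_quadrature(potential, temperature = temp)
  }, numeric(1))
  f - f[1]
}

#' Harmonic restraint on a collective variable
#'
#' E = k/2 (eta - eta0)^2 on a single collective coordinate (a PCA
#' projection or a plain 1-D coordinate). The gradient acts only along the
#' collective direction; all orthogonal degrees of freedom are untouched.
#'
#' @param center Restraint centre eta0, nm.
#' @param k Force constant, kJ/mol/nm^2, >= 0.
#' @param cv Optional [collective_vector()]; when supplied, coordinate-space
#'   energies/gradients can be evaluated via [cv_restraint_energy()].
#' @return Object of class `cv_restraint`.
#' @export
cv_restraint <- function(center, k = 1000, cv = NULL) {
  stopifnot(is.finite(center), k >= 0)
  if (!is.null(cv)) stopifnot(inherits(cv, "collective_vector"))
  structure(list(center = center, k = k, cv = cv), class = "cv_restraint")
}

#' @rdname cv_restraint
#' @param eta Collective coordinate value (nm), or — when the restraint
#'   carries a collective vector — a frame coordinate matrix from which eta
#'   is computed by projection.
#' @param restraint A `cv_restraint`.
#' @return List with `energy` (kJ/mol), `eta`, and `gradient`: d E / d eta
#'   when eta was given directly, or the full coordinate-space gradient
#'   k (eta - eta0) v (atoms x 3) when a frame was given.
#' @export
cv_restraint_energy <- function(eta, restraint) {
  stopifnot(inherits(restraint, "cv_restraint"))
  if (is.matrix(eta)) {
    if (is.null(restraint$cv)) {
      stop("coordinate input needs a restraint with a collective vector",
           call. = FALSE)
    }
    v <- restraint$cv$vector
    dx <- as.numeric(eta) - as.numeric(restraint$cv$mean_structure)
    eta_val <- sum(dx * v)
    grad <- matrix(restraint$k * (eta_val - restraint$center) * v, ncol = 3L)
  } else {
    eta_val <- eta
    grad <- restraint$k * (eta_val - restraint$center)
  }
  list(energy = 0.5 * restraint$k * (eta_val - restraint$center)^2,
       eta = eta_val, gradient = grad)
}
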