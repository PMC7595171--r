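#' Constant-velocity pull schedule
#'
#' Moving harmonic bias U_pull = k/2 (xi - ref(t))^2 whose reference
#' advances at constant velocity v from `ref_start` to `ref_end`.
#'
#' @param k Pull force constant, kJ/mol/nm^2, > 0.
#' @param velocity Reference velocity magnitude, nm/ps, > 0.
#' @param ref_start,ref_end Reference start/end positions, nm (must differ).
#' @param attempt_interval Tempering attempt interval, ps (multiple of dt in
#'   the driver).
#' @return Object of class `pull_schedule`.
#' @export
pull_schedule <- function(k, velocity, ref_start, ref_end,
                          attempt_interval = 1) {
  stopifnot(k > 0, velocity >= 0, attempt_interval > 0)
  if (ref_end == ref_start) stop("ref_end must differ from ref_start",
                                 call. = FALSE)
  structure(list(k = k, velocity = velocity, ref_start = ref_start,
                 ref_end = ref_end, attempt_interval = attempt_interval),
            class = "pull_schedule")
}

#' Simulated-tempering constant-velocity pulling
#'
#' Overdamped Langevin dynamics on a [potential_1d()] (plus optional static
#' restraints) under a moving harmonic bias whose reference advances at the
#' schedule velocity, coupled to a simulated-tempering temperature ladder:
#' every `attempt_interval` an adjacent-rung Metropolis exchange is
#' attempted ([st_attempt()]), optionally with Wang-Landau weight adaptation.
#' The external work is accumulated per reference increment with the
#' midpoint rule, dW = k (ref_mid - xi) dref (the discretised
#' dU_pull/dref * dref), which is second-order accurate and recovers the
#' reversible limit as v -> 0. Frames at the base (first-rung) temperature
#' are flagged for downstream umbrella-window seeding. The run is at
#' constant volume (recorded in the metadata; trivially true for a 1-D
#' model system).
#'
#' @param potential A [potential_1d()].
#' @param schedule A [pull_schedule()].
#' @param ladder A [temperature_ladder()] (single-rung ladders give plain
#'   pulling at one temperature).
#' @param restraints List of [harmonic_bias()] static restraint terms.
#' @param friction Friction gamma, kJ mol^-1 ps nm^-2.
#' @param dt Time step, ps.
#' @param seed Integer seed.
#' @param sample_every Record a trajectory row every this many steps.
#' @param wang_landau Adapt ladder weights during the run.
#' @param n_steps Number of integration steps; by default derived from the
#'   schedule (span / (velocity * dt)). Required when `velocity = 0`
#'   (stationary reference, zero work by construction).
#' @param x0 Initial position (default: the starting reference).
#' @return List with `trajectory` (data frame: time, position, rung,
#'   reference, work, base_temp flag), `work` (total external work, kJ/mol),
#'   `ladder` (final state) and `metadata`.
#' @export
run_tempered_pull <- function(potential, schedule, ladder,
                              restraints = list(), friction = 10, dt = 0.002,
                              seed = 1L, sample_every = 10L,
                              wang_landau = FALSE, n_steps = NULL, x0 = NULL) {
  stopifnot(inherits(potential, "potential_1d"),
            inherits(schedule, "pull_schedule"),
            inherits(ladder, "temperature_ladder"))
  span <- schedule$ref_end - schedule$ref_start
  if (is.null(n_steps)) {
    if (schedule$velocity == 0) {
      stop("n_steps must be given when the pull velocity is zero",
           call. = FALSE)
    }
    n_steps <- ceiling(abs(span) / (schedule$velocity * dt))
  }
  dref <- if (schedule$velocity == 0) 0 else span / n_steps
  attempt_every <- max(1L, round(schedule$attempt_interval / dt))

  dom <- sampling_domain(potential,
                         c(restraints,
                           list(harmonic_bias(schedule$k, schedule$ref_start),
                                harmonic_bias(schedule$k, schedule$ref_end))),
                         max(ladder$temperatures))
  kmax <- potential_max_curvature(potential, dom[1], dom[2]) + schedule$k +
    sum(vapply(restraints, function(b) b$k, numeric(1)))
  if (dt * kmax / friction >= 2) {
    stop(sprintf(
      "unstable integrator parameters: dt * Kmax / friction = %.3g >= 2",
      dt * kmax / friction), call. = FALSE)
  }

  if (is.null(x0)) x0 <- schedule$ref_start
  kb2dt <- 2 * KB_KJ_MOL_K * dt / friction
  n_rung <- length(ladder$temperatures)
  bound <- max(abs(dom)) * 10 + 10

  rec_idx <- unique(c(seq(1L, n_steps, by = sample_every), n_steps))
  nr <- length(rec_idx)
  rec_time <- numeric(nr); rec_pos <- numeric(nr); rec_rung <- integer(nr)
  rec_ref <- numeric(nr); rec_work <- numeric(nr)
  with_seed(seed, {
    noise <- stats::rnorm(n_steps)
    u_dir <- stats::runif(n_steps)
    u_acc <- stats::runif(n_steps)
    x <- x0
    r <- 1L
    refc <- schedule$ref_start
    W <- 0
    ri <- 1L
    for (t in seq_len(n_steps)) {
      # forces at current reference
      g <- potential_gradient(potential, x) + schedule$k * (x - refc)
      for (b in restraints) g <- g + b$k * (x - b$ref)
      temp <- ladder$temperatures[r]
      x <- x - g * dt / friction + sqrt(kb2dt * temp) * noise[t]
      if (!is.finite(x) || abs(x) > bound) {
        stop(sprintf("pulling trajectory diverged at step %d", t),
             call. = FALSE)
      }
      # advance reference; midpoint-rule work increment
      # dW = (dU_pull/dref) dref evaluated at the reference midpoint
      ref_new <- refc + dref
      W <- W + schedule$k * ((refc + ref_new) / 2 - x) * dref
      refc <- ref_new
      if (t %% attempt_every == 0L && n_rung > 1L) {
        U <- potential_energy(potential, x) +
          0.5 * schedule$k * (x - refc)^2
        for (b in restraints) U <- U + 0.5 * b$k * (x - b$ref)^2
        j <- if (u_dir[t] < 0.5) r - 1L else r + 1L
        if (j >= 1L && j <= n_rung) {
          r <- st_attempt(r, j, U, ladder, u_acc[t])
        }
        if (wang_landau) ladder <- wl_update(ladder, r)
      }
      if (ri <= nr && t == rec_idx[ri]) {
        rec_time[ri] <- t * dt
        rec_pos[ri] <- x
        rec_rung[ri] <- r
        rec_ref[ri] <- refc
        rec_work[ri] <- W
        ri <- ri + 1L
      }
    }
    list(trajectory = data.frame(time = rec_time, position = rec_pos,
                                 rung = rec_rung, reference = rec_ref,
                                 work = rec_work, base_temp = rec_rung == 1L),
         work = W, ladder = ladder,
         metadata = list(n_steps = n_steps, dt = dt, friction = friction,
                         seed = as.integer(seed), ensemble = "constant volume",
                         schedule = unclass(schedule)))
  })
}

#' Forward/reverse work sets from repeated pulls
#'
#' Runs `n_per_direction` forward pulls (schedule as given) and the same
#' number of reverse pulls (start/end swapped), each from an equilibrium
#' start drawn exactly at the first-rung temperature under the end-state
#' bias, and collects the external work values into a [work_set()] that the
#' Crooks/BAR estimators consume. The known free-energy difference between
#' the restrained end states, by quadrature, is stored as `true_dg`.
#'
#' @param potential A [potential_1d()].
#' @param schedule A [pull_schedule()].
#' @param ladder A [temperature_ladder()].
#' @param n_per_direction Pulls per direction.
#' @param seed Integer seed.
#' @param ... Passed to [run_tempered_pull()].
#' @return A [work_set()] with `true_dg` from [free_energy_quadrature()].
#' @export
pull_work_set <- function(potential, schedule, ladder, n_per_direction,
                          seed = 1L, ...) {
  rev_schedule <- pull_schedule(schedule$k, schedule$velocity,
                                schedule$ref_end, schedule$ref_start,
                                schedule$attempt_interval)
  temp0 <- ladder$temperatures[1]
  seeds <- derive_seeds(seed, 4L * n_per_direction)
  one <- function(sch, k) {
    x0 <- sample_boltzmann_1d(
      potential, bias = harmonic_bias(sch$k, sch$ref_start),
      temperature = temp0, n = 1L, seed = seeds[2L * k - 1L])
    run_tempered_pull(potential, sch, ladder, seed = seeds[2L * k],
                      x0 = x0, ...)$work
  }
  wf <- vapply(seq_len(n_per_direction), function(k) one(schedule, k),
               numeric(1))
  wr <- vapply(seq_len(n_per_direction), function(k) {
    one(rev_schedule, n_per_direction + k)
  }, numeric(1))
  true_dg <- free_energy_quadrature(
    potential, list(harmonic_bias(schedule$k, schedule$ref_end)), temp0) -
    free_energy_quadrature(
      potential, list(harmonic_bias(schedule$k, schedule$ref_start)), temp0)
  work_set(wf, wr, temperature = temp0, true_dg = true_dg)
}
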