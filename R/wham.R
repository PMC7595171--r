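#' Umbrella window sets
#'
#' Per-window records feeding WHAM: harmonic-bias reference position (nm),
#' force constant (kJ/mol/nm^2) and samples of the reaction coordinate (nm),
#' all at one shared temperature.
#'
#' @param references Numeric vector of window reference positions, nm.
#' @param force_constants Numeric vector (recycled if length 1), kJ/mol/nm^2.
#' @param samples List of numeric sample vectors, one per window, non-empty.
#' @param temperature Shared temperature, K.
#' @return Object of class `umbrella_window_set`.
#' @export
umbrella_window_set <- function(references, force_constants, samples,
                                temperature = 300) {
  n <- length(references)
  if (n < 1L) stop("need at least one window", call. = FALSE)
  if (length(force_constants) == 1L) force_constants <- rep(force_constants, n)
  stopifnot(length(force_constants) == n, is.list(samples),
            length(samples) == n)
  if (any(vapply(samples, length, 1L) == 0L)) {
    stop("every window must contain samples", call. = FALSE)
  }
  beta_of(temperature)
  structure(list(references = references, force_constants = force_constants,
                 samples = lapply(samples, as.numeric),
                 temperature = temperature),
            class = "umbrella_window_set")
}

#' @export
print.umbrella_window_set <- function(x, ...) {
  cat(sprintf(
    "umbrella_window_set: %d windows at %g K, refs %.3g..%.3g nm, %d samples total\n",
    length(x$references), x$temperature, min(x$references),
    max(x$references), sum(vapply(x$samples, length, 1L))))
  invisible(x)
}

#' Sample an umbrella window set from an analytic potential
#'
#' Convenience generator: exact Boltzmann samples (see
#' [sample_boltzmann_1d()]) in each harmonic window over a [potential_1d()],
#' so the WHAM estimate can be compared against the analytic profile.
#'
#' @param potential A [potential_1d()].
#' @param references Window reference positions, nm.
#' @param force_constant Umbrella force constant, kJ/mol/nm^2.
#' @param n_per_window Samples per window.
#' @param temperature Temperature, K.
#' @param seed Integer seed (one sub-seed per window).
#' @return An [umbrella_window_set()].
#' @export
sample_umbrella_windows <- function(potential, references, force_constant,
                                    n_per_window, temperature = 300, seed = 1L) {
  seeds <- derive_seeds(seed, length(references))
  samples <- lapply(seq_along(references), function(i) {
    sample_boltzmann_1d(potential,
                        bias = harmonic_bias(force_constant, references[i]),
                        temperature = temperature, n = n_per_window,
                        seed = seeds[i])
  })
  umbrella_window_set(references, force_constant, samples, temperature)
}

# Histogram window samples on shared bin edges. Returns counts matrix
# (windows x bins).
window_histograms <- function(windows, edges) {
  nb <- length(edges) - 1L
  t(vapply(windows$samples, function(s) {
    idx <- cut(s, breaks = edges, include.lowest = TRUE, labels = FALSE)
    tabulate(idx[!is.na(idx)], nbins = nb)
  }, numeric(nb)))
}

#' Free-energy profile by the weighted histogram analysis method
#'
#' Self-consistent iteration of the WHAM equations for harmonic umbrella
#' windows: with per-window bias w_i(xi) = k_i/2 (xi - ref_i)^2, window
#' sample counts n_ij on shared bins xi_j and window totals N_i,
#' \deqn{p_j = \frac{\sum_i n_{ij}}{\sum_i N_i \exp[\beta(F_i - w_i(\xi_j))]},
#'   \qquad F_i = -k_B T \ln \sum_j p_j e^{-\beta w_i(\xi_j)},}
#' iterated until max|dF_i| < `tolerance`. The profile is
#' G_j = -kB T ln p_j, shifted so min(G) = 0 ("min-zero" convention); empty
#' bins are dropped.
#'
#' @param windows An [umbrella_window_set()].
#' @param bins Number of uniform bins over the sampled range, or an explicit
#'   vector of bin edges (nm).
#' @param tolerance Convergence tolerance on max|dF_i|, kJ/mol.
#' @param max_iter Maximum number of iterations.
#' @param window_weights Optional non-negative per-window weights (used by
#'   the Bayesian bootstrap); default all 1.
#' @return Object of class `free_energy_profile`: data frame fields `center`
#'   (nm), `G` (kJ/mol), `error` (NA until bootstrapped), plus attributes
#'   `F_i` (window shifts), `iterations`, `offset_convention`, `edges`.
#' @export
wham_solve <- function(windows, bins = 200L, tolerance = 1e-4,
                       max_iter = 100000L, window_weights = NULL) {
  stopifnot(inherits(windows, "umbrella_window_set"))
  beta <- beta_of(windows$temperature)
  nw <- length(windows$references)
  if (length(bins) == 1L) {
    rng <- range(unlist(windows$samples))
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else {
    edges <- sort(bins)
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- window_histograms(windows, edges)      # nw x nb
  if (is.null(window_weights)) window_weights <- rep(1, nw)
  stopifnot(length(window_weights) == nw, all(window_weights >= 0))
  counts <- counts * window_weights
  Ni <- rowSums(counts)

  # pairwise overlap check on adjacent windows (by reference order): warn
  # when an adjacent pair shares no occupied bin, and error when there is a
  # genuine coverage gap (empty bins between the two windows' occupied
  # ranges, which disconnects the profile)
  ord <- order(windows$references)
  occ <- counts > 0
  for (k in seq_len(max(nw - 1L, 0L))) {
    a <- ord[k]; b <- ord[k + 1L]
    if (Ni[a] == 0 || Ni[b] == 0) next
    if (!any(occ[a, ] & occ[b, ])) {
      hi_a <- max(which(occ[a, ])); lo_b <- min(which(occ[b, ]))
      gap_bins <- if (lo_b > hi_a + 1L) (hi_a + 1L):(lo_b - 1L) else integer(0)
      if (length(gap_bins) > 0L && all(colSums(occ)[gap_bins] == 0)) {
        stop(sprintf(
          "windows at ref %.4g and %.4g nm do not overlap: no samples in [%.4g, %.4g] nm",
          windows$references[a], windows$references[b],
          edges[min(gap_bins)], edges[max(gap_bins) + 1L]), call. = FALSE)
      }
      warning(sprintf(
        "adjacent windows at ref %.4g and %.4g nm share no occupied bin",
        windows$references[a], windows$references[b]), call. = FALSE)
    }
  }

  bias <- outer(seq_len(nw), seq_along(centers), function(i, j) {
    0.5 * windows$force_constants[i] * (centers[j] - windows$references[i])^2
  })
  expnb <- exp(-beta * bias)                        # nw x nb
  num <- colSums(counts)
  Fi <- numeric(nw)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(Ni * exp(beta * Fi) * expnb)   # recycles by column
    p <- ifelse(denom > 0, num / denom, 0)
    z <- as.numeric(expnb %*% p)
    Fi_new <- -log(z) / beta
    Fi_new <- Fi_new - Fi_new[1]
    delta <- max(abs(Fi_new - Fi))
    Fi <- Fi_new
    if (delta < tolerance) break
    if (iter >= max_iter) {
      stop(sprintf("WHAM did not converge in %d iterations (last max|dF| = %.3g kJ/mol)",
                   max_iter, delta), call. = FALSE)
    }
  }
  keep <- num > 0 & p > 0
  G <- -log(p[keep]) / beta
  G <- G - min(G)
  structure(
    data.frame(center = centers[keep], G = G, error = NA_real_),
    F_i = Fi, iterations = iter, offset_convention = "min-zero",
    edges = edges, temperature = windows$temperature,
    class = c("free_energy_profile", "data.frame")
  )
}

#' Bayesian bootstrap of complete histograms
#'
#' Per-bin statistical errors of a WHAM profile, treating only complete
#' window histograms as independent: in each replicate every whole window is
#' assigned a random weight (i.i.d. exponential weights normalised over
#' windows, the Bayesian-bootstrap Dirichlet weighting), WHAM is re-solved
#' with the weighted histograms, replicate profiles are aligned to the
#' original by their mean over shared bins, and the per-bin error is the
#' standard deviation over replicates. Weights attach to windows, never to
#' individual samples.
#'
#' @param windows An [umbrella_window_set()] with >= 2 windows.
#' @param bins As in [wham_solve()].
#' @param n_boot Number of replicates, >= 20.
#' @param seed Integer seed.
#' @param tolerance,max_iter Passed to [wham_solve()].
#' @return The [wham_solve()] profile with its `error` column filled in.
#' @export
bayesian_bootstrap <- function(windows, bins = 200L, n_boot = 100L, seed = 1L,
                               tolerance = 1e-4, max_iter = 100000L) {
  stopifnot(inherits(windows, "umbrella_window_set"))
  nw <- length(windows$references)
  if (nw < 2L) {
    stop("Bayesian bootstrap needs >= 2 windows (no inter-window variability)",
         call. = FALSE)
  }
  if (n_boot < 20L) stop("n_boot must be >= 20", call. = FALSE)
  base <- wham_solve(windows, bins, tolerance, max_iter)
  edges <- attr(base, "edges")
  reps <- matrix(NA_real_, n_boot, nrow(base))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      w <- stats::rexp(nw)
      w <- w / sum(w) * nw
      prof <- suppressWarnings(
        wham_solve(windows, edges, tolerance, max_iter, window_weights = w))
      idx <- match(round(prof$center, 12), round(base$center, 12))
      g <- rep(NA_real_, nrow(base))
      g[idx[!is.na(idx)]] <- prof$G[!is.na(idx)]
      shared <- !is.na(g)
      g <- g - mean(g[shared] - base$G[shared])
      reps[b, ] <- g
    }
  })
  base$error <- apply(reps, 2, stats::sd, na.rm = TRUE)
  attr(base, "n_boot") <- n_boot
  base
}

#' Shift one profile onto another
#'
#' Adds the constant that minimises the mean offset between two profiles
#' over a shared bin region (the least-squares additive alignment); shapes
#' are untouched.
#'
#' @param a,b [wham_solve()] profiles (`b` is shifted onto `a`).
#' @param region Optional length-2 numeric range of bin centers to align on;
#'   default: all shared bins.
#' @return `b` with `G` shifted; attribute `shift` records the constant.
#' @export
align_profiles <- function(a, b, region = NULL) {
  shared_a <- a$center %in% b$center
  if (!is.null(region)) {
    shared_a <- shared_a & a$center >= region[1] & a$center <= region[2]
  }
  centers <- a$center[shared_a]
  if (length(centers) == 0L) {
    stop("profiles share no bins in the alignment region", call. = FALSE)
  }
  shift <- mean(a$G[match(centers, a$center)] - b$G[match(centers, b$center)])
  b$G <- b$G + shift
  attr(b, "shift") <- shift
  attr(b, "offset_convention") <- "aligned"
  b
}
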