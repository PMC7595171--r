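#' Free-energy difference container
#'
#' @param value Estimate, kJ/mol.
#' @param error Standard error, kJ/mol, >= 0 (NA until bootstrapped).
#' @param method `"bar"` or `"crossing"`.
#' @param n_forward,n_reverse Sample counts behind the estimate.
#' @param temperature Temperature, K.
#' @return Object of class `delta_g`.
#' @export
delta_g <- function(value, error = NA_real_, method = c("bar", "crossing"),
                    n_forward, n_reverse, temperature = 300) {
  method <- match.arg(method)
  if (!is.na(error) && error < 0) stop("error must be >= 0", call. = FALSE)
  structure(list(value = value, error = error, method = method,
                 n_forward = n_forward, n_reverse = n_reverse,
                 temperature = temperature),
            class = "delta_g")
}

#' @export
print.delta_g <- function(x, ...) {
  cat(sprintf("dG = %.4g %s kJ/mol  [%s; %d fwd / %d rev at %g K]\n",
              x$value,
              if (is.na(x$error)) "" else sprintf("+/- %.3g", x$error),
              x$method, x$n_forward, x$n_reverse, x$temperature))
  invisible(x)
}

#' Bennett acceptance-ratio (BAR) free-energy estimate
#'
#' Maximum-likelihood estimate of dG under the Crooks fluctuation relation.
#' With M = kB T ln(n_F / n_R) and f the logistic function
#' f(x) = 1 / (1 + e^x), dG solves
#' \deqn{\sum_{i \in F} f(\beta(W_i - \Delta G + M)) =
#'       \sum_{j \in R} f(\beta(W_j + \Delta G - M)),}
#' found by bracketed root-finding over
#' [min(-W_R), max(W_F)] expanded by 10 kB T.
#'
#' @param work A [work_set()].
#' @param tolerance Root-finding tolerance, kJ/mol.
#' @return A [delta_g()] with method `"bar"` (error NA; see
#'   [work_bootstrap()]).
#' @export
bar_solve <- function(work, tolerance = 1e-6) {
  stopifnot(inherits(work, "work_set"))
  beta <- beta_of(work$temperature)
  kt <- 1 / beta
  wf <- work$forward_work
  wr <- work$reverse_work
  nf <- length(wf); nr <- length(wr)
  # overlap guard: forward work and negated reverse work must not be
  # separated by an enormous gap, otherwise the estimator is numerically
  # meaningless
  gap <- max(min(wf), min(-wr)) - min(max(wf), max(-wr))
  if (gap > 50 * kt) {
    stop(sprintf(
      "forward and reversed-reverse work distributions are separated by %.3g kBT; more sampling is needed",
      gap * beta), call. = FALSE)
  }
  M <- kt * log(nf / nr)
  logistic <- function(x) 1 / (1 + exp(x))
  g <- function(dg) {
    sum(logistic(beta * (wf - dg + M))) - sum(logistic(beta * (wr + dg - M)))
  }
  lo <- min(-wr) - 10 * kt
  hi <- max(wf) + 10 * kt
  # g is increasing in dg; widen the bracket if needed
  while (g(lo) > 0) lo <- lo - 10 * kt
  while (g(hi) < 0) hi <- hi + 10 * kt
  root <- stats::uniroot(g, c(lo, hi), tol = tolerance)
  delta_g(root$root, method = "bar", n_forward = nf, n_reverse = nr,
          temperature = work$temperature)
}

#' Crossing-point free-energy estimate
#'
#' Diagnostic estimator from the Crooks relation: the forward work density
#' P_F(W) and the negated-reverse density P_R(-W) cross exactly at W = dG.
#' Gaussian kernel-density estimates (Silverman bandwidth) of the two
#' densities are evaluated on a shared grid inside their overlap region and
#' the abscissa of the crossing is returned; with several sign changes, the
#' crossing with the highest combined density is taken.
#'
#' @param work A [work_set()].
#' @param n_grid Evaluation grid size inside the overlap region.
#' @return A [delta_g()] with method `"crossing"`.
#' @export
crossing_estimate <- function(work, n_grid = 2048L) {
  stopifnot(inherits(work, "work_set"))
  wf <- work$forward_work
  wnr <- -work$reverse_work
  lo <- max(min(wf), min(wnr))
  hi <- min(max(wf), max(wnr))
  if (!(hi > lo)) {
    stop("forward and negated-reverse work histograms do not overlap",
         call. = FALSE)
  }
  grid <- seq(lo, hi, length.out = n_grid)
  df <- stats::density(wf, bw = "nrd0", n = n_grid, from = lo, to = hi)$y
  dr <- stats::density(wnr, bw = "nrd0", n = n_grid, from = lo, to = hi)$y
  diff_ <- df - dr
  sgn <- sign(diff_)
  chg <- which(sgn[-1] * sgn[-n_grid] < 0 | diff_[-n_grid] == 0)
  if (length(chg) == 0L) {
    stop("work densities do not intersect within the overlap region",
         call. = FALSE)
  }
  # linear interpolation of the zero; prefer the best-supported crossing
  xs <- vapply(chg, function(i) {
    d1 <- diff_[i]; d2 <- diff_[i + 1L]
    if (d1 == d2) grid[i] else grid[i] + (grid[i + 1L] - grid[i]) * d1 / (d1 - d2)
  }, numeric(1))
  support <- (df + dr)[chg]
  dg <- xs[which.max(support)]
  delta_g(dg, method = "crossing", n_forward = length(wf),
          n_reverse = length(work$reverse_work),
          temperature = work$temperature)
}

#' Bootstrap error of a work-based free-energy estimate
#'
#' Resamples the forward and reverse work sets independently with
#' replacement, re-estimates dG on each replicate, and reports the standard
#' deviation of the replicate estimates.
#'
#' @param work A [work_set()].
#' @param estimator Function `work_set -> delta_g` (default [bar_solve()]).
#' @param n_boot Number of replicates, >= 50.
#' @param seed Integer seed.
#' @return A [delta_g()]: the estimator's value on the full set with `error`
#'   set to the bootstrap standard deviation.
#' @export
work_bootstrap <- function(work, estimator = bar_solve, n_boot = 200L,
                           seed = 1L) {
  stopifnot(inherits(work, "work_set"))
  if (n_boot < 50L) stop("n_boot must be >= 50", call. = FALSE)
  point <- estimator(work)
  nf <- length(work$forward_work)
  nr <- length(work$reverse_work)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ws <- work_set(
        sample(work$forward_work, nf, replace = TRUE),
        sample(work$reverse_work, nr, replace = TRUE),
        temperature = work$temperature)
      tryCatch(estimator(ws)$value, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.2 * n_boot) {
    stop(sprintf("estimator failed on %d of %d bootstrap replicates",
                 n_fail, n_boot), call. = FALSE)
  }
  point$error <- stats::sd(vals, na.rm = TRUE)
  point
}

#' Thermodynamic-cycle ddG composition
#'
#' Composes two alchemical legs into a double free-energy difference
#' ddG = dG(bound) - dG(unbound) with the errors added in quadrature.
#' Contexts:
#' * `"binding-affinity"`: legs are the mutation free energy with and
#'   without a bound ligand; ddG is the change in ligand binding affinity
#'   caused by the mutation.
#' * `"alpha-vs-beta-preference"`: same arithmetic with the documented sign
#'   convention that positive ddG means an augmented preference for the
#'   alpha (activating) state, negative for the beta state.
#'
#' @param leg_bound,leg_unbound [delta_g()] legs at the same temperature.
#' @param context `"binding-affinity"` or `"alpha-vs-beta-preference"`.
#' @return Object of class `thermodynamic_cycle`: list with the two legs,
#'   `ddg`, `error`, `context`, and `interpretation` (text rendering of the
#'   sign convention).
#' @export
cycle_ddg <- function(leg_bound, leg_unbound,
                      context = c("binding-affinity",
                                  "alpha-vs-beta-preference")) {
  context <- match.arg(context)
  stopifnot(inherits(leg_bound, "delta_g"), inherits(leg_unbound, "delta_g"))
  if (leg_bound$temperature != leg_unbound$temperature) {
    stop("cycle legs must be estimated at the same temperature", call. = FALSE)
  }
  ddg <- leg_bound$value - leg_unbound$value
  err <- sqrt(
    (if (is.na(leg_bound$error)) 0 else leg_bound$error^2) +
      (if (is.na(leg_unbound$error)) 0 else leg_unbound$error^2))
  interpretation <- if (context == "alpha-vs-beta-preference") {
    if (ddg > 0) "augmented preference for the alpha state"
    else if (ddg < 0) "augmented preference for the beta state"
    else "no change in alpha/beta preference"
  } else {
    if (ddg > 0) "reduced binding affinity upon mutation"
    else if (ddg < 0) "increased binding affinity upon mutation"
    else "unchanged binding affinity"
  }
  structure(list(leg_bound = leg_bound, leg_unbound = leg_unbound,
                 ddg = ddg, error = err, context = context,
                 interpretation = interpretation),
            class = "thermodynamic_cycle")
}

#' @export
print.thermodynamic_cycle <- function(x, ...) {
  cat(sprintf("ddG = %.4g +/- %.4g kJ/mol [%s]: %s\n",
              x$ddg, x$error, x$context, x$interpretation))
  invisible(x)
}
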