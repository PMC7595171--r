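#' Forward/reverse nonequilibrium work sets
#'
#' Container for nonequilibrium work values from forward (lambda 0 -> 1) and
#' reverse (lambda 1 -> 0) transformations at one temperature, the input of
#' the Crooks/Bennett free-energy estimators. Sign convention: work is the
#' work done on the system along the stated direction, in kJ/mol.
#'
#' @param forward_work,reverse_work Numeric vectors of work values, kJ/mol.
#' @param temperature Temperature, K.
#' @param true_dg Optional known free-energy difference (synthetic sets).
#' @return An object of class `work_set`.
#' @export
work_set <- function(forward_work, reverse_work, temperature = 300,
                     true_dg = NULL) {
  stopifnot(is.numeric(forward_work), is.numeric(reverse_work))
  if (length(forward_work) == 0 || length(reverse_work) == 0) {
    stop("both work directions must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(forward_work)) || any(!is.finite(reverse_work))) {
    stop("work values must be finite", call. = FALSE)
  }
  beta_of(temperature) # validates > 0
  structure(
    list(forward_work = as.numeric(forward_work),
         reverse_work = as.numeric(reverse_work),
         temperature = temperature, true_dg = true_dg),
    class = "work_set"
  )
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf(
    "work_set: %d forward / %d reverse values at %g K%s\n",
    length(x$forward_work), length(x$reverse_work), x$temperature,
    if (is.null(x$true_dg)) "" else sprintf(" (true dG = %g kJ/mol)", x$true_dg)
  ))
  invisible(x)
}

#' Crooks-consistent Gaussian work pairs
#'
#' Generates synthetic forward/reverse work samples
#' \deqn{W_F \sim N(\Delta G + \beta\sigma^2/2,\ \sigma^2), \quad
#'       W_R \sim N(-\Delta G + \beta\sigma^2/2,\ \sigma^2),}
#' a pair that satisfies the Crooks fluctuation relation
#' P_F(W) / P_R(-W) = exp[beta (W - dG)] exactly for every W. This is the
#' stand-in for spawning a fixed number of fast nonequilibrium transitions in
#' each direction from equilibrium end states.
#'
#' @param true_dg Known free-energy difference, kJ/mol.
#' @param sigma Work standard deviation, kJ/mol, > 0.
#' @param temperature Temperature, K.
#' @param n_per_direction Number of work values in each direction, >= 2.
#' @param seed Integer seed.
#' @return A [work_set()] with `true_dg` stored.
#' @export
gaussian_work_pairs <- function(true_dg, sigma, temperature = 300,
                                n_per_direction, seed) {
  stopifnot(is.finite(true_dg), sigma > 0)
  if (n_per_direction < 2) {
    stop("n_per_direction must be >= 2 (estimator undefined otherwise)",
         call. = FALSE)
  }
  beta <- beta_of(temperature)
  shift <- beta * sigma^2 / 2
  with_seed(seed, {
    wf <- stats::rnorm(n_per_direction, mean = true_dg + shift, sd = sigma)
    wr <- stats::rnorm(n_per_direction, mean = -true_dg + shift, sd = sigma)
    work_set(wf, wr, temperature = temperature, true_dg = true_dg)
  })
}
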