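#' Per-frame order parameters of the alpha/beta equilibrium
#'
#' Computes the three inter-site distances characterising the two
#' conformational states, per frame, in Angstrom:
#' pY = |Lys35 CA - Thr42 CA| (pY-loop opening),
#' sheet = |Gly39 C - Asn58 N| (central beta-sheet spread),
#' plus5 = |Tyr66 CA - Leu88 CA| (+5 site opening).
#'
#' @param ensemble A [structure_ensemble()] containing the six anchor atoms.
#' @return Data frame with columns `frame`, `pY`, `sheet`, `plus5` (Angstrom).
#' @export
order_parameters <- function(ensemble) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atoms
  anchor_index <- function(resno, atom) {
    i <- which(at$resno == resno & at$atom == atom)
    if (length(i) != 1L) {
      stop(sprintf("anchor atom %s of residue %d is missing", atom, resno),
           call. = FALSE)
    }
    i
  }
  pair_dist <- function(r1, a1, r2, a2) {
    i <- anchor_index(r1, a1); j <- anchor_index(r2, a2)
    d <- ensemble$coords[, i, , drop = FALSE] -
      ensemble$coords[, j, , drop = FALSE]
    nm_to_angstrom(sqrt(rowSums(matrix(d, nrow = dim(d)[1])^2)))
  }
  data.frame(
    frame = seq_len(n_frames(ensemble)),
    pY = pair_dist(35L, "CA", 42L, "CA"),
    sheet = pair_dist(39L, "C", 58L, "N"),
    plus5 = pair_dist(66L, "CA", 88L, "CA")
  )
}

#' Pearson product-moment correlation
#'
#' Standard Pearson R between two equal-length series, as used for the
#' inter-site coupling analysis (e.g. beta-sheet spread vs pY-loop opening).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in input series", call. = FALSE)
  }
  stats::cor(x, y)
}

# Wilson score confidence interval for a binomial fraction.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Classify frames into alpha / beta / mixed states
#'
#' Default mode classifies on the order parameters: a frame is `alpha` iff
#' the pY loop is closed AND the +5 site is closed (both distances below
#' their thresholds), `beta` iff both are open, and `mixed` otherwise (the
#' two off-diagonal quadrants: e.g. a closed pY loop with an open +5 site,
#' typical of the isolated domain in a crystal environment). Thresholds
#' default to the midpoints of the alpha/beta reference values: pY 10 A,
#' +5 site 9.5 A (the sheet threshold, 8 A, is carried for provenance and
#' for projection-mode classification).
#'
#' @param ops Data frame from [order_parameters()] (columns `pY`, `plus5`).
#' @param thresholds Named vector with entries `pY` and `plus5` (Angstrom).
#' @return Object of class `state_labels`: list with `labels` (character per
#'   frame), `thresholds`, `fractions` (named vector over alpha/beta/mixed),
#'   `ci` (Wilson 95% intervals, one row per state) and `log`.
#' @export
classify_states <- function(ops, thresholds = c(pY = 10, sheet = 8,
                                                plus5 = 9.5)) {
  stopifnot(all(c("pY", "plus5") %in% names(ops)),
            all(c("pY", "plus5") %in% names(thresholds)))
  log <- character(0)
  for (p in c("pY", "plus5")) {
    if (thresholds[[p]] < min(ops[[p]]) || thresholds[[p]] > max(ops[[p]])) {
      log <- c(log, sprintf(
        "threshold %s = %g A lies outside the data range [%.2f, %.2f]",
        p, thresholds[[p]], min(ops[[p]]), max(ops[[p]])))
    }
  }
  py_closed <- ops$pY < thresholds[["pY"]]
  p5_closed <- ops$plus5 < thresholds[["plus5"]]
  labels <- ifelse(py_closed & p5_closed, "alpha",
                   ifelse(!py_closed & !p5_closed, "beta", "mixed"))
  state_labels(labels, thresholds, log)
}

#' @rdname classify_states
#' @param eta_py,eta_plus5 Projections of the frames onto the pY-loop and
#'   +5-site subvectors (nm).
#' @param eta_thresholds Named vector `c(pY = ..., plus5 = ...)` separating
#'   the two states along each subvector; typically midpoints of the
#'   projected reference geometries. Projections use the package sign
#'   convention (+eta toward alpha), so alpha lies above threshold.
#' @export
classify_states_projection <- function(eta_py, eta_plus5, eta_thresholds) {
  stopifnot(length(eta_py) == length(eta_plus5),
            all(c("pY", "plus5") %in% names(eta_thresholds)))
  alpha_side_py <- eta_py > eta_thresholds[["pY"]]
  alpha_side_p5 <- eta_plus5 > eta_thresholds[["plus5"]]
  labels <- ifelse(alpha_side_py & alpha_side_p5, "alpha",
                   ifelse(!alpha_side_py & !alpha_side_p5, "beta", "mixed"))
  state_labels(labels, eta_thresholds, character(0))
}

state_labels <- function(labels, thresholds, log) {
  n <- length(labels)
  states <- c("alpha", "beta", "mixed")
  counts <- vapply(states, function(s) sum(labels == s), numeric(1))
  ci <- t(vapply(states, function(s) wilson_ci(sum(labels == s), n),
                 numeric(2)))
  structure(list(labels = labels, thresholds = thresholds,
                 fractions = counts / n, ci = ci, log = log),
            class = "state_labels")
}

#' @export
print.state_labels <- function(x, ...) {
  cat(sprintf("state_labels over %d frames:\n", length(x$labels)))
  for (s in names(x$fractions)) {
    cat(sprintf("  %-5s %.3f  (95%% CI %.3f-%.3f)\n", s, x$fractions[[s]],
                x$ci[s, "lower"], x$ci[s, "upper"]))
  }
  if (length(x$log)) cat(" log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}
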