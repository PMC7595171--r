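#' Pairwise RMSD matrix of an ensemble
#'
#' Entry (i, j) is the RMSD of frame j fitted onto frame i by the optimal
#' least-squares superposition on the selection, in Angstrom. The matrix is
#' symmetric with a zero diagonal; because every pair is fitted
#' independently, the triangle inequality holds only up to the numerical
#' tolerance of the pairwise fits.
#'
#' @param ensemble A [structure_ensemble()] with >= 2 frames.
#' @param selection A [selection_spec()].
#' @return Symmetric `n x n` matrix of class `rmsd_matrix`, Angstrom.
#' @export
rmsd_matrix <- function(ensemble, selection = nsh2_selection("analysis")) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  nf <- n_frames(ensemble)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  idx <- resolve_selection(ensemble, selection)
  if (length(idx) < 3L) stop("degenerate selection", call. = FALSE)
  sel <- lapply(seq_len(nf), function(i) {
    frame_coords(ensemble, i)[idx, , drop = FALSE]
  })
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- pair_rmsd(sel[[j]], sel[[i]])
    }
  }
  structure(m, class = c("rmsd_matrix", "matrix"))
}

#' GROMOS conformational clustering
#'
#' Greedy neighbour-count clustering on a pairwise RMSD matrix: repeatedly
#' take the frame with the most neighbours within `cutoff` (ties broken by
#' lowest frame index), form a cluster of that frame plus its neighbours,
#' remove them from the pool, and continue until no frames remain. Cluster
#' centres are the neighbour-richest frames, and clusters are emitted in the
#' order of extraction, i.e. decreasing size at extraction time.
#'
#' @param matrix An [rmsd_matrix()] (any symmetric non-negative matrix with
#'   zero diagonal works).
#' @param cutoff Neighbour cutoff, Angstrom, > 0.
#' @return Object of class `gromos_clustering`: list with `clusters` (list of
#'   lists, each with `center` and `members`, original frame indices),
#'   `cutoff`, and `assignment` (per-frame cluster id).
#' @export
gromos_cluster <- function(matrix, cutoff) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  n <- nrow(matrix)
  remaining <- seq_len(n)
  clusters <- list()
  assignment <- integer(n)
  while (length(remaining) > 0L) {
    sub <- matrix[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)   # includes self
    center_pos <- which.max(counts)    # which.max: lowest index on ties
    members_pos <- which(sub[center_pos, ] <= cutoff)
    members <- remaining[members_pos]
    clusters[[length(clusters) + 1L]] <- list(
      center = remaining[center_pos], members = members)
    assignment[members] <- length(clusters)
    remaining <- remaining[-members_pos]
  }
  structure(list(clusters = clusters, cutoff = cutoff,
                 assignment = assignment),
            class = "gromos_clustering")
}

#' @export
print.gromos_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), numeric(1))
  cat(sprintf("gromos_clustering: %d clusters at cutoff %.2f A; sizes %s\n",
              length(sizes), x$cutoff, paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Clustering cutoff from the RMSD distribution
#'
#' Histograms the off-diagonal pairwise RMSD values (Freedman-Diaconis bin
#' width), smooths the counts with a 3-bin moving average, and returns the
#' abscissa of the first local maximum — the "first relative maximum" rule
#' for choosing a GROMOS cutoff. Bins with fewer than 5% of the maximum
#' smoothed count are not eligible as maxima, so isolated tail-noise bumps
#' of a few counts cannot masquerade as the first mode. If the smoothed
#' histogram has no interior maximum (monotone distribution) the median of
#' the values is returned with a logged warning.
#'
#' @param matrix An [rmsd_matrix()] with >= 10 off-diagonal values.
#' @return Cutoff in Angstrom, with attribute `log`.
#' @export
choose_cutoff <- function(matrix) {
  stopifnot(is.matrix(matrix))
  vals <- matrix[upper.tri(matrix)]
  if (length(vals) < 10L) {
    stop("need at least 10 pairwise RMSD values", call. = FALSE)
  }
  iqr <- stats::IQR(vals)
  bw <- if (iqr > 0) 2 * iqr / length(vals)^(1 / 3) else diff(range(vals)) / 10
  if (bw <= 0) bw <- max(max(vals), 1) / 10
  breaks <- seq(min(vals) - bw / 2, max(vals) + bw, by = bw)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  counts <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  counts[is.na(counts)] <- h$counts[is.na(counts)]
  # first interior bin strictly above both neighbours (plateaus: first bin of
  # the plateau whose right neighbour is lower)
  nb <- length(counts)
  floor_ <- 0.05 * max(counts)
  log <- character(0)
  cutoff <- NA_real_
  for (k in seq_len(nb)) {
    if (counts[k] < floor_) next
    left <- if (k == 1L) -Inf else counts[k - 1L]
    right_idx <- k
    while (right_idx < nb && counts[right_idx + 1L] == counts[k]) {
      right_idx <- right_idx + 1L
    }
    right <- if (right_idx == nb) -Inf else counts[right_idx + 1L]
    if (counts[k] > left && counts[k] > right) {
      cutoff <- h$mids[k]
      break
    }
  }
  if (!is.finite(cutoff)) {
    cutoff <- stats::median(vals)
    log <- "no interior maximum in the RMSD histogram; falling back to the median"
  }
  attr(cutoff, "log") <- log
  cutoff
}

#' Umbrella-window seed frames from a pulling trace
#'
#' Partitions a pulling trajectory into `n_windows` equal reaction-coordinate
#' intervals over `window_range`, and within each interval picks the most
#' representative conformation: the centre of the largest GROMOS cluster of
#' the member frames, at a cutoff chosen per interval by [choose_cutoff()].
#' Intervals with one or two frames (too few pairwise values for a cutoff)
#' seed with their first frame.
#'
#' @param pull_trace Data frame with columns `value` (reaction coordinate)
#'   and `frame` (frame index into `ensemble`).
#' @param ensemble [structure_ensemble()] holding the trace frames.
#' @param n_windows Number of umbrella windows.
#' @param window_range Length-2 numeric `c(lo, hi)` spanned by the trace.
#' @param selection Selection for the per-interval RMSD matrices.
#' @return Data frame with one row per window: `window`, `lo`, `hi`,
#'   `seed_frame`, `cutoff` (NA when clustering was skipped).
#' @export
seed_windows <- function(pull_trace, ensemble, n_windows, window_range,
                         selection = nsh2_selection("analysis")) {
  stopifnot(all(c("value", "frame") %in% names(pull_trace)), n_windows >= 1)
  lo <- window_range[1]; hi <- window_range[2]
  stopifnot(hi > lo)
  if (min(pull_trace$value) > lo || max(pull_trace$value) < hi) {
    stop("pulling trace does not span the window range", call. = FALSE)
  }
  edges <- seq(lo, hi, length.out = n_windows + 1L)
  out <- data.frame(window = seq_len(n_windows), lo = edges[-(n_windows + 1L)],
                    hi = edges[-1L], seed_frame = NA_integer_,
                    cutoff = NA_real_)
  for (w in seq_len(n_windows)) {
    inside <- pull_trace$value >= out$lo[w] &
      (pull_trace$value < out$hi[w] | (w == n_windows &
                                         pull_trace$value <= out$hi[w]))
    frames <- pull_trace$frame[inside]
    if (length(frames) == 0L) {
      stop(sprintf("umbrella interval %d [%.4g, %.4g] contains no frames",
                   w, out$lo[w], out$hi[w]), call. = FALSE)
    }
    if (length(frames) <= 2L) {
      out$seed_frame[w] <- frames[1L]
      next
    }
    sub <- structure_ensemble(
      ensemble$coords[frames, , , drop = FALSE], ensemble$atoms,
      provenance = sprintf("window %d members", w))
    m <- rmsd_matrix(sub, selection)
    cutoff <- tryCatch(as.numeric(choose_cutoff(m)),
                       error = function(e) stats::median(m[upper.tri(m)]))
    cl <- gromos_cluster(m, max(cutoff, 1e-6))
    sizes <- vapply(cl$clusters, function(x) length(x$members), numeric(1))
    out$seed_frame[w] <- frames[cl$clusters[[which.max(sizes)]]$center]
    out$cutoff[w] <- cutoff
  }
  out
}
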