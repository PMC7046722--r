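#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two coordinate sets, via SVD of the weighted
#' cross-covariance with determinant sign correction, so reflections are
#' never returned.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param reference n x 3 coordinate matrix.
#' @param weights per-atom nonnegative weights; uniform by default.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length-3; apply as \code{mobile \%*\% rotation + translation}), and
#'   \code{rmsd} (Angstrom, the weighted least-squares minimum).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  stopifnot(nrow(reference) == n, ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be nonnegative")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  if (sum(H^2) < 1e-24) {
    warning("degenerate superposition (coincident points); identity rotation")
    R <- diag(3)
  } else {
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  }
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

# apply a kabsch fit of frame[sel,] onto ref_sel to ALL atoms of frame
.apply_fit <- function(frame, sel_idx, ref_sel, weights = NULL) {
  fit <- kabsch_superpose(frame[sel_idx, , drop = FALSE], ref_sel, weights)
  sweep(frame %*% fit$rotation, 2, fit$translation, "+")
}

#' Superpose every frame of a trajectory onto the iterative mean structure
#'
#' Two-pass procedure: frames are first fitted (on the analysis selection)
#' onto the first frame, the mean of the fitted selection is taken as the new
#' reference, and all frames are re-fitted onto that mean. Two passes are
#' enough for the mean to stabilise on the ensembles this package targets.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param selection atoms used for the fit (\code{AtomSelection}, expression
#'   string, or \code{NULL} for all atoms).
#' @param n_pass number of mean-refit passes (>= 1).
#' @return list with \code{traj} (superposed \code{Trajectory}) and
#'   \code{mean} (the n_sel x 3 mean coordinates of the selection).
#' @export
superpose_trajectory <- function(traj, selection = NULL, n_pass = 2L) {
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  nf <- n_frames(traj)
  coords <- traj$coords
  ref <- matrix(coords[1, idx, ], ncol = 3)
  for (pass in seq_len(n_pass)) {
    for (t in seq_len(nf)) {
      coords[t, , ] <- .apply_fit(matrix(coords[t, , ], ncol = 3), idx, ref)
    }
    mean_sel <- apply(coords[, idx, , drop = FALSE], c(2, 3), mean)
    ref <- mean_sel
  }
  list(traj = Trajectory(traj$topology, coords, traj$times), mean = ref)
}
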