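#' Deterministic unit-sphere point set (Fibonacci spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors. Deterministic, so SASA values are
#'   bit-reproducible across runs.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)   # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere of radius (vdW + probe) is sampled with a deterministic
#' Fibonacci point set; a point is accessible iff it lies outside every
#' neighbouring atom's expanded sphere. Per-atom area is the accessible
#' fraction of 4*pi*(r_i + probe)^2; residue and total areas are sums.
#'
#' @param structure a \code{\link{Structure}} supplying radii and metadata.
#' @param frame coordinates to evaluate (default \code{structure$xyz}).
#' @param probe_radius probe sphere radius, Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom (>= 60; default 960).
#' @param selection atoms to include (default all heavy atoms; hydrogens are
#'   skipped unless explicitly selected).
#' @return list with \code{per_atom} (Angstrom^2 per selected atom),
#'   \code{per_residue} (a \code{\link{ProfileResult}}), and \code{total}.
#' @export
sasa <- function(structure, frame = NULL, probe_radius = 1.4,
                 n_points = 960L, selection = NULL) {
  if (n_points < 60L) stop("n_points must be >= 60")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (is.null(frame)) frame <- structure$xyz
  frame <- as.matrix(frame)
  if (is.null(selection)) {
    idx <- which(structure$atoms$element != "H")
    if (length(idx) == 0L) idx <- seq_len(n_atoms(structure))
  } else {
    idx <- .resolve_selection(structure, selection)$indices
  }
  xyz <- frame[idx, , drop = FALSE]
  rad <- structure$atoms$vdw_radius[idx] + probe_radius
  n <- length(idx)
  pts <- fibonacci_sphere(n_points)

  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    # neighbours whose expanded sphere can occlude points on sphere i
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb) > 0L) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dd <- sweep(sp, 2, xyz[j, ])
        acc <- acc & (rowSums(dd^2) > rad[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * frac
  }

  res <- .sel_residues(structure, idx)
  per_res <- tapply(per_atom, res$group, sum)
  list(
    per_atom = per_atom,
    per_residue = ProfileResult(as.numeric(per_res), res$author_resid,
                                "sasa", "A^2", labels = res$labels),
    total = sum(per_atom)
  )
}

#' Per-frame total SASA over a trajectory
#'
#' @inheritParams sasa
#' @param traj a \code{\link{Trajectory}}.
#' @return a \code{\link{SeriesResult}} in Angstrom^2.
#' @export
sasa_series <- function(traj, probe_radius = 1.4, n_points = 960L,
                        selection = NULL) {
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    sasa(traj$topology, get_frame(traj, t), probe_radius, n_points,
         selection)$total
  }, numeric(1))
  SeriesResult(vals, "sasa_total", "A^2",
               if (is.null(selection)) "heavy" else "custom")
}
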