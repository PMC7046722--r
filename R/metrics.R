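#' Per-frame scalar series
#' @param values numeric per-frame values (>= 0).
#' @param metric metric label (e.g. "rmsd").
#' @param unit unit string ("A", "A^2", "nm").
#' @param selection_label label of the selection the metric was computed on.
#' @return object of class \code{"SeriesResult"}.
#' @export
SeriesResult <- function(values, metric, unit, selection_label = "") {
  structure(list(values = as.numeric(values), metric = metric, unit = unit,
                 selection_label = selection_label),
            class = "SeriesResult")
}

#' @export
print.SeriesResult <- function(x, ...) {
  cat(sprintf("SeriesResult '%s' [%s], %d frames, mean %.4f\n",
              x$metric, x$unit, length(x$values), mean(x$values)))
  invisible(x)
}

#' Per-residue scalar profile
#' @param values numeric per-residue values.
#' @param author_resid author residue numbers keying \code{values}.
#' @param metric metric label.
#' @param unit unit string.
#' @param labels optional display labels (CHAIN:RESNAME:NUM).
#' @return object of class \code{"ProfileResult"}.
#' @export
ProfileResult <- function(values, author_resid, metric, unit, labels = NULL) {
  stopifnot(length(values) == length(author_resid))
  structure(list(values = as.numeric(values),
                 author_resid = as.integer(author_resid),
                 metric = metric, unit = unit, labels = labels),
            class = "ProfileResult")
}

#' @export
print.ProfileResult <- function(x, ...) {
  cat(sprintf("ProfileResult '%s' [%s], %d residues\n",
              x$metric, x$unit, length(x$values)))
  invisible(x)
}

# map atom selection -> residue grouping of selected atoms
.sel_residues <- function(structure, idx) {
  a <- structure$atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resindex)
  first <- !duplicated(key)
  list(group = match(key, key[first]),
       author_resid = a$author_resid[first],
       labels = sprintf("%s:%s:%d", a$chain[first], a$resname[first],
                        a$author_resid[first]))
}

#' Per-frame RMSD against a reference after optimal superposition
#'
#' Each frame's selected atoms are Kabsch-fitted onto the reference and the
#' least-squares RMSD is reported, as in backbone-RMSD stability analysis of
#' MD trajectories.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param reference n_sel x 3 reference coordinates, or \code{NULL} to use
#'   the first frame's selection.
#' @param selection atoms to fit and measure (default backbone N, CA, C).
#' @return a \code{\link{SeriesResult}} in Angstrom.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = "name N CA C") {
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  if (is.null(reference)) reference <- matrix(traj$coords[1, idx, ], ncol = 3)
  reference <- as.matrix(reference)
  if (nrow(reference) != length(idx)) {
    stop("reference has ", nrow(reference), " atoms but selection has ",
         length(idx))
  }
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    kabsch_superpose(matrix(traj$coords[t, idx, ], ncol = 3), reference)$rmsd
  }, numeric(1))
  SeriesResult(vals, "rmsd", "A", sel$label)
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed onto the iteratively computed mean structure of the
#' selection (two passes), then RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).
#' With one selected atom per residue (the default Calpha selection) the
#' profile is the per-residue fluctuation; with several, atom RMSF values
#' within a residue are root-mean-square combined.
#'
#' @param traj a \code{\link{Trajectory}} with >= 2 frames.
#' @param selection atoms to analyse (default \code{"calpha"}).
#' @param superpose fit frames onto the iterative mean first (default TRUE).
#'   Set FALSE for ensembles already expressed in a common frame (e.g. the
#'   package's synthetic generators), where fitting would absorb part of the
#'   planted fluctuation.
#' @return a \code{\link{ProfileResult}} in Angstrom keyed by author residue
#'   number.
#' @export
rmsf_profile <- function(traj, selection = "calpha", superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  if (superpose) {
    sup <- superpose_trajectory(traj, sel)
  } else {
    sup <- list(traj = traj,
                mean = apply(traj$coords[, idx, , drop = FALSE], c(2, 3), mean))
  }
  sub <- sup$traj$coords[, idx, , drop = FALSE]
  msf <- numeric(length(idx))
  for (k in seq_along(idx)) {
    dev <- sweep(matrix(sub[, k, ], ncol = 3), 2, sup$mean[k, ])
    msf[k] <- mean(rowSums(dev^2))
  }
  res <- .sel_residues(traj$topology, idx)
  per_res <- sqrt(tapply(msf, res$group, mean))
  ProfileResult(as.numeric(per_res), res$author_resid, "rmsf", "A",
                labels = res$labels)
}

#' Radius of gyration per frame
#'
#' Rg(t) = sqrt( sum_i w_i |r_i - r_com|^2 / sum_i w_i ), with w the atomic
#' mass (default) or 1.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param selection atoms to include (default all).
#' @param mass_weighted use atomic masses as weights.
#' @return a \code{\link{SeriesResult}} in Angstrom.
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = TRUE) {
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  w <- if (mass_weighted) traj$topology$atoms$mass[idx] else rep(1, length(idx))
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    xyz <- matrix(traj$coords[t, idx, ], ncol = 3)
    com <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
  }, numeric(1))
  SeriesResult(vals, "rg", "A", sel$label)
}

#' Normalised density histogram of a series
#'
#' @param series a \code{\link{SeriesResult}}.
#' @param n_bins number of bins (>= 2).
#' @return list with \code{edges} (length n_bins+1), \code{density}
#'   (integrates to 1), and \code{counts}.
#' @export
series_density <- function(series, n_bins = 50L) {
  stopifnot(n_bins >= 2L)
  x <- series$values
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)   # constant series: one occupied bin
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  list(edges = edges, density = h$density, counts = h$counts)
}

#' Write a series or profile result as CSV
#'
#' Series rows are (frame, value); profile rows are (author_resid, label,
#' value). The header carries the metric, unit and selection.
#'
#' @param x a \code{SeriesResult} or \code{ProfileResult}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "SeriesResult")) {
    df <- data.frame(frame = seq_along(x$values), value = x$values)
    names(df)[2] <- sprintf("%s_%s", x$metric, gsub("[^A-Za-z0-9]", "", x$unit))
  } else if (inherits(x, "ProfileResult")) {
    df <- data.frame(author_resid = x$author_resid,
                     label = if (is.null(x$labels)) "" else x$labels,
                     value = x$values)
    names(df)[3] <- sprintf("%s_%s", x$metric, gsub("[^A-Za-z0-9]", "", x$unit))
  } else {
    stop("unsupported result type")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
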