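#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalised time-averaged dot products of atomic displacement vectors:
#' entry (i, j) = <d_i . d_j> / sqrt(<d_i . d_i> <d_j . d_j>), where d_i(t)
#' is atom i's vector displacement from its time-mean position after the
#' trajectory has been superposed onto the iterative mean structure of the
#' analysis selection. Values lie in [-1, 1]; +1 marks fully correlated and
#' -1 fully anti-correlated motion of a residue pair.
#'
#' @param traj a \code{\link{Trajectory}} with >= 2 frames.
#' @param selection atoms to correlate (default \code{"calpha"}).
#' @param superpose superpose frames onto the selection's iterative mean
#'   first (default TRUE; set FALSE if the trajectory is already fitted).
#' @return object of class \code{"DCCMatrix"}: list with \code{matrix}
#'   (n_sel x n_sel, unit diagonal; entries for zero-variance atoms are
#'   \code{NA}), \code{labels} (author-numbered residue labels),
#'   \code{selection_label}, \code{n_frames_used}.
#' @export
dccm <- function(traj, selection = "calpha", superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  if (superpose) traj <- superpose_trajectory(traj, sel)$traj
  nf <- n_frames(traj)
  n <- length(idx)

  # displacement components about the time mean, one (nf x n) matrix per axis
  dx <- vector("list", 3)
  for (ax in 1:3) {
    m <- matrix(traj$coords[, idx, ax], nrow = nf)
    dx[[ax]] <- sweep(m, 2, colMeans(m))
  }
  inner <- (crossprod(dx[[1]]) + crossprod(dx[[2]]) + crossprod(dx[[3]])) / nf
  v <- diag(inner)
  zero <- v <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s); DCCM entries set to NA")
  }
  denom <- sqrt(outer(v, v))
  cc <- inner / denom
  cc[zero, ] <- NA_real_
  cc[, zero] <- NA_real_
  cc <- pmin(pmax(cc, -1), 1)
  diag(cc)[!zero] <- 1

  res <- .sel_residues(traj$topology, idx)
  structure(list(matrix = cc, labels = res$labels[res$group],
                 selection_label = sel$label, n_frames_used = nf),
            class = "DCCMatrix")
}

#' @export
print.DCCMatrix <- function(x, ...) {
  cat("DCCMatrix:", nrow(x$matrix), "x", ncol(x$matrix), "from",
      x$n_frames_used, "frames\n")
  invisible(x)
}

#' Write a DCCM as a square CSV with residue labels
#' @param x a \code{DCCMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_dccm_csv <- function(x, path) {
  m <- as.data.frame(x$matrix)
  names(m) <- x$labels
  m <- cbind(residue = x$labels, m)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Principal component analysis of the positional covariance
#'
#' Essential-dynamics PCA: frames are superposed onto the iterative mean
#' structure of the selection, the 3n x 3n covariance matrix of the selected
#' coordinates is formed, and its symmetric eigendecomposition taken. The
#' trace (sum of eigenvalues, Angstrom^2) measures total fluctuation;
#' leading eigenvectors are the dominant collective motions.
#'
#' @param traj a \code{\link{Trajectory}} with >= 2 frames.
#' @param selection atoms to analyse (default \code{"calpha"}).
#' @param superpose superpose first (default TRUE).
#' @return object of class \code{"PCAResult"}: \code{eigenvalues}
#'   (Angstrom^2, descending, clipped at 0), \code{eigenvectors} (columns,
#'   orthonormal, largest-magnitude component made positive), \code{trace},
#'   \code{variance_fractions}, \code{mean_structure} (n_sel x 3),
#'   \code{selection_label}, \code{labels}.
#' @export
pca_covariance <- function(traj, selection = "calpha", superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames")
  sel <- .resolve_selection(traj$topology, selection)
  idx <- sel$indices
  if (superpose) {
    sup <- superpose_trajectory(traj, sel)
    traj <- sup$traj
  }
  nf <- n_frames(traj)
  n <- length(idx)
  # frames as nf x 3n matrix, atom-major (x1 y1 z1 x2 ...)
  X <- matrix(0, nf, 3 * n)
  for (ax in 1:3) X[, seq(ax, 3 * n, by = 3)] <- matrix(traj$coords[, idx, ax], nrow = nf)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  res <- .sel_residues(traj$topology, idx)
  structure(list(
    eigenvalues = vals, eigenvectors = vecs, trace = sum(diag(C)),
    variance_fractions = vals / sum(vals),
    mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
    selection_label = sel$label, sel_indices = idx,
    labels = res$labels[res$group], res_group = res$group,
    author_resid = res$author_resid
  ), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: trace %.3f A^2; first 3 PCs %.1f%% of variance\n",
              x$trace, 100 * sum(x$variance_fractions[1:min(3, length(x$variance_fractions))])))
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' Each frame (superposed, mean-centred) is projected onto the first k
#' eigenvectors; the per-PC projection variance equals the corresponding
#' eigenvalue up to sampling.
#'
#' @param traj a \code{\link{Trajectory}} (same system the PCA was fitted on).
#' @param pca a \code{\link{pca_covariance}} result.
#' @param k number of components (>= 1).
#' @param superpose superpose frames onto the PCA's mean structure first.
#' @return n_frames x k matrix of projections, Angstrom.
#' @export
project_onto_pcs <- function(traj, pca, k = 2L, superpose = TRUE) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(pca$eigenvectors)) stop("k exceeds the number of eigenvectors")
  idx <- pca$sel_indices
  nf <- n_frames(traj)
  n <- length(idx)
  proj <- matrix(0, nf, k)
  mu_vec <- as.vector(t(pca$mean_structure))
  for (t in seq_len(nf)) {
    fr <- matrix(traj$coords[t, , ], ncol = 3)
    if (superpose) fr <- .apply_fit(fr, idx, pca$mean_structure)
    v <- as.vector(t(fr[idx, , drop = FALSE])) - mu_vec
    proj[t, ] <- v %*% pca$eigenvectors[, seq_len(k), drop = FALSE]
  }
  colnames(proj) <- paste0("PC", seq_len(k))
  proj
}

#' Per-residue loading profile and extreme structures of a PCA mode
#'
#' The loading of residue r is the Euclidean norm of the mode's 3-vector at
#' that residue's selected atom(s); the two extreme coordinate sets are the
#' mean structure displaced by +/- s * sqrt(eigenvalue) along the mode
#' (porcupine-style end points).
#'
#' @param pca a \code{\link{pca_covariance}} result.
#' @param mode mode index (1 = PC1).
#' @param s displacement multiplier in standard deviations (default 2).
#' @return list with \code{profile} (a \code{\link{ProfileResult}}, unitless
#'   loadings), \code{plus} and \code{minus} (n_sel x 3 coordinate sets).
#' @export
mode_profile <- function(pca, mode = 1L, s = 2) {
  if (mode < 1L || mode > ncol(pca$eigenvectors)) stop("invalid mode index")
  v <- pca$eigenvectors[, mode]
  n <- length(v) / 3
  vm <- matrix(v, ncol = 3, byrow = TRUE)
  per_atom <- sqrt(rowSums(vm^2))
  per_res <- sqrt(tapply(per_atom^2, pca$res_group, sum))
  amp <- s * sqrt(pca$eigenvalues[mode])
  list(
    profile = ProfileResult(as.numeric(per_res), pca$author_resid,
                            sprintf("pc%d_loading", mode), "",
                            labels = pca$labels[!duplicated(pca$res_group)]),
    plus = pca$mean_structure + amp * vm,
    minus = pca$mean_structure - amp * vm
  )
}
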