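#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Two-dimensional free-energy landscape by Boltzmann inversion
#'
#' Frames are binned on two collective variables (by default Rg and RMSD);
#' the free energy of an occupied bin is G_i = -kB * T * ln(N_i / N_max),
#' so the most populated bin sits at exactly 0 and less populated bins at
#' positive G. Empty bins are assigned an artificial barrier of
#' (max occupied G) + kB*T and flagged, keeping the surface finite.
#'
#' @param x,y \code{\link{SeriesResult}}s (or plain numeric vectors) of equal
#'   length, the two collective variables.
#' @param n_bins integer vector (nx, ny), each >= 2 (default c(50, 50)).
#' @param temperature temperature in K (default 300).
#' @return object of class \code{"FELGrid"}: \code{x_edges}, \code{y_edges},
#'   \code{counts} (nx x ny), \code{G} (kcal/mol), \code{empty_mask},
#'   \code{temperature}, \code{kB}, \code{x_bin}, \code{y_bin} (per-frame bin
#'   assignments), and axis labels.
#' @export
compute_fel <- function(x, y, n_bins = c(50L, 50L), temperature = 300) {
  xv <- if (inherits(x, "SeriesResult")) x$values else as.numeric(x)
  yv <- if (inherits(y, "SeriesResult")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("collective-variable series differ in length")
  if (length(xv) < 1L) stop("need at least one frame")
  n_bins <- rep_len(as.integer(n_bins), 2)
  if (any(n_bins < 2L)) stop("n_bins must be >= 2 in each dimension")

  edges <- function(v, nb) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    half <- diff(r) / nb / 2            # pad by half a bin so extremes are interior
    seq(r[1] - half, r[2] + half, length.out = nb + 1L)
  }
  xe <- edges(xv, n_bins[1]); ye <- edges(yv, n_bins[2])
  xb <- findInterval(xv, xe, rightmost.closed = TRUE)
  yb <- findInterval(yv, ye, rightmost.closed = TRUE)
  counts <- matrix(0L, n_bins[1], n_bins[2])
  for (t in seq_along(xv)) counts[xb[t], yb[t]] <- counts[xb[t], yb[t]] + 1L

  kB <- KB_KCAL
  G <- matrix(NA_real_, n_bins[1], n_bins[2])
  occ <- counts > 0L
  nmax <- max(counts)
  G[occ] <- -kB * temperature * log(counts[occ] / nmax)
  barrier <- max(G[occ]) + kB * temperature
  G[!occ] <- barrier

  structure(list(x_edges = xe, y_edges = ye, counts = counts, G = G,
                 empty_mask = !occ, temperature = temperature, kB = kB,
                 x_bin = xb, y_bin = yb,
                 x_label = if (inherits(x, "SeriesResult")) x$metric else "x",
                 y_label = if (inherits(y, "SeriesResult")) y$metric else "y"),
            class = "FELGrid")
}

#' @export
print.FELGrid <- function(x, ...) {
  cat(sprintf("FELGrid %dx%d (%s vs %s), T=%g K, %d occupied bins\n",
              nrow(x$G), ncol(x$G), x$x_label, x$y_label, x$temperature,
              sum(!x$empty_mask)))
  invisible(x)
}

# 8-neighbourhood offsets
.nbr8 <- cbind(
  di = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dj = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

#' Locate free-energy basins
#'
#' Local minima of G over the 8-neighbourhood of occupied bins; every
#' occupied bin is assigned to a basin by steepest descent (repeatedly
#' stepping to the lowest-G occupied neighbour; ties broken toward the
#' smallest (i, j)). Basins are ordered by ascending minimum G, then
#' ascending (i, j).
#'
#' @param grid a \code{\link{compute_fel}} result.
#' @return list of basins, each a list with \code{minimum_bin} (i, j),
#'   \code{member_bins} (m x 2 matrix), \code{G_min}, \code{depth}
#'   (barrier level minus G_min, kcal/mol), \code{population_fraction}.
#' @export
locate_minima <- function(grid) {
  occ <- !grid$empty_mask
  if (!any(occ)) stop("grid has no occupied bins")
  G <- grid$G
  nx <- nrow(G); ny <- ncol(G)
  occ_idx <- which(occ, arr.ind = TRUE)
  occ_idx <- occ_idx[order(occ_idx[, 1], occ_idx[, 2]), , drop = FALSE]

  # steepest-descent successor of each occupied bin (0 = is a local minimum).
  # The descent target minimises (G, i, j) lexicographically over the bin and
  # its occupied neighbours, so plateaus drain to their smallest-(i, j) bin.
  key <- function(i, j) (j - 1L) * nx + i
  succ <- integer(nx * ny)
  for (r in seq_len(nrow(occ_idx))) {
    i <- occ_idx[r, 1]; j <- occ_idx[r, 2]
    bg <- G[i, j]; bi <- i; bj <- j
    for (q in seq_len(8)) {
      ii <- i + .nbr8[q, 1]; jj <- j + .nbr8[q, 2]
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || !occ[ii, jj]) next
      g <- G[ii, jj]
      if (g < bg || (g == bg && (ii < bi || (ii == bi && jj < bj)))) {
        bg <- g; bi <- ii; bj <- jj
      }
    }
    succ[key(i, j)] <- if (bi == i && bj == j) 0L else key(bi, bj)
  }

  # follow descent paths to their terminal minima
  root <- integer(nx * ny)
  for (r in seq_len(nrow(occ_idx))) {
    k <- key(occ_idx[r, 1], occ_idx[r, 2])
    p <- k
    while (succ[p] != 0L) p <- succ[p]
    root[k] <- p
  }

  barrier <- max(G[occ]) + grid$kB * grid$temperature
  total <- sum(grid$counts)
  mins <- unique(root[root != 0L])
  basins <- lapply(mins, function(m) {
    members_k <- which(root == m)
    mi <- (members_k - 1L) %% nx + 1L
    mj <- (members_k - 1L) %/% nx + 1L
    i0 <- (m - 1L) %% nx + 1L; j0 <- (m - 1L) %/% nx + 1L
    list(minimum_bin = c(i0, j0),
         member_bins = cbind(i = mi, j = mj),
         G_min = G[i0, j0],
         depth = barrier - G[i0, j0],
         population_fraction = sum(grid$counts[cbind(mi, mj)]) / total)
  })
  ord <- order(vapply(basins, function(b) b$G_min, numeric(1)),
               vapply(basins, function(b) b$minimum_bin[1], numeric(1)),
               vapply(basins, function(b) b$minimum_bin[2], numeric(1)))
  basins[ord]
}

#' Frame best representing a basin
#'
#' Among frames falling in the basin's minimum bin, returns the frame whose
#' (x, y) is closest (Euclidean after scaling each axis by its bin width) to
#' the bin centre; ties go to the lowest frame index.
#'
#' @param grid a \code{\link{compute_fel}} result built from the same series.
#' @param basin one element of \code{\link{locate_minima}}'s result.
#' @param x,y the collective-variable series used to build \code{grid}.
#' @return frame index (1-based).
#' @export
representative_frame <- function(grid, basin, x, y) {
  xv <- if (inherits(x, "SeriesResult")) x$values else as.numeric(x)
  yv <- if (inherits(y, "SeriesResult")) y$values else as.numeric(y)
  i <- basin$minimum_bin[1]; j <- basin$minimum_bin[2]
  inbin <- which(grid$x_bin == i & grid$y_bin == j)
  if (length(inbin) == 0L) stop("no frames fall in the basin's minimum bin")
  wx <- diff(grid$x_edges[c(i, i + 1L)])
  wy <- diff(grid$y_edges[c(j, j + 1L)])
  cx <- mean(grid$x_edges[c(i, i + 1L)])
  cy <- mean(grid$y_edges[c(j, j + 1L)])
  d2 <- ((xv[inbin] - cx) / wx)^2 + ((yv[inbin] - cy) / wy)^2
  inbin[which.min(d2)]    # which.min takes the first, i.e. lowest frame index
}

#' Write an FEL grid as long-format CSV
#'
#' One row per bin: (x_center, y_center, count, G, empty_flag).
#'
#' @param grid a \code{FELGrid}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fel_csv <- function(grid, path) {
  nx <- nrow(grid$G); ny <- ncol(grid$G)
  xc <- (grid$x_edges[-1] + grid$x_edges[-(nx + 1)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-(ny + 1)]) / 2
  df <- data.frame(
    x_center = rep(xc, times = ny),
    y_center = rep(yc, each = nx),
    count = as.vector(grid$counts),
    G_kcal_mol = as.vector(grid$G),
    empty = as.vector(grid$empty_mask)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
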