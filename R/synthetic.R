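# run expr with a local, restored RNG state so generators are pure functions
# of (spec, seed) and never disturb the caller's random stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# NeRF atom placement: position D at bond length r from C, angle theta
# (deg) at B-C-D, dihedral phi (deg) for A-B-C-D
.place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone bond lengths (A) and angles (deg)
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8)

# backbone chain from per-residue (phi, psi); returns list of per-residue
# lists with N, CA, C, O, H coordinate vectors
.build_backbone <- function(phi, psi, omega = 180) {
  n <- length(phi)
  bb <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(.BB$n_ca, 0, 0)
  ang <- .BB$ang_n_ca_c * pi / 180
  C <- CA + .BB$ca_c * c(-cos(ang), sin(ang), 0)
  bb[[1]] <- list(N = N, CA = CA, C = C)
  for (i in 2:n) {
    Np <- .place_atom(bb[[i - 1]]$N, bb[[i - 1]]$CA, bb[[i - 1]]$C,
                      .BB$c_n, .BB$ang_ca_c_n, psi[i - 1])
    CAp <- .place_atom(bb[[i - 1]]$CA, bb[[i - 1]]$C, Np,
                       .BB$n_ca, .BB$ang_c_n_ca, omega)
    Cp <- .place_atom(bb[[i - 1]]$C, Np, CAp,
                      .BB$ca_c, .BB$ang_n_ca_c, phi[i])
    bb[[i]] <- list(N = Np, CA = CAp, C = Cp)
  }
  for (i in seq_len(n)) {
    ps <- if (i < n) psi[i] else 180
    bb[[i]]$O <- .place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                             .BB$c_o, .BB$ang_ca_c_o, ps + 180)
  }
  for (i in 2:n) {
    v <- bb[[i]]$N - bb[[i - 1]]$O
    bb[[i]]$H <- bb[[i]]$N + v / sqrt(sum(v^2))
  }
  bb
}

.bb_to_structure <- function(bb, resname = "ALA", chain = "A",
                             first_resid = 1L) {
  rows <- list()
  for (i in seq_along(bb)) {
    for (nm in c("N", "H", "CA", "C", "O")) {
      if (is.null(bb[[i]][[nm]])) next
      rows[[length(rows) + 1L]] <- list(
        name = nm, el = if (nm %in% c("CA", "C")) "C" else substr(nm, 1, 1),
        res = i, xyz = bb[[i]][[nm]])
    }
  }
  Structure(
    name = vapply(rows, `[[`, character(1), "name"),
    resname = resname,
    author_resid = first_resid - 1L + vapply(rows, `[[`, numeric(1), "res"),
    chain = chain,
    xyz = do.call(rbind, lapply(rows, `[[`, "xyz")),
    element = vapply(rows, `[[`, character(1), "el")
  )
}

#' Generate an idealised toy protein backbone
#'
#' Full backbone (N, H, CA, C, O) with ideal bond geometry. Folds:
#' \itemize{
#'   \item \code{helix}: alpha-helical dihedrals phi/psi = -57/-47 degrees;
#'   \item \code{extended}: a fully extended chain (phi/psi = -120/120);
#'   \item \code{hairpin}: two antiparallel fully-extended strands whose
#'     inter-strand placement is refined (deterministic grid search over the
#'     rigid offset) to maximise the number of backbone H-bonds, joined by a
#'     4-residue turn.
#' }
#'
#' @param n_res number of residues (>= 5).
#' @param fold one of \code{"helix"}, \code{"extended"}, \code{"hairpin"}.
#' @return a \code{\link{Structure}}; for hairpins the attribute
#'   \code{"fold_info"} lists \code{strand} and \code{turn} residue indices.
#' @export
make_toy_protein <- function(n_res, fold = c("helix", "extended", "hairpin")) {
  fold <- match.arg(fold)
  if (n_res < 5L) stop("n_res must be >= 5")
  if (fold == "helix") {
    return(.bb_to_structure(.build_backbone(rep(-57, n_res), rep(-47, n_res))))
  }
  if (fold == "extended") {
    return(.bb_to_structure(.build_backbone(rep(-120, n_res), rep(120, n_res))))
  }
  .make_hairpin(n_res)
}

.make_hairpin <- function(n_res) {
  n_turn <- 4L
  ns <- (n_res - n_turn) %/% 2L
  if (ns < 2L) stop("hairpin needs at least 8 residues")
  extra <- n_res - n_turn - 2L * ns   # odd leftover goes to strand 1
  n1 <- ns + extra

  # strand template: planar fully-extended chain (phi = psi = 180)
  strand <- function(n) .build_backbone(rep(180, n), rep(180, n))
  s1 <- strand(n1)
  s2 <- strand(ns)
  # antiparallel partner: proper 180-degree rotation about z, then a rigid
  # (dx, dy) offset chosen by deterministic grid search to maximise the
  # number of Kabsch-Sander bonds between the strands
  rot <- function(p) c(-p[1], -p[2], p[3])
  s2r <- lapply(s2, function(res) lapply(res, function(p) {
    if (is.null(p)) NULL else rot(p)
  }))
  span1 <- s1[[n1]]$CA[1]
  score <- function(dx, dy) {
    sh <- lapply(s2r, function(res) lapply(res, function(p) {
      if (is.null(p)) NULL else p + c(dx, dy, 0)
    }))
    cnt <- 0L
    for (i in seq_len(n1)) for (j in seq_len(ns)) {
      di <- s1[[i]]; aj <- sh[[j]]
      if (!is.null(di$H) &&
          kabsch_sander_energy(di$N, di$H, aj$C, aj$O) < .KS_CUTOFF) cnt <- cnt + 1L
      if (!is.null(aj$H) &&
          kabsch_sander_energy(aj$N, aj$H, di$C, di$O) < .KS_CUTOFF) cnt <- cnt + 1L
    }
    cnt
  }
  best <- c(0, 0); best_cnt <- -1L
  for (dx in seq(span1 + 1, span1 + 9, by = 0.25)) {
    for (dy in seq(3.8, 6.0, by = 0.2)) {
      cnt <- score(dx, dy)
      if (cnt > best_cnt) { best_cnt <- cnt; best <- c(dx, dy) }
    }
  }
  s2f <- lapply(s2r, function(res) lapply(res, function(p) {
    if (is.null(p)) NULL else p + c(best[1], best[2], 0)
  }))

  # 4-residue turn arcs from strand 1's C-terminus to strand 2's N-terminus
  p0 <- s1[[n1]]$CA; p1 <- s2f[[1]]$CA
  mid <- (p0 + p1) / 2 + c(4.5, 0, 0)
  turn <- vector("list", n_turn)
  for (k in seq_len(n_turn)) {
    u <- k / (n_turn + 1)
    ca <- (1 - u)^2 * p0 + 2 * u * (1 - u) * mid + u^2 * p1  # quadratic Bezier
    turn[[k]] <- list(N = ca + c(-0.9, 0.6, 0.8), CA = ca,
                      C = ca + c(0.9, 0.6, -0.8),
                      O = ca + c(0.9, 0.6, -2.03))
  }
  st <- .bb_to_structure(c(s1, turn, s2f))
  attr(st, "fold_info") <- list(
    strand = c(seq_len(n1), (n1 + n_turn + 1L):n_res),
    turn = (n1 + 1L):(n1 + n_turn))
  st
}

#' Generate a chain of Calpha pseudo-atoms
#'
#' Minimal reference for fluctuation toys: one CA per residue, 3.8 Angstrom
#' apart along x.
#'
#' @param n_res number of residues.
#' @return a \code{\link{Structure}}.
#' @export
make_ca_chain <- function(n_res) {
  Structure(name = rep("CA", n_res), resname = "ALA",
            author_resid = seq_len(n_res), chain = "A",
            xyz = cbind(3.8 * seq_len(n_res), 0, 0),
            element = "C")
}

#' Generate a stationary Gaussian ensemble with planted correlations
#'
#' Frames are the reference plus Gaussian displacements: each coordinate
#' axis independently draws from N(0, sigma^2 * C) across atoms, where C is
#' the planted atom-atom correlation matrix — so the expected DCCM equals C.
#' Correlation blocks set C to \code{rho} between every atom of residue set
#' A and every atom of residue set B (and to |rho| within each set, which
#' keeps C positive semi-definite for any |rho| <= 1).
#'
#' @param reference a \code{\link{Structure}}.
#' @param sigma per-coordinate displacement standard deviation, Angstrom;
#'   a scalar, or one value per atom (e.g. to plant extra fluctuation in a
#'   loop region).
#' @param n_frames number of frames.
#' @param seed RNG seed (explicit; the global RNG state is untouched).
#' @param blocks list of correlation blocks, each
#'   \code{list(a = residue indices, b = residue indices, rho = value)}
#'   (sequence positions, i.e. \code{resindex}).
#' @return a \code{\link{Trajectory}}. Identical inputs give bit-identical
#'   frames.
#' @export
make_gaussian_ensemble <- function(reference, sigma = 0.5, n_frames = 1000L,
                                   seed = 1L, blocks = list()) {
  stopifnot(all(sigma > 0), n_frames >= 1)
  n <- n_atoms(reference)
  sigma <- rep_len(sigma, n)
  C <- diag(n)
  resix <- reference$atoms$resindex
  for (b in blocks) {
    ia <- which(resix %in% b$a)
    ib <- which(resix %in% b$b)
    if (abs(b$rho) > 1) stop("block correlation must lie in [-1, 1]")
    C[ia, ia] <- abs(b$rho); C[ib, ib] <- abs(b$rho)
    C[ia, ib] <- b$rho; C[ib, ia] <- b$rho
    diag(C) <- 1
  }
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("implied covariance is not positive semi-definite")
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  coords <- .with_seed(seed, {
    arr <- array(0, dim = c(n_frames, n, 3))
    for (ax in 1:3) {
      Z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
      D <- (Z %*% L) * rep(sigma, each = n_frames)
      arr[, , ax] <- sweep(D, 2, reference$xyz[, ax], "+")
    }
    arr
  })
  Trajectory(reference, coords)
}

#' Generate a two-state metastable trajectory with planted populations
#'
#' Frames alternate between two conformers with prescribed populations plus
#' isotropic Gaussian jitter — the planted-basin substrate for free-energy
#' landscape tests. In \code{"schedule"} mode exactly
#' \code{round(p_a * n_frames)} frames are conformer A, interleaved evenly;
#' \code{"bernoulli"} draws each frame's state independently.
#'
#' @param topology a \code{\link{Structure}} (atom metadata).
#' @param conf_a,conf_b n_atoms x 3 conformer coordinates.
#' @param p_a population of conformer A in (0, 1).
#' @param n_frames number of frames.
#' @param jitter per-coordinate Gaussian jitter sd, Angstrom.
#' @param seed RNG seed.
#' @param assignment \code{"schedule"} (deterministic) or \code{"bernoulli"}.
#' @return a \code{\link{Trajectory}} with attribute \code{"state"} (the
#'   per-frame conformer labels "A"/"B").
#' @export
make_two_state_trajectory <- function(topology, conf_a, conf_b, p_a = 0.7,
                                      n_frames = 1000L, jitter = 0.05,
                                      seed = 1L,
                                      assignment = c("schedule", "bernoulli")) {
  assignment <- match.arg(assignment)
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  if (!all(dim(conf_a) == dim(conf_b))) stop("conformers differ in size")
  if (nrow(conf_a) != n_atoms(topology)) stop("conformer size does not match topology")
  stopifnot(p_a > 0, p_a <= 1)
  n <- nrow(conf_a)
  state <- .with_seed(seed, {
    if (assignment == "schedule") {
      na <- round(p_a * n_frames)
      t <- seq_len(n_frames)
      is_a <- ceiling(t * na / n_frames) > ceiling((t - 1) * na / n_frames)
      ifelse(is_a, "A", "B")
    } else {
      ifelse(stats::runif(n_frames) < p_a, "A", "B")
    }
  })
  coords <- .with_seed(seed + 1L, {
    arr <- array(0, dim = c(n_frames, n, 3))
    for (t in seq_len(n_frames)) {
      base <- if (state[t] == "A") conf_a else conf_b
      arr[t, , ] <- base + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    }
    arr
  })
  tr <- Trajectory(topology, coords)
  attr(tr, "state") <- state
  tr
}

#' Generate a two-residue trajectory with a planted hydrogen bond
#'
#' A donor residue (N-H) faces an acceptor residue (C=O). In the designated
#' frames the donor-acceptor distance is 2.9 Angstrom with a linear
#' N-H...O geometry (a textbook hydrogen bond); otherwise 5.0 Angstrom
#' (none). Schedule mode plants the bond in exactly
#' \code{round(f * n_frames)} evenly interleaved frames.
#'
#' @param f bonded fraction in [0, 1].
#' @param n_frames number of frames.
#' @param mode \code{"schedule"} or \code{"bernoulli"}.
#' @param seed RNG seed (bernoulli mode).
#' @return a \code{\link{Trajectory}} with attribute \code{"bonded"}
#'   (logical per frame).
#' @export
make_hbond_toy <- function(f, n_frames = 100L, mode = c("schedule", "bernoulli"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(f >= 0, f <= 1)
  topo <- Structure(
    name = c("N", "H", "C", "O"),
    resname = c("GLY", "GLY", "GLY", "GLY"),
    author_resid = c(1L, 1L, 2L, 2L),
    chain = "A",
    xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(4.13, 0, 0), c(2.9, 0, 0)),
    element = c("N", "H", "C", "O")
  )
  bonded <- if (mode == "schedule") {
    nb <- round(f * n_frames)
    t <- seq_len(n_frames)
    ceiling(t * nb / n_frames) > ceiling((t - 1) * nb / n_frames)
  } else {
    .with_seed(seed, stats::runif(n_frames) < f)
  }
  coords <- array(0, dim = c(n_frames, 4, 3))
  far <- topo$xyz; far[3, 1] <- 6.23; far[4, 1] <- 5.0
  for (t in seq_len(n_frames)) {
    coords[t, , ] <- if (bonded[t]) topo$xyz else far
  }
  tr <- Trajectory(topo, coords)
  attr(tr, "bonded") <- bonded
  tr
}
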