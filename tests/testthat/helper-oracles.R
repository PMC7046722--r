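# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# brute-force minimum RMSD over a dense rotation grid (coarse Euler sweep
# followed by local refinement); centroids are aligned first
brute_min_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(a, b, g) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rz2
  }
  rmsd_of <- function(R) sqrt(mean(rowSums((X %*% R - Y)^2)))
  best <- c(0, 0, 0); best_r <- rmsd_of(diag(3))
  for (a in seq(0, 2 * pi, length.out = 19)[-19]) {
    for (b in seq(0, pi, length.out = 10)) {
      for (g in seq(0, 2 * pi, length.out = 19)[-19]) {
        r <- rmsd_of(rotmat(a, b, g))
        if (r < best_r) { best_r <- r; best <- c(a, b, g) }
      }
    }
  }
  step <- 0.25
  for (iter in 1:4) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in 1:3) for (s in c(-step, step)) {
        cand <- best; cand[k] <- cand[k] + s
        r <- rmsd_of(rotmat(cand[1], cand[2], cand[3]))
        if (r < best_r) { best_r <- r; best <- cand; improved <- TRUE }
      }
    }
    step <- step / 4
  }
  best_r
}

# literal double-loop DCCM on raw coordinates (no superposition)
dccm_oracle <- function(traj, idx = seq_len(dim(traj$coords)[2])) {
  nf <- dim(traj$coords)[1]
  n <- length(idx)
  mean_pos <- lapply(idx, function(i) {
    colMeans(matrix(traj$coords[, i, ], nrow = nf))
  })
  disp <- lapply(seq_along(idx), function(k) {
    sweep(matrix(traj$coords[, idx[k], ], nrow = nf), 2, mean_pos[[k]])
  })
  cc <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0
      for (t in seq_len(nf)) num <- num + sum(disp[[i]][t, ] * disp[[j]][t, ])
      num <- num / nf
      di <- mean(rowSums(disp[[i]]^2))
      dj <- mean(rowSums(disp[[j]]^2))
      cc[i, j] <- num / sqrt(di * dj)
    }
  }
  cc
}
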