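test_that("DCCM self-correlation is exactly one and anti-correlation exactly minus one", {
  tr <- make_gaussian_ensemble(make_ca_chain(5), sigma = 0.5,
                               n_frames = 100, seed = 1)
  d <- dccm(tr, superpose = FALSE)
  expect_identical(unname(diag(d$matrix)), rep(1, 5))

  anti <- anticorrelated_trajectory(50)
  d2 <- dccm(anti, superpose = FALSE)
  expect_equal(d2$matrix[1, 2], -1, tolerance = 1e-12)
  expect_equal(d2$matrix[2, 1], -1, tolerance = 1e-12)
})

test_that("DCCM equals the literal double-loop oracle on small instances", {
  for (seed in 1:3) {
    tr <- make_gaussian_ensemble(make_ca_chain(8), sigma = 0.4,
                                 n_frames = 40, seed = seed)
    d <- dccm(tr, superpose = FALSE)
    expect_equal(d$matrix, dccm_oracle(tr), tolerance = 1e-12)
  }
})

test_that("DCCM agrees with bio3d on the same coordinates", {
  tr <- make_gaussian_ensemble(make_ca_chain(6), sigma = 0.5,
                               n_frames = 200, seed = 6)
  mine <- dccm(tr, superpose = FALSE)$matrix
  xyz <- matrix(0, 200, 18)
  for (t in 1:200) xyz[t, ] <- as.vector(t(get_frame(tr, t)))
  ref <- unclass(bio3d::dccm.xyz(xyz, pre.fit = FALSE))
  expect_equal(unname(mine), unname(ref[seq_len(6), seq_len(6)]),
               tolerance = 1e-8)
})

test_that("planted block correlations are recovered and null entries stay small", {
  tr <- make_gaussian_ensemble(
    make_ca_chain(10), sigma = 0.5, n_frames = 5000, seed = 7,
    blocks = list(list(a = 1:5, b = 6:10, rho = 0.8)))
  d <- dccm(tr, superpose = FALSE)
  cross <- d$matrix[1:5, 6:10]
  expect_equal(mean(cross), 0.8, tolerance = 0.05)
  expect_true(all(abs(cross - 0.8) < 0.1))

  null_tr <- make_gaussian_ensemble(make_ca_chain(10), sigma = 0.5,
                                    n_frames = 5000, seed = 8)
  d0 <- dccm(null_tr, superpose = FALSE)
  expect_lt(max(abs(d0$matrix[upper.tri(d0$matrix)])), 0.06)
})

test_that("negative planted correlations carry their sign", {
  tr <- make_gaussian_ensemble(
    make_ca_chain(8), sigma = 0.5, n_frames = 3000, seed = 12,
    blocks = list(list(a = 1:4, b = 5:8, rho = -0.6)))
  d <- dccm(tr, superpose = FALSE)
  expect_equal(mean(d$matrix[1:4, 5:8]), -0.6, tolerance = 0.06)
})

test_that("DCCM is invariant under a global rotation applied to all frames", {
  tr <- make_gaussian_ensemble(make_ca_chain(6), sigma = 0.4,
                               n_frames = 300, seed = 3)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- lapply(seq_len(300), function(t) get_frame(tr, t) %*% R)
  d1 <- dccm(tr)$matrix
  d2 <- dccm(Trajectory(tr$topology, rot))$matrix
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("zero-variance atoms yield flagged missing entries", {
  topo <- make_ca_chain(3)
  coords <- lapply(1:20, function(t) {
    xyz <- topo$xyz
    xyz[1, 1] <- xyz[1, 1] + sin(t)   # only atom 1 moves
    xyz
  })
  tr <- Trajectory(topo, coords)
  expect_warning(d <- dccm(tr, superpose = FALSE), "zero-variance")
  expect_true(is.na(d$matrix[2, 3]))
  expect_equal(d$matrix[1, 1], 1)
})

test_that("PCA trace equals the eigenvalue sum and per-coordinate variance sum", {
  tr <- make_gaussian_ensemble(make_ca_chain(7), sigma = 0.5,
                               n_frames = 400, seed = 10)
  p <- pca_covariance(tr, superpose = FALSE)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-8 * p$trace)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-12)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # orthonormality and covariance reconstruction
  V <- p$eigenvectors
  expect_equal(t(V) %*% V, diag(ncol(V)), tolerance = 1e-8)
  # isotropic ensemble: trace ~ 3 n sigma^2
  big <- make_gaussian_ensemble(make_ca_chain(5), sigma = 0.5,
                                n_frames = 4000, seed = 14)
  pb <- pca_covariance(big, superpose = FALSE)
  expect_equal(pb$trace, 3 * 5 * 0.25, tolerance = 0.05 * 3 * 5 * 0.25)
})

test_that("a planted dominant mode is recovered in direction and variance", {
  n <- 10
  ref <- make_ca_chain(n)
  set.seed(0)
  mode <- matrix(rnorm(3 * n), n, 3)
  mode <- mode / sqrt(sum(mode^2))
  nf <- 2000
  set.seed(42)
  amp <- rnorm(nf, sd = 2)
  coords <- lapply(seq_len(nf), function(t) {
    ref$xyz + amp[t] * mode + matrix(rnorm(3 * n, sd = 0.01), n, 3)
  })
  p <- pca_covariance(Trajectory(ref, coords), superpose = FALSE)
  expect_gte(p$variance_fractions[1], 0.99)
  cosang <- abs(sum(p$eigenvectors[, 1] * as.vector(t(mode))))
  expect_gte(cosang, 0.99)
})

test_that("projections reproduce eigenvalues and separate two-state ensembles", {
  tr <- make_gaussian_ensemble(make_ca_chain(6), sigma = 0.5,
                               n_frames = 500, seed = 17)
  p <- pca_covariance(tr, superpose = FALSE)
  proj <- project_onto_pcs(tr, p, k = 3, superpose = FALSE)
  # population variance of PC1 projections equals eigenvalue 1
  v1 <- mean((proj[, 1] - mean(proj[, 1]))^2)
  expect_equal(v1, p$eigenvalues[1], tolerance = 1e-8)
  expect_error(project_onto_pcs(tr, p, k = 0), "k must be")

  ref <- make_ca_chain(6)
  ts <- make_two_state_trajectory(ref, ref$xyz, ref$xyz + 3, p_a = 0.5,
                                  n_frames = 400, jitter = 0.05, seed = 2)
  pts <- pca_covariance(ts, superpose = FALSE)
  pr <- project_onto_pcs(ts, pts, k = 1, superpose = FALSE)
  state <- attr(ts, "state")
  gap <- abs(mean(pr[state == "A", 1]) - mean(pr[state == "B", 1]))
  # planted separation: |conf_a - conf_b| = 3 A on each of 18 coordinates
  expect_equal(gap, sqrt(18 * 9), tolerance = 0.05 * sqrt(18 * 9))
})

test_that("mode profiles localise planted single-residue motion", {
  topo <- make_ca_chain(8)
  set.seed(1)
  coords <- lapply(1:300, function(t) {
    xyz <- topo$xyz
    xyz[5, 2] <- xyz[5, 2] + 2 * sin(t)
    xyz + matrix(rnorm(24, sd = 0.01), 8, 3)
  })
  p <- pca_covariance(Trajectory(topo, coords), superpose = FALSE)
  mp <- mode_profile(p, 1)
  expect_equal(which.max(mp$profile$values), 5)
  expect_equal(sum(mp$profile$values^2), 1, tolerance = 1e-10)
  expect_error(mode_profile(p, 999), "invalid mode")
})
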