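rot_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(x, x)$rotation, diag(3), tolerance = 1e-9)
  y <- x %*% rot_z(pi / 2) + matrix(rep(c(3, -1, 2), each = 10), 10)
  f <- kabsch_superpose(y, x)
  expect_lt(f$rmsd, 1e-10)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("mirror images of a chiral set keep a proper rotation and match the grid oracle", {
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.4, 1.7))
  mirror <- chiral %*% diag(c(1, 1, -1))
  f <- kabsch_superpose(mirror, chiral)
  expect_gt(f$rmsd, 0.1)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  expect_equal(f$rmsd, brute_min_rmsd(mirror, chiral), tolerance = 0.02)
})

test_that("weighted Kabsch with uniform weights equals the unweighted fit", {
  set.seed(5)
  x <- matrix(rnorm(24), 8, 3)
  y <- x + matrix(rnorm(24, sd = 0.3), 8, 3)
  f1 <- kabsch_superpose(y, x)
  f2 <- kabsch_superpose(y, x, weights = rep(0.25, 8))
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-12)
  expect_equal(f1$rotation, f2$rotation, tolerance = 1e-10)
  expect_error(kabsch_superpose(y[1:2, ], x[1:2, ]), "at least 3")
})

test_that("RMSD series is zero for rigid motions and matches the grid oracle on noisy frames", {
  topo <- make_ca_chain(6)
  frames <- lapply(1:5, function(t) {
    topo$xyz %*% rot_z(t / 3) + matrix(rep(c(t, -t, 0.5 * t), each = 6), 6)
  })
  tr <- Trajectory(topo, frames)
  expect_lt(max(rmsd_series(tr, selection = "calpha")$values), 1e-9)

  noisy <- make_gaussian_ensemble(topo, sigma = 0.4, n_frames = 40, seed = 9)
  r <- rmsd_series(noisy, reference = topo$xyz, selection = "calpha")
  oracle <- vapply(seq_len(40), function(t) {
    brute_min_rmsd(get_frame(noisy, t), topo$xyz)
  }, numeric(1))
  expect_equal(mean(r$values), mean(oracle), tolerance = 0.05)
  expect_true(all(r$values <= oracle + 1e-6))  # Kabsch is the minimiser
})

test_that("RMSF vanishes for static trajectories and matches closed forms", {
  topo <- make_ca_chain(5)
  expect_error(rmsf_profile(Trajectory(topo, list(topo$xyz))), "2 frames")
  static <- static_trajectory(topo, 4)
  expect_lt(max(rmsf_profile(static)$values), 1e-12)

  # isotropic sigma per coordinate -> RMSF ~ sigma * sqrt(3); the ensemble is
  # generated in a fixed lab frame, so no superposition is applied
  sigma <- 0.3
  tr <- make_gaussian_ensemble(topo, sigma = sigma, n_frames = 2000, seed = 4)
  prof <- rmsf_profile(tr, superpose = FALSE)
  expect_equal(mean(prof$values), sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
})

test_that("RMSF about a fixed mean is independent of frame order", {
  topo <- make_ca_chain(6)
  tr <- make_gaussian_ensemble(topo, sigma = 0.5, n_frames = 200, seed = 21)
  p1 <- rmsf_profile(tr, superpose = FALSE)
  set.seed(99)
  perm <- sample(seq_len(200))
  tr2 <- Trajectory(topo, tr$coords[perm, , , drop = FALSE])
  p2 <- rmsf_profile(tr2, superpose = FALSE)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("radius of gyration matches analytic cases", {
  two <- Structure(name = c("X1", "X2"), resname = "UNK",
                   author_resid = c(1, 2), chain = "A",
                   xyz = rbind(c(-1, 0, 0), c(1, 0, 0)), element = "C")
  tr <- Trajectory(two, list(two$xyz))
  expect_equal(rg_series(tr, mass_weighted = FALSE)$values, 1)
  expect_equal(rg_series(tr)$values, 1)  # equal masses

  four <- Structure(name = paste0("X", 1:4), resname = "UNK",
                    author_resid = 1:4, chain = "A",
                    xyz = rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)),
                    element = "C")
  expect_equal(rg_series(Trajectory(four, list(four$xyz)),
                         mass_weighted = FALSE)$values, sqrt(2))
  coincident <- Trajectory(four, list(matrix(5, 4, 3)))
  expect_equal(rg_series(coincident)$values, 0)
})

test_that("RMSD and Rg series are invariant under global rigid motion", {
  topo <- make_ca_chain(8)
  tr <- make_gaussian_ensemble(topo, sigma = 0.4, n_frames = 30, seed = 13)
  moved <- lapply(seq_len(30), function(t) {
    get_frame(tr, t) %*% rot_z(0.7) + matrix(rep(c(10, -4, 2), each = 8), 8)
  })
  tr2 <- Trajectory(topo, moved)
  expect_equal(rmsd_series(tr2, reference = topo$xyz, selection = "calpha")$values,
               rmsd_series(tr, reference = topo$xyz, selection = "calpha")$values,
               tolerance = 1e-9)
  expect_equal(rg_series(tr2)$values, rg_series(tr)$values, tolerance = 1e-9)
})

test_that("series densities integrate to one and handle degenerate input", {
  s <- SeriesResult(rep(2.5, 10), "rmsd", "A")
  d <- series_density(s, 5)
  expect_equal(sum(d$counts > 0), 1)
  expect_equal(sum(d$counts), 10)
  set.seed(3)
  s2 <- SeriesResult(runif(500), "rg", "A")
  d2 <- series_density(s2, 20)
  widths <- diff(d2$edges)
  expect_equal(sum(d2$density * widths), 1, tolerance = 1e-12)
})
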