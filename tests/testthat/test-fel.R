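test_that("Boltzmann inversion zeroes the most populated bin and is monotone in counts", {
  x <- c(rep(1, 6), rep(2, 3), rep(3, 1))
  y <- rep(1, 10)
  g <- compute_fel(x, y, n_bins = c(3, 2), temperature = 300)
  occ <- !g$empty_mask
  expect_equal(min(g$G[occ]), 0)
  expect_equal(sum(g$counts), 10)
  # N_i > N_j => G_i < G_j over occupied bins
  cn <- g$counts[occ]; gn <- g$G[occ]
  for (i in seq_along(cn)) for (j in seq_along(cn)) {
    if (cn[i] > cn[j]) expect_lt(gn[i], gn[j])
  }
  # a bin with N = Nmax / e sits at kB * T
  xe <- c(rep(1, 1000), rep(2, 368))
  ge <- compute_fel(xe, rep(1, length(xe)), n_bins = c(2, 2))
  expect_equal(sort(ge$G[!ge$empty_mask])[2], KB_KCAL * 300 * log(1000 / 368),
               tolerance = 1e-12)
  expect_equal(KB_KCAL * 300, 0.5962, tolerance = 1e-4)
})

test_that("empty bins carry the flagged artificial barrier", {
  x <- c(rep(1, 7), rep(5, 3))
  g <- compute_fel(x, rep(1, 10), n_bins = c(4, 2))
  occ <- !g$empty_mask
  barrier <- max(g$G[occ]) + KB_KCAL * 300
  expect_true(all(g$G[g$empty_mask] == barrier))
  expect_true(all(g$G >= 0))
  # all frames in one bin: that bin 0, everything else flagged
  g1 <- compute_fel(rep(2, 50), rep(3, 50), n_bins = c(3, 3))
  expect_equal(sum(!g1$empty_mask), 1)
  expect_equal(g1$G[!g1$empty_mask], 0)
})

test_that("axis relabelling leaves free energies unchanged", {
  set.seed(8)
  x <- rnorm(500); y <- rnorm(500)
  g1 <- compute_fel(x, y, n_bins = c(12, 12))
  g2 <- compute_fel(x + 100, y - 42, n_bins = c(12, 12))
  expect_equal(g1$G, g2$G, tolerance = 1e-12)
  expect_equal(g1$counts, g2$counts)
})

test_that("basin detection finds planted minima and honours the tie rule", {
  # unimodal Gaussian counts -> single basin at the mode
  set.seed(2)
  x <- rnorm(4000); y <- rnorm(4000)
  g <- compute_fel(x, y, n_bins = c(9, 9))
  b <- locate_minima(g)
  expect_equal(length(b), 1)
  expect_equal(unname(b[[1]]$minimum_bin),
               unname(which(g$counts == max(g$counts), arr.ind = TRUE)[1, ]))
  expect_equal(b[[1]]$population_fraction, 1)

  # uniform counts: everything ties; one basin at the smallest (i, j)
  grid_vals <- expand.grid(1:5, 1:5)
  gu <- compute_fel(grid_vals[, 1], grid_vals[, 2], n_bins = c(5, 5))
  expect_true(all(gu$counts == 1))
  bu <- locate_minima(gu)
  expect_equal(length(bu), 1)
  expect_equal(unname(bu[[1]]$minimum_bin), c(1, 1))
})

test_that("two-state populations reproduce the planted free-energy gap", {
  ref <- make_ca_chain(10)
  tr <- make_two_state_trajectory(ref, ref$xyz, ref$xyz * 1.3, p_a = 0.7,
                                  n_frames = 10000, jitter = 0.05, seed = 3)
  rg <- rg_series(tr)
  rmsd <- rmsd_series(tr, reference = ref$xyz, selection = "calpha")
  g <- compute_fel(rg, rmsd, n_bins = c(10, 10))
  b <- locate_minima(g)
  expect_equal(length(b), 2)
  expect_equal(b[[1]]$population_fraction, 0.7, tolerance = 1e-12)
  dG_expected <- -KB_KCAL * 300 * log(30 / 70)
  # schedule mode plants exact populations, so the gap is exact
  expect_equal(b[[2]]$G_min - b[[1]]$G_min, dG_expected, tolerance = 1e-9)

  # bernoulli mode: within 3 binomial standard errors (delta method)
  trb <- make_two_state_trajectory(ref, ref$xyz, ref$xyz * 1.3, p_a = 0.7,
                                   n_frames = 10000, jitter = 0.05, seed = 11,
                                   assignment = "bernoulli")
  gb <- compute_fel(rg_series(trb),
                    rmsd_series(trb, reference = ref$xyz, selection = "calpha"),
                    n_bins = c(10, 10))
  bb <- locate_minima(gb)
  expect_equal(length(bb), 2)
  se <- KB_KCAL * 300 * sqrt(0.3 / (1e4 * 0.7) + 0.7 / (1e4 * 0.3))
  expect_lt(abs((bb[[2]]$G_min - bb[[1]]$G_min) - dG_expected), 3 * se)

  # degenerate population (jitter-free): single basin
  tr1 <- make_two_state_trajectory(ref, ref$xyz, ref$xyz * 1.3, p_a = 1,
                                   n_frames = 200, jitter = 0, seed = 5)
  g1 <- compute_fel(rg_series(tr1),
                    rmsd_series(tr1, reference = ref$xyz, selection = "calpha"),
                    n_bins = c(10, 10))
  expect_equal(length(locate_minima(g1)), 1)
})

test_that("representative frames fall in the minimum bin with deterministic ties", {
  ref <- make_ca_chain(10)
  tr <- make_two_state_trajectory(ref, ref$xyz, ref$xyz * 1.3, p_a = 0.7,
                                  n_frames = 2000, jitter = 0.05, seed = 3)
  rg <- rg_series(tr)
  rmsd <- rmsd_series(tr, reference = ref$xyz, selection = "calpha")
  g <- compute_fel(rg, rmsd, n_bins = c(10, 10))
  b <- locate_minima(g)
  f <- representative_frame(g, b[[1]], rg, rmsd)
  expect_equal(g$x_bin[f], b[[1]]$minimum_bin[1])
  expect_equal(g$y_bin[f], b[[1]]$minimum_bin[2])
  expect_equal(attr(tr, "state")[f], "A")

  # explicit tie: frames symmetric about the bin centre -> lower index wins
  x <- c(1.0, 4.0, 5.0, 4.0)   # bin [3, 6], centre 4.5: frames 2-4 equidistant
  y <- rep(1, 4)
  gt <- compute_fel(x, y, n_bins = c(2, 2))
  bt <- locate_minima(gt)
  inbin <- which(gt$x_bin == bt[[1]]$minimum_bin[1] &
                 gt$y_bin == bt[[1]]$minimum_bin[2])
  expect_equal(representative_frame(gt, bt[[1]], x, y), inbin[1])
})

test_that("FEL CSV export is long-format with one row per bin", {
  g <- compute_fel(rnorm(100), rnorm(100), n_bins = c(6, 5))
  p <- tempfile(fileext = ".csv")
  write_fel_csv(g, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 30)
  expect_equal(sum(df$count), 100)
  expect_named(df, c("x_center", "y_center", "count", "G_kcal_mol", "empty"))
})
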