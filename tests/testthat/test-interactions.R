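# donor residue (N-H) facing an acceptor residue (C=O) at distance d, with
# the N-H...O angle controlled; a GLY spacer keeps the pair non-adjacent
hbond_pair <- function(d_on = 2.9, angle_dev = 0) {
  th <- angle_dev * pi / 180
  o <- c(1 + (d_on - 1) * cos(th), (d_on - 1) * sin(th), 0)
  Structure(
    name = c("N", "H", "CA", "CA", "C", "O"),
    resname = c("GLY", "GLY", "GLY", "GLY", "GLY", "GLY"),
    author_resid = c(1, 1, 1, 2, 3, 3),
    chain = "A",
    xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(0, -1.5, 0), c(50, 50, 50),
                o + c(1.23, 0, 0), o),
    element = c("N", "H", "C", "C", "C", "O"))
}

test_that("geometric criteria gate hydrogen-bond detection", {
  hb <- detect_hbonds(hbond_pair(2.9, 0))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  # too long
  expect_equal(nrow(detect_hbonds(hbond_pair(3.4, 0))), 0)
  # 60 degrees off linear with a 20-degree tolerance
  far_bent <- hbond_pair(2.9, 60)
  expect_equal(nrow(detect_hbonds(far_bent)), 0)
  # bent geometry accepted when the tolerance allows it
  expect_equal(nrow(detect_hbonds(far_bent, angle_cutoff = 90)), 1)
})

test_that("hydrogen-free topologies fall back to the distance criterion with a warning", {
  st <- hbond_pair(2.9, 0)
  keep <- st$atoms$name != "H"
  st2 <- Structure(name = st$atoms$name[keep], resname = st$atoms$resname[keep],
                   author_resid = st$atoms$author_resid[keep], chain = "A",
                   xyz = st$xyz[keep, ], element = st$atoms$element[keep])
  expect_warning(hb <- detect_hbonds(st2), "no hydrogens")
  expect_equal(nrow(hb), 1)   # unordered pair reported once
  expect_true(is.na(hb$angle))
})

test_that("planted schedules give exact occupancies and Bernoulli plants fall in the CI", {
  tr <- make_hbond_toy(0.30, n_frames = 100, mode = "schedule")
  tab <- hbond_occupancy(tr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$occupancy, 30.0)
  expect_equal(sum(attr(tr, "bonded")), 30)

  expect_equal(hbond_occupancy(make_hbond_toy(0.25, 200, "schedule"))$occupancy,
               25.0)
  none <- hbond_occupancy(make_hbond_toy(0, 50, "schedule"),
                          pairs = cbind(1, 2))
  expect_equal(none$occupancy, 0)

  f <- 0.1234
  n <- 10000
  tr2 <- make_hbond_toy(f, n, mode = "bernoulli", seed = 99)
  occ <- hbond_occupancy(tr2)$occupancy
  ci <- 100 * (f + c(-1, 1) * 1.96 * sqrt(f * (1 - f) / n))
  expect_gt(occ, ci[1]); expect_lt(occ, ci[2])
})

test_that("planted Bernoulli occupancy is recovered across 20 seeds", {
  f <- 0.30; n <- 400
  hits <- vapply(1:20, function(s) {
    occ <- hbond_occupancy(make_hbond_toy(f, n, "bernoulli", seed = s))$occupancy
    ci <- 100 * (f + c(-1, 1) * 1.96 * sqrt(f * (1 - f) / n))
    occ >= ci[1] && occ <= ci[2]
  }, logical(1))
  expect_gte(sum(hits), 18)   # ~95% coverage
})

test_that("stride subsampling agrees with full evaluation on stationary plants", {
  tr <- make_hbond_toy(0.4, n_frames = 400, mode = "schedule")
  full <- hbond_occupancy(tr)$occupancy
  strided <- hbond_occupancy(tr, stride = 4L)$occupancy
  expect_lt(abs(strided - full), 5)
})

test_that("typed contacts follow their distance rules", {
  # disulfide: CYS SG pair at 2.05 A, spacer keeps them non-adjacent
  ss <- Structure(name = c("SG", "CA", "SG"),
                  resname = c("CYS", "GLY", "CYS"),
                  author_resid = 1:3, chain = "A",
                  xyz = rbind(c(0, 0, 0), c(30, 0, 0), c(2.05, 0, 0)),
                  element = c("S", "C", "S"))
  ct <- detect_contacts(ss)
  expect_true("disulfide" %in% ct$type)
  # salt bridge: LYS NZ to ASP OD1 at 3.5 A
  sb <- Structure(name = c("NZ", "CA", "OD1"),
                  resname = c("LYS", "GLY", "ASP"),
                  author_resid = 1:3, chain = "A",
                  xyz = rbind(c(0, 0, 0), c(30, 0, 0), c(3.5, 0, 0)),
                  element = c("N", "C", "O"))
  expect_true("salt_bridge" %in% detect_contacts(sb)$type)
  # pi-pi: ring centroids at 7.5 A exceed the 6.5 A cutoff
  mk_rings <- function(sep) {
    Structure(
      name = c(rep("CG", 1), "CD1", "CD2", "CE1", "CE2", "CZ", "CA",
               "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      resname = c(rep("PHE", 6), "GLY", rep("PHE", 6)),
      author_resid = c(rep(1, 6), 2, rep(3, 6)), chain = "A",
      xyz = rbind(ring_coords(c(0, 0, 0)), c(60, 60, 60),
                  ring_coords(c(sep, 0, 0))),
      element = "C")
  }
  expect_false("pipi" %in% detect_contacts(mk_rings(7.5))$type)
  expect_true("pipi" %in% detect_contacts(mk_rings(5.0))$type)
  # vdW: heavy atoms within r_i + r_j + 0.5
  expect_true("vdw" %in% detect_contacts(Structure(
    name = c("CB", "CA", "CB"), resname = "ALA", author_resid = 1:3,
    chain = "A", xyz = rbind(c(0, 0, 0), c(30, 0, 0), c(3.8, 0, 0)),
    element = "C"))$type)
})

test_that("adjacent residues are excluded from contacts", {
  ss_adj <- Structure(name = c("SG", "SG"), resname = c("CYS", "CYS"),
                      author_resid = 1:2, chain = "A",
                      xyz = rbind(c(0, 0, 0), c(2.05, 0, 0)),
                      element = c("S", "S"))
  expect_equal(nrow(detect_contacts(ss_adj)), 0)
})

test_that("RIN edges respect the occupancy threshold and node set covers all residues", {
  tr <- make_hbond_toy(1.0, n_frames = 20, mode = "schedule")
  rin <- suppressWarnings(build_rin(tr, occupancy_threshold = 10))
  hb_edges <- rin$edges[rin$edges$type == "hbond", ]
  expect_equal(nrow(hb_edges), 1)
  expect_equal(hb_edges$weight, 100)
  expect_equal(igraph::vcount(rin$graph), n_residues(tr$topology))

  # 5% occupancy excluded at a 10% threshold
  tr5 <- make_hbond_toy(0.05, n_frames = 100, mode = "schedule")
  rin5 <- suppressWarnings(build_rin(tr5, occupancy_threshold = 10))
  expect_equal(nrow(rin5$edges[rin5$edges$type == "hbond", ]), 0)
})

test_that("single-frame RIN at threshold zero reproduces the per-frame detectors", {
  st <- make_toy_protein(10, "helix")
  tr <- Trajectory(st, list(st$xyz))
  rin <- build_rin(tr, occupancy_threshold = 0)
  hb <- detect_hbonds(st)
  ct <- detect_contacts(st)
  rt <- residue_table(st)
  hb_part <- if (nrow(hb) > 0) {
    data.frame(s = rt$label[pmin(hb$donor_res, hb$acceptor_res)],
               t = rt$label[pmax(hb$donor_res, hb$acceptor_res)],
               type = "hbond")
  } else {
    data.frame(s = character(0), t = character(0), type = character(0))
  }
  expected <- unique(rbind(
    hb_part,
    data.frame(s = ct$label_i, t = ct$label_j, type = ct$type)))
  got <- rin$edges[, c("source", "target", "type")]
  expect_equal(nrow(got), nrow(expected))
  key <- function(d) sort(paste(d[[1]], d[[2]], d[[3]]))
  expect_equal(key(got), key(expected))
})

test_that("RIN exports GraphML and edge CSV", {
  tr <- make_hbond_toy(0.5, n_frames = 10, mode = "schedule")
  rin <- suppressWarnings(build_rin(tr, occupancy_threshold = 10))
  gml <- tempfile(fileext = ".graphml"); csv <- tempfile(fileext = ".csv")
  write_rin(rin, gml, csv)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(rin$graph))
  df <- read.csv(csv)
  expect_named(df, c("source", "target", "type", "weight"))
})
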