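# Residue-template atom groups used for typed contacts
.charged_pos <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.charged_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.aromatic_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# warn once (per call site) when a topology carries no hydrogens
.warn_if_no_h <- function(structure) {
  if (!any(structure$atoms$element == "H")) {
    warning("topology has no hydrogens; H-bond angle test skipped ",
            "(distance-only criterion)", call. = FALSE)
  }
}

# global residue id (row of residue_table) per atom
.atom_resid_global <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resindex)
  match(key, unique(key))
}

#' Detect hydrogen bonds in a single frame (geometric criterion)
#'
#' Donors are N/O atoms carrying a hydrogen (a hydrogen within 1.25 Angstrom
#' in the frame); acceptors are N/O atoms. A bond is reported iff the
#' donor-acceptor distance is at most \code{dist_cutoff} and, when the
#' hydrogen is present, the D-H...A angle deviates from linearity by at most
#' \code{angle_cutoff} degrees. Topologies without any hydrogens fall back
#' to the distance-only criterion with a warning. Intra-residue pairs are
#' excluded.
#'
#' @param structure a \code{\link{Structure}}.
#' @param frame coordinates (default \code{structure$xyz}).
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom (default 3.0).
#' @param angle_cutoff allowed deviation from linearity, degrees (default 20).
#' @return data.frame with columns \code{donor}, \code{hydrogen} (NA when
#'   absent), \code{acceptor} (atom indices), \code{distance},
#'   \code{angle} (D-H...A, degrees; NA when no hydrogen),
#'   \code{donor_res}, \code{acceptor_res} (global residue ids),
#'   \code{donor_label}, \code{acceptor_label}.
#' @export
detect_hbonds <- function(structure, frame = NULL, dist_cutoff = 3.0,
                          angle_cutoff = 20) {
  if (is.null(frame)) frame <- structure$xyz
  frame <- as.matrix(frame)
  a <- structure$atoms
  rg <- .atom_resid_global(structure)
  rt <- residue_table(structure)
  is_h <- a$element == "H"
  no_cols <- which(a$element %in% c("N", "O"))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0), donor_res = integer(0),
                      acceptor_res = integer(0), donor_label = character(0),
                      acceptor_label = character(0))
  if (length(no_cols) < 2L) return(empty)

  have_h <- any(is_h)
  if (!have_h) {
    warning("topology has no hydrogens; H-bond angle test skipped ",
            "(distance-only criterion)", call. = FALSE)
  }
  # attached hydrogen per candidate donor: nearest H within 1.25 A
  h_of <- rep(NA_integer_, length(no_cols))
  if (have_h) {
    h_idx <- which(is_h)
    for (k in seq_along(no_cols)) {
      d2 <- rowSums(sweep(frame[h_idx, , drop = FALSE], 2,
                          frame[no_cols[k], ])^2)
      j <- which.min(d2)
      if (d2[j] <= 1.25^2) h_of[k] <- h_idx[j]
    }
  }
  donors <- if (have_h) no_cols[!is.na(h_of)] else no_cols
  donor_h <- if (have_h) h_of[!is.na(h_of)] else rep(NA_integer_, length(no_cols))

  out <- list()
  for (k in seq_along(donors)) {
    d <- donors[k]
    acc <- no_cols[rg[no_cols] != rg[d]]
    if (length(acc) == 0L) next
    dist <- sqrt(rowSums(sweep(frame[acc, , drop = FALSE], 2, frame[d, ])^2))
    ok <- dist <= dist_cutoff
    if (!any(ok)) next
    acc <- acc[ok]; dist <- dist[ok]
    ang <- rep(NA_real_, length(acc))
    if (!is.na(donor_h[k])) {
      h <- donor_h[k]
      v1 <- frame[d, ] - frame[h, ]
      for (m in seq_along(acc)) {
        v2 <- frame[acc[m], ] - frame[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang[m] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
      keep <- (180 - ang) <= angle_cutoff
      acc <- acc[keep]; dist <- dist[keep]; ang <- ang[keep]
    }
    if (length(acc) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      donor = d, hydrogen = donor_h[k], acceptor = acc, distance = dist,
      angle = ang, donor_res = rg[d], acceptor_res = rg[acc],
      donor_label = rt$label[rg[d]], acceptor_label = rt$label[rg[acc]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  if (!have_h) {
    # without hydrogens the donor/acceptor roles are arbitrary: report each
    # unordered residue pair once (lower residue id as the nominal donor)
    res <- res[res$donor_res < res$acceptor_res, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' occupancy(pair) = 100 x (frames in which at least one H-bond links the
#' donor residue's donors to the acceptor residue's acceptors) / frames
#' examined. Direction (donor -> acceptor) is kept in the labelling.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param pairs optional 2-column matrix/data.frame of (donor, acceptor)
#'   author residue numbers restricting the table; \code{NULL} reports every
#'   pair ever bonded.
#' @param stride evaluate every \code{stride}-th frame.
#' @param dist_cutoff,angle_cutoff see \code{\link{detect_hbonds}}.
#' @return data.frame (class \code{"OccupancyTable"}) with columns
#'   \code{donor_label}, \code{acceptor_label}, \code{donor_resid},
#'   \code{acceptor_resid}, \code{occupancy} (percent), \code{n_frames}.
#' @export
hbond_occupancy <- function(traj, pairs = NULL, stride = 1L,
                            dist_cutoff = 3.0, angle_cutoff = 20) {
  frames <- seq(1L, n_frames(traj), by = stride)
  rt <- residue_table(traj$topology)
  seen <- new.env(parent = emptyenv())
  .warn_if_no_h(traj$topology)
  for (t in frames) {
    hb <- suppressWarnings(detect_hbonds(traj$topology, get_frame(traj, t),
                                         dist_cutoff, angle_cutoff))
    if (nrow(hb) == 0L) next
    pk <- unique(paste(hb$donor_res, hb$acceptor_res, sep = ">"))
    for (p in pk) {
      seen[[p]] <- if (is.null(seen[[p]])) 1L else seen[[p]] + 1L
    }
  }
  keys <- ls(seen)
  nF <- length(frames)
  if (length(keys) == 0L) {
    tab <- data.frame(donor_label = character(0), acceptor_label = character(0),
                      donor_resid = integer(0), acceptor_resid = integer(0),
                      occupancy = numeric(0), n_frames = integer(0))
  } else {
    dr <- as.integer(sub(">.*", "", keys))
    ar <- as.integer(sub(".*>", "", keys))
    cnt <- vapply(keys, function(p) seen[[p]], integer(1))
    tab <- data.frame(donor_label = rt$label[dr], acceptor_label = rt$label[ar],
                      donor_resid = rt$author_resid[dr],
                      acceptor_resid = rt$author_resid[ar],
                      occupancy = 100 * cnt / nF, n_frames = nF,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    want <- paste(pairs[, 1], pairs[, 2])
    miss <- setdiff(want, paste(tab$donor_resid, tab$acceptor_resid))
    if (length(miss) > 0L) {
      ms <- do.call(rbind, strsplit(miss, " "))
      dr <- match(as.integer(ms[, 1]), rt$author_resid)
      ar <- match(as.integer(ms[, 2]), rt$author_resid)
      tab <- rbind(tab, data.frame(
        donor_label = rt$label[dr], acceptor_label = rt$label[ar],
        donor_resid = as.integer(ms[, 1]), acceptor_resid = as.integer(ms[, 2]),
        occupancy = 0, n_frames = nF, stringsAsFactors = FALSE))
    }
    tab <- tab[paste(tab$donor_resid, tab$acceptor_resid) %in% want, ,
               drop = FALSE]
  }
  tab <- tab[order(-tab$occupancy, tab$donor_resid, tab$acceptor_resid), ,
             drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("OccupancyTable", "data.frame")
  tab
}

#' Detect typed non-covalent residue contacts in a single frame
#'
#' Rules (all cutoffs configurable):
#' \itemize{
#'   \item \code{vdw}: any heavy-atom pair at distance <= r_i + r_j + slack
#'     between residues at least 2 apart in sequence (or on different chains);
#'   \item \code{salt_bridge}: opposite-charge N/O pair (Arg/Lys/His side
#'     chain N vs Asp/Glu side chain O) <= 4.0 Angstrom;
#'   \item \code{pipi}: aromatic ring centroids (Phe/Tyr/Trp/His) <= 6.5;
#'   \item \code{disulfide}: Cys SG-SG <= 2.5.
#' }
#'
#' @param structure a \code{\link{Structure}}.
#' @param frame coordinates (default \code{structure$xyz}).
#' @param vdw_slack vdW contact slack, Angstrom (default 0.5).
#' @param salt_cutoff,pipi_cutoff,ss_cutoff distance cutoffs, Angstrom.
#' @return data.frame with \code{res_i}, \code{res_j} (global residue ids,
#'   i < j), \code{label_i}, \code{label_j}, \code{type}.
#' @export
detect_contacts <- function(structure, frame = NULL, vdw_slack = 0.5,
                            salt_cutoff = 4.0, pipi_cutoff = 6.5,
                            ss_cutoff = 2.5) {
  if (is.null(frame)) frame <- structure$xyz
  frame <- as.matrix(frame)
  a <- structure$atoms
  rg <- .atom_resid_global(structure)
  rt <- residue_table(structure)

  # residues "adjacent" when on the same chain and within 1 sequence position
  nonadjacent <- function(r1, r2) {
    same <- rt$chain[r1] == rt$chain[r2]
    !(same & abs(rt$resindex[r1] - rt$resindex[r2]) < 2L)
  }
  res <- list()
  add <- function(r1, r2, type) {
    sw <- r1 > r2
    tmp <- r1[sw]; r1[sw] <- r2[sw]; r2[sw] <- tmp
    res[[length(res) + 1L]] <<- data.frame(
      res_i = r1, res_j = r2, label_i = rt$label[r1], label_j = rt$label[r2],
      type = type, stringsAsFactors = FALSE)
  }

  # vdW contacts over heavy atoms
  heavy <- which(a$element != "H")
  if (length(heavy) >= 2L) {
    d <- as.matrix(stats::dist(frame[heavy, , drop = FALSE]))
    cut <- outer(a$vdw_radius[heavy], a$vdw_radius[heavy], "+") + vdw_slack
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      r1 <- rg[heavy[hit[, 1]]]; r2 <- rg[heavy[hit[, 2]]]
      ok <- r1 != r2 & nonadjacent(r1, r2)
      if (any(ok)) {
        pr <- unique(data.frame(r1 = pmin(r1[ok], r2[ok]),
                                r2 = pmax(r1[ok], r2[ok])))
        add(pr$r1, pr$r2, "vdw")
      }
    }
  }

  pair_by_dist <- function(idx1, idx2, cutoff, type) {
    if (length(idx1) == 0L || length(idx2) == 0L) return()
    for (i in idx1) {
      d <- sqrt(rowSums(sweep(frame[idx2, , drop = FALSE], 2, frame[i, ])^2))
      hit <- idx2[d <= cutoff]
      r1 <- rg[rep(i, length(hit))]; r2 <- rg[hit]
      ok <- r1 != r2 & nonadjacent(r1, r2)
      if (any(ok)) add(r1[ok], r2[ok], type)
    }
  }

  grp_atoms <- function(tpl) {
    which(mapply(function(rn, an) {
      !is.null(tpl[[rn]]) && an %in% tpl[[rn]]
    }, a$resname, a$name))
  }
  pair_by_dist(grp_atoms(.charged_pos), grp_atoms(.charged_neg),
               salt_cutoff, "salt_bridge")
  sg <- which(a$resname == "CYS" & a$name == "SG")
  pair_by_dist(sg, sg, ss_cutoff, "disulfide")

  # pi-pi: ring centroids
  ring_res <- which(rt$resname %in% names(.aromatic_rings))
  if (length(ring_res) >= 2L) {
    cents <- t(vapply(ring_res, function(r) {
      at <- which(rg == r & a$name %in% .aromatic_rings[[rt$resname[r]]])
      if (length(at) < 3L) return(c(NA_real_, NA_real_, NA_real_))
      colMeans(frame[at, , drop = FALSE])
    }, numeric(3)))
    okc <- !is.na(cents[, 1])
    ring_res <- ring_res[okc]; cents <- cents[okc, , drop = FALSE]
    if (length(ring_res) >= 2L) {
      dc <- as.matrix(stats::dist(cents))
      hit <- which(dc <= pipi_cutoff & upper.tri(dc), arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        r1 <- ring_res[hit[, 1]]; r2 <- ring_res[hit[, 2]]
        ok <- nonadjacent(r1, r2)
        if (any(ok)) add(r1[ok], r2[ok], "pipi")
      }
    }
  }

  if (length(res) == 0L) {
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      label_i = character(0), label_j = character(0),
                      type = character(0)))
  }
  out <- unique(do.call(rbind, res))
  out <- out[order(out$res_i, out$res_j, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an occupancy-weighted residue interaction network
#'
#' H-bonds and typed contacts are evaluated on strided frames; an edge
#' (residue pair, type) is kept iff its occupancy (percent of examined
#' frames) reaches \code{occupancy_threshold}, and is weighted by that
#' occupancy. Every residue is a node regardless of degree. The default
#' stride is chosen so that at most \code{max_frames} frames are analysed,
#' echoing ensemble-network protocols built on ~1000 trajectory snapshots.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param occupancy_threshold minimum edge occupancy, percent (default 10).
#' @param stride frame stride; \code{NULL} picks the smallest stride giving
#'   <= \code{max_frames} frames.
#' @param max_frames frame budget used when \code{stride} is \code{NULL}.
#' @param dist_cutoff,angle_cutoff H-bond criteria.
#' @param ... further cutoffs passed to \code{\link{detect_contacts}}.
#' @return object of class \code{"RINGraph"}: list with \code{graph} (an
#'   igraph object; vertices labelled CHAIN:RESNAME:AUTHORNUM), \code{edges}
#'   (data.frame source, target, type, weight), \code{n_frames_used},
#'   \code{params}.
#' @export
build_rin <- function(traj, occupancy_threshold = 10, stride = NULL,
                      max_frames = 1000L, dist_cutoff = 3.0,
                      angle_cutoff = 20, ...) {
  nf <- n_frames(traj)
  if (is.null(stride)) stride <- max(1L, ceiling(nf / max_frames))
  frames <- seq(1L, nf, by = stride)
  rt <- residue_table(traj$topology)
  counts <- new.env(parent = emptyenv())
  .warn_if_no_h(traj$topology)
  for (t in frames) {
    fr <- get_frame(traj, t)
    hb <- suppressWarnings(detect_hbonds(traj$topology, fr,
                                         dist_cutoff, angle_cutoff))
    keys <- character(0)
    if (nrow(hb) > 0L) {
      keys <- paste(pmin(hb$donor_res, hb$acceptor_res),
                    pmax(hb$donor_res, hb$acceptor_res), "hbond", sep = "|")
    }
    ct <- detect_contacts(traj$topology, fr, ...)
    if (nrow(ct) > 0L) {
      keys <- c(keys, paste(ct$res_i, ct$res_j, ct$type, sep = "|"))
    }
    for (k in unique(keys)) {
      counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
    }
  }
  keys <- ls(counts)
  nF <- length(frames)
  edges <- data.frame(source = character(0), target = character(0),
                      type = character(0), weight = numeric(0))
  if (length(keys) > 0L) {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    occ <- 100 * vapply(keys, function(k) counts[[k]], integer(1)) / nF
    keep <- occ >= occupancy_threshold
    if (any(keep)) {
      edges <- data.frame(
        source = rt$label[as.integer(parts[keep, 1])],
        target = rt$label[as.integer(parts[keep, 2])],
        type = parts[keep, 3], weight = occ[keep],
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$source, edges$target, edges$type), ,
                     drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rt$label, chain = rt$chain,
                          resname = rt$resname,
                          author_resid = rt$author_resid))
  structure(list(graph = g, edges = edges, n_frames_used = nF,
                 params = list(occupancy_threshold = occupancy_threshold,
                               stride = stride, dist_cutoff = dist_cutoff,
                               angle_cutoff = angle_cutoff)),
            class = "RINGraph")
}

#' @export
print.RINGraph <- function(x, ...) {
  cat("RINGraph:", igraph::vcount(x$graph), "residues,",
      nrow(x$edges), "edges from", x$n_frames_used, "frames\n")
  invisible(x)
}

#' Export a residue interaction network
#'
#' @param rin a \code{RINGraph}.
#' @param graphml_path optional GraphML output path.
#' @param csv_path optional edge-list CSV path (source, target, type, weight).
#' @return invisibly, \code{rin}.
#' @export
write_rin <- function(rin, graphml_path = NULL, csv_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(rin$graph, graphml_path, format = "graphml")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(rin$edges, csv_path, row.names = FALSE)
  }
  invisible(rin)
}
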