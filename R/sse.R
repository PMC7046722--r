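#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model for a backbone N-H...O=C hydrogen bond:
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol,
#' with the bond called at E < -0.5 kcal/mol.
#'
#' @param n,h donor backbone N and amide H coordinates (length-3).
#' @param c,o acceptor backbone carbonyl C and O coordinates (length-3).
#' @return energy in kcal/mol.
#' @export
kabsch_sander_energy <- function(n, h, c, o) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * 332 * (1 / r(o, n) + 1 / r(c, h) - 1 / r(o, h) - 1 / r(c, n))
}

.KS_CUTOFF <- -0.5

# per-residue backbone atom coordinates; amide H taken from the topology
# when present, otherwise constructed 1.0 A from N anti to the preceding
# residue's carbonyl O direction. First residue and prolines have no donor.
.backbone_coords <- function(structure, frame) {
  a <- structure$atoms
  rg <- .atom_resid_global(structure)
  rt <- residue_table(structure)
  nres <- nrow(rt)
  get1 <- function(r, nm) {
    k <- which(rg == r & a$name == nm)
    if (length(k) == 0L) return(NULL)
    frame[k[1], ]
  }
  bb <- vector("list", nres)
  for (r in seq_len(nres)) {
    bb[[r]] <- list(N = get1(r, "N"), CA = get1(r, "CA"),
                    C = get1(r, "C"), O = get1(r, "O"),
                    H = {
                      h <- get1(r, "H")
                      if (is.null(h)) h <- get1(r, "HN")
                      h
                    })
  }
  for (r in seq_len(nres)) {
    if (rt$resname[r] == "PRO") { bb[[r]]$H <- NULL; next }
    if (!is.null(bb[[r]]$H) || is.null(bb[[r]]$N)) next
    if (r > 1L && rt$chain[r] == rt$chain[r - 1L] &&
        !is.null(bb[[r - 1L]]$O)) {
      v <- bb[[r]]$N - bb[[r - 1L]]$O
      bb[[r]]$H <- bb[[r]]$N + v / sqrt(sum(v^2))
    }
  }
  list(bb = bb, rt = rt)
}

# n_res x n_res logical matrix: [d, a] TRUE iff residue d's N-H donates a
# Kabsch-Sander bond to residue a's C=O; same residue and sequence
# neighbours (|d - a| < 2 on one chain) are excluded by definition
.ks_hbond_matrix <- function(structure, frame) {
  bc <- .backbone_coords(structure, frame)
  bb <- bc$bb; rt <- bc$rt
  nres <- length(bb)
  hb <- matrix(FALSE, nres, nres)
  for (d in seq_len(nres)) {
    dn <- bb[[d]]
    if (is.null(dn$N) || is.null(dn$H)) next
    for (ac in seq_len(nres)) {
      if (d == ac) next
      if (rt$chain[d] == rt$chain[ac] &&
          abs(rt$resindex[d] - rt$resindex[ac]) < 2L) next
      an <- bb[[ac]]
      if (is.null(an$C) || is.null(an$O)) next
      # cheap distance screen before the 4-term energy
      if (sum((dn$N - an$O)^2) > 25) next
      e <- kabsch_sander_energy(dn$N, dn$H, an$C, an$O)
      hb[d, ac] <- e < .KS_CUTOFF
    }
  }
  hb
}

#' Assign 3-class secondary structure to one frame
#'
#' DSSP-style rules reduced to three classes: a residue is \code{H} when it
#' lies inside two consecutive i -> i+4 Kabsch-Sander turns (3-10 and pi
#' turns, i -> i+3 / i -> i+5, are folded in only when flanking an i -> i+4
#' helix); \code{E} when it takes part in a parallel or antiparallel bridge
#' (ladder patterns over the backbone H-bond matrix); otherwise \code{C}.
#' Helix takes precedence over strand.
#'
#' @param structure a \code{\link{Structure}} with backbone N, CA, C, O.
#' @param frame coordinates (default \code{structure$xyz}).
#' @return character vector of labels in \{H, E, C\}, one per residue.
#' @export
assign_sse <- function(structure, frame = NULL) {
  if (is.null(frame)) frame <- structure$xyz
  frame <- as.matrix(frame)
  rt <- residue_table(structure)
  nres <- nrow(rt)
  lab <- rep("C", nres)
  if (nres < 5L) return(lab)
  hb <- .ks_hbond_matrix(structure, frame)
  same_chain <- function(i, j) rt$chain[i] == rt$chain[j]

  turn <- function(sep) {
    v <- rep(FALSE, nres)
    for (i in seq_len(nres - sep)) {
      v[i] <- hb[i + sep, i] && same_chain(i, i + sep)
    }
    v
  }
  t4 <- turn(4L)
  helix <- rep(FALSE, nres)
  for (i in seq_len(max(0L, nres - 5L))) {
    if (t4[i] && t4[i + 1L]) helix[(i + 1L):(i + 4L)] <- TRUE
  }
  # relaxed 3-10 / pi patterns only extend an existing i -> i+4 helix
  for (sep in c(3L, 5L)) {
    ts <- turn(sep)
    for (i in seq_len(max(0L, nres - sep - 1L))) {
      if (ts[i] && ts[i + 1L]) {
        span <- (i + 1L):(i + sep)
        if (any(helix[max(1L, i - 1L):min(nres, i + sep + 1L)])) {
          helix[span] <- TRUE
        }
      }
    }
  }

  strand <- rep(FALSE, nres)
  H <- function(d, a) d >= 1L && d <= nres && a >= 1L && a <= nres && hb[d, a]
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (abs(i - j) <= 2L && same_chain(i, j)) next
      anti <- (H(i, j) && H(j, i)) || (H(i - 1L, j + 1L) && H(j - 1L, i + 1L))
      para <- (H(i - 1L, j) && H(j, i + 1L)) || (H(j - 1L, i) && H(i, j + 1L))
      if (anti || para) strand[i] <- TRUE
    }
  }
  lab[strand] <- "E"
  lab[helix] <- "H"
  lab
}

#' Secondary-structure statistics over a trajectory
#'
#' @param traj a \code{\link{Trajectory}}.
#' @return object of class \code{"SSETimeline"}: \code{labels} (n_frames x
#'   n_residues character matrix), per-residue \code{helix_pct} and
#'   \code{strand_pct} (\code{\link{ProfileResult}}s), and global
#'   \code{helix_pct_total}, \code{strand_pct_total}, \code{total_sse_pct}.
#' @export
sse_statistics <- function(traj) {
  nf <- n_frames(traj)
  rt <- residue_table(traj$topology)
  labs <- matrix("C", nf, nrow(rt))
  for (t in seq_len(nf)) {
    labs[t, ] <- assign_sse(traj$topology, get_frame(traj, t))
  }
  hp <- 100 * colMeans(labs == "H")
  ep <- 100 * colMeans(labs == "E")
  structure(list(
    labels = labs,
    helix_pct = ProfileResult(hp, rt$author_resid, "helix_pct", "%",
                              labels = rt$label),
    strand_pct = ProfileResult(ep, rt$author_resid, "strand_pct", "%",
                               labels = rt$label),
    helix_pct_total = mean(labs == "H") * 100,
    strand_pct_total = mean(labs == "E") * 100,
    total_sse_pct = mean(labs %in% c("H", "E")) * 100
  ), class = "SSETimeline")
}

#' @export
print.SSETimeline <- function(x, ...) {
  cat(sprintf("SSETimeline: %d frames x %d residues; helix %.1f%%, strand %.1f%%, total SSE %.1f%%\n",
              nrow(x$labels), ncol(x$labels), x$helix_pct_total,
              x$strand_pct_total, x$total_sse_pct))
  invisible(x)
}

#' Write an SSE timeline as CSV plus a JSON percentage summary
#'
#' @param sse a \code{SSETimeline}.
#' @param csv_path frame x residue label matrix CSV (optional).
#' @param json_path percentage summary JSON (optional).
#' @return invisibly, \code{sse}.
#' @export
write_sse <- function(sse, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- as.data.frame(sse$labels)
    names(df) <- sse$helix_pct$labels
    df <- cbind(frame = seq_len(nrow(df)), df)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      helix_pct_total = sse$helix_pct_total,
      strand_pct_total = sse$strand_pct_total,
      total_sse_pct = sse$total_sse_pct,
      per_residue = data.frame(residue = sse$helix_pct$labels,
                               helix_pct = sse$helix_pct$values,
                               strand_pct = sse$strand_pct$values)
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(sse)
}
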