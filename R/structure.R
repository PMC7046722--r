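#' Construct a Structure object
#'
#' A \code{Structure} holds an ordered atom table plus reference coordinates
#' in Angstrom. Residues carry a dual numbering: \code{resindex} is the
#' 1-based sequence position within a chain, \code{author_resid} is the
#' author (PDB) residue number. For the TREM2 ectodomain the two differ by a
#' constant offset of +20, which is why user-facing labels always use author
#' numbering.
#'
#' @param name character vector of atom names (PDB convention, e.g. "CA").
#' @param resname 3-letter residue names.
#' @param author_resid author/PDB residue numbers (integer).
#' @param chain chain identifiers (single characters).
#' @param xyz n_atoms x 3 numeric matrix of coordinates, Angstrom.
#' @param element element symbols; inferred from \code{name} where \code{NA}.
#' @param serial atom serial numbers; defaults to 1..n.
#' @return object of class \code{"Structure"}: a list with an \code{atoms}
#'   data.frame (serial, name, element, resindex, author_resid, resname,
#'   chain, mass, vdw_radius), an \code{xyz} coordinate matrix, and a
#'   per-chain \code{offset} (author numbering minus sequence index; \code{NA}
#'   when the chain has gaps or insertions that break a constant offset).
#' @export
Structure <- function(name, resname, author_resid, chain, xyz,
                      element = NA_character_, serial = NULL) {
  n <- length(name)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(serial)) serial <- seq_len(n)
  chain <- as.character(chain)
  element <- rep_len(as.character(element), n)
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- vapply(name[miss], infer_element, character(1))
  element <- toupper(element)

  # residue bookkeeping: a new residue starts whenever (chain, author_resid,
  # resname) changes along the file order
  key <- paste(chain, author_resid, resname, sep = "|")
  new_res <- c(TRUE, key[-1] != key[-n])
  res_id <- cumsum(new_res)
  resindex <- integer(n)
  for (ch in unique(chain)) {
    sel <- chain == ch
    resindex[sel] <- match(res_id[sel], unique(res_id[sel]))
  }

  props <- .element_props(element)
  atoms <- data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = element, resindex = resindex,
    author_resid = as.integer(author_resid), resname = as.character(resname),
    chain = chain, mass = props$mass, vdw_radius = props$vdw_radius,
    stringsAsFactors = FALSE
  )

  offset <- vapply(unique(chain), function(ch) {
    a <- atoms[atoms$chain == ch, ]
    d <- unique(a$author_resid - a$resindex)
    if (length(d) == 1L) as.numeric(d) else NA_real_
  }, numeric(1))

  structure(list(atoms = atoms, xyz = unname(xyz), offset = offset),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,", n_residues(x), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure a \code{Structure}.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Number of residues in a Structure
#' @param structure a \code{Structure}.
#' @return integer residue count.
#' @export
n_residues <- function(structure) nrow(residue_table(structure))

#' Residue table of a Structure
#'
#' @param structure a \code{Structure}.
#' @return data.frame with one row per residue: \code{resindex},
#'   \code{author_resid}, \code{resname}, \code{chain}, and a display
#'   \code{label} of the form \code{CHAIN:RESNAME:AUTHORNUM}.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  first <- !duplicated(paste(a$chain, a$resindex))
  r <- a[first, c("resindex", "author_resid", "resname", "chain")]
  rownames(r) <- NULL
  r$label <- sprintf("%s:%s:%d", r$chain, r$resname, r$author_resid)
  r
}

#' Construct a Trajectory object
#'
#' @param topology a \code{Structure} providing atom metadata.
#' @param coords numeric array of dimension (n_frames, n_atoms, 3), Angstrom,
#'   or a list of n_atoms x 3 matrices.
#' @param times optional per-frame times (ns), strictly increasing.
#' @return object of class \code{"Trajectory"}.
#' @export
Trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "Structure"))
  if (is.list(coords)) {
    nf <- length(coords)
    arr <- array(0, dim = c(nf, nrow(coords[[1]]), 3))
    for (t in seq_len(nf)) arr[t, , ] <- coords[[t]]
    coords <- arr
  }
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L) stop("coords must be n_frames x n_atoms x 3")
  if (d[2] != n_atoms(topology)) stop("topology mismatch: trajectory has ",
                                      d[2], " atoms, topology has ", n_atoms(topology))
  if (d[1] < 1L) stop("trajectory has zero frames")
  if (!is.null(times)) {
    stopifnot(length(times) == d[1])
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = times),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", n_atoms(x$topology), "atoms\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a \code{Trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a Trajectory as a coordinate matrix
#' @param traj a \code{Trajectory}.
#' @param t frame number (1-based).
#' @return n_atoms x 3 matrix, Angstrom.
#' @export
get_frame <- function(traj, t) {
  stopifnot(t >= 1, t <= n_frames(traj))
  matrix(traj$coords[t, , ], ncol = 3)
}

# ---- readers / writers (PDB and DCD dialects go through bio3d) ----

.structure_from_bio3d <- function(pdb, include_hetero = FALSE,
                                  include_water = FALSE) {
  a <- pdb$atom
  water <- a$resid %in% c("HOH", "WAT", "TIP3", "SOL", "DOD")
  keep <- rep(TRUE, nrow(a))
  if (!include_water) keep <- keep & !water
  if (!include_hetero) keep <- keep & (a$type == "ATOM" | (include_water & water))
  if (!any(keep)) stop("empty structure: no atoms left after filtering")
  a <- a[keep, , drop = FALSE]
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  elesy[!is.na(elesy) & trimws(elesy) == ""] <- NA_character_
  ch <- a$chain
  ch[is.na(ch)] <- "A"
  st <- Structure(
    name = trimws(a$elety), resname = trimws(a$resid),
    author_resid = a$resno, chain = ch,
    xyz = cbind(a$x, a$y, a$z),
    element = trimws(ifelse(is.na(elesy), NA_character_, elesy)),
    serial = a$eleno
  )
  list(structure = st, keep = keep)
}

#' Read a PDB file into a Structure
#'
#' Waters and hetero groups are excluded by default; elements come from PDB
#' columns 77-78 when present and are otherwise inferred from the atom name.
#' Only the first model of a multi-model file is used (see
#' \code{\link{read_trajectory}} for the ensemble).
#'
#' @param path PDB file path.
#' @param include_hetero include non-water HETATM records.
#' @param include_water include water molecules.
#' @return a \code{\link{Structure}}.
#' @export
read_pdb <- function(path, include_hetero = FALSE, include_water = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  .structure_from_bio3d(pdb, include_hetero, include_water)$structure
}

#' Read a trajectory (multi-model PDB or DCD)
#'
#' @param path trajectory file; format chosen by extension (\code{.dcd} for
#'   X-PLOR/CHARMM-style DCD in Angstrom, anything else treated as
#'   multi-model PDB).
#' @param topology a \code{Structure}; every frame must match its atom count.
#'   For multi-model PDB, \code{NULL} reads the topology from the file itself.
#' @param stride keep every \code{stride}-th frame, starting at the first.
#' @return a \code{\link{Trajectory}}.
#' @export
read_trajectory <- function(path, topology = NULL, stride = 1L) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  stopifnot(stride >= 1L)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology)) stop("DCD trajectories need an explicit topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- matrix(xyz, nrow = nrow(xyz))
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    parsed <- .structure_from_bio3d(pdb)
    if (is.null(topology)) topology <- parsed$structure
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    # apply the same atom filter to every model's coordinates
    keep3 <- as.vector(rbind(parsed$keep, parsed$keep, parsed$keep))
    xyz <- xyz[, keep3, drop = FALSE]
  }
  na <- ncol(xyz) / 3
  if (na != n_atoms(topology)) {
    stop("topology mismatch: trajectory frames have ", na,
         " atoms, topology has ", n_atoms(topology))
  }
  idx <- seq(1L, nrow(xyz), by = stride)
  nf <- length(idx)
  if (nf == 0L) stop("trajectory has zero frames")
  coords <- array(0, dim = c(nf, na, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- matrix(xyz[idx[t], ], ncol = 3, byrow = TRUE)
  }
  Trajectory(topology, coords)
}

#' Write a Structure (optionally with replacement coordinates) as PDB
#'
#' Author residue numbers, chain identifiers, atom names and elements are
#' preserved; coordinates round-trip at PDB precision (0.001 Angstrom).
#'
#' @param structure a \code{Structure}.
#' @param path output file.
#' @param frame optional n_atoms x 3 coordinate matrix replacing
#'   \code{structure$xyz}.
#' @return invisibly, \code{path}.
#' @export
write_structure <- function(structure, path, frame = NULL) {
  if (is.null(frame)) frame <- structure$xyz
  frame <- as.matrix(frame)
  if (nrow(frame) != n_atoms(structure)) {
    stop("frame has ", nrow(frame), " atoms but structure has ",
         n_atoms(structure))
  }
  a <- structure$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(frame)),
                   resno = a$author_resid, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Write a Trajectory as a multi-model PDB
#'
#' @param traj a \code{Trajectory}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  nf <- n_frames(traj)
  xyz <- matrix(0, nrow = nf, ncol = n_atoms(traj$topology) * 3)
  for (t in seq_len(nf)) xyz[t, ] <- as.vector(t(get_frame(traj, t)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$author_resid, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}
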