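# Fixtures are built in code at test time; nothing binary ships with the
# package.

# write a minimal PDB text file and return its path
write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = "", record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resid, x, y, z, 1.0, 0.0,
          element)
}

# two-residue dipeptide fixture with author numbering offset +20
# (sequence positions 1,2 = author residues 21,22)
tiny_pdb <- function() {
  write_pdb_text(c(
    pdb_atom_line(1, "N",  "ALA", "A", 21, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 21, 1.458, 0.0, 0.0, "C"),
    pdb_atom_line(3, "C",  "ALA", "A", 21, 2.0, 1.4, 0.0, "C"),
    pdb_atom_line(4, "N",  "GLY", "A", 22, 3.3, 1.5, 0.0, "N"),
    pdb_atom_line(5, "CA", "GLY", "A", 22, 4.2, 2.6, 0.0, "C"),
    "END"))
}

# multi-model PDB trajectory of a 2-atom system, frame t shifted by t-1 in x
multi_model_pdb <- function(n_models = 10) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines,
               sprintf("MODEL     %4d", m),
               pdb_atom_line(1, "CA", "ALA", "A", 1, (m - 1) * 1.0, 0, 0, "C"),
               pdb_atom_line(2, "CA", "ALA", "A", 2, (m - 1) * 1.0 + 3.8, 0, 0, "C"),
               "ENDMDL")
  }
  write_pdb_text(c(lines, "END"))
}

# minimal CHARMM-style DCD writer (little-endian, no fixed atoms, no cell)
write_dcd_fixture <- function(coords_list, path = tempfile(fileext = ".dcd")) {
  con <- file(path, "wb")
  on.exit(close(con))
  natom <- nrow(coords_list[[1]])
  nframe <- length(coords_list)
  icntrl <- integer(20)
  icntrl[1] <- nframe; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nframe
  icntrl[8] <- 3L * natom; icntrl[20] <- 24L
  writeBin(84L, con, endian = "little")
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, endian = "little")
  writeBin(84L, con, endian = "little")
  title <- sprintf("%-80s", "test fixture")
  writeBin(c(4L + 80L), con, endian = "little")
  writeBin(1L, con, endian = "little")
  writeBin(charToRaw(title), con)
  writeBin(c(4L + 80L), con, endian = "little")
  writeBin(4L, con, endian = "little")
  writeBin(as.integer(natom), con, endian = "little")
  writeBin(4L, con, endian = "little")
  for (fr in coords_list) {
    for (ax in 1:3) {
      writeBin(as.integer(4L * natom), con, endian = "little")
      writeBin(as.numeric(fr[, ax]), con, size = 4, endian = "little")
      writeBin(as.integer(4L * natom), con, endian = "little")
    }
  }
  path
}

# constant-coordinate trajectory from a structure
static_trajectory <- function(structure, n = 3) {
  Trajectory(structure, replicate(n, structure$xyz, simplify = FALSE))
}

# 2-atom anti-correlated toy: atom 2's displacement is exactly minus atom 1's
anticorrelated_trajectory <- function(n = 50) {
  topo <- make_ca_chain(2)
  amp <- sin(seq_len(n))
  coords <- lapply(seq_len(n), function(t) {
    xyz <- topo$xyz
    xyz[1, 1] <- xyz[1, 1] + amp[t]
    xyz[2, 1] <- xyz[2, 1] - amp[t]
    xyz
  })
  Trajectory(topo, coords)
}

# hexagonal aromatic ring atom coordinates around a centroid
ring_coords <- function(center, radius = 1.39) {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th), center[3])
}
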