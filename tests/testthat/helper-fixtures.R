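# shared in-code fixtures: tiny PDB texts and atom-table builders

atom_line <- function(serial, name, res, chain, seq, x, y, z,
                      het = FALSE, alt = "", occ = 1, element = NULL) {
  if (is.null(element)) element <- substr(name, 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, alt, res, chain, seq, "",
          x, y, z, occ, 0, element)
}

# 3 protein atoms + 1 water
pdb_with_water <- function() {
  c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(2, "CA", "GLY", "A", 2, 1, 0, 0),
    atom_line(3, "CA", "GLY", "A", 3, 0, 1, 0),
    atom_line(4, "O", "HOH", "A", 4, 5, 5, 5),
    "END")
}

# one atom in two alternate conformers (A occ 0.4, B occ 0.6) + one plain atom
pdb_with_altlocs <- function() {
  c(atom_line(1, "OG1", "THR", "A", 1, 0, 0, 0, alt = "A", occ = 0.4),
    atom_line(2, "OG1", "THR", "A", 1, 0.5, 0, 0, alt = "B", occ = 0.6),
    atom_line(3, "CA", "THR", "A", 1, 1, 1, 1),
    "END")
}

# 5-atom ligand with 4 CONECT bonds, plus a protein atom
pdb_with_ligand <- function() {
  c(atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    atom_line(10, "C1", "LIG", "B", 1, 5, 5, 5, het = TRUE, element = "C"),
    atom_line(11, "C2", "LIG", "B", 1, 6, 5, 5, het = TRUE, element = "C"),
    atom_line(12, "C3", "LIG", "B", 1, 7, 5, 5, het = TRUE, element = "C"),
    atom_line(13, "O1", "LIG", "B", 1, 8, 5, 5, het = TRUE, element = "O"),
    atom_line(14, "N1", "LIG", "B", 1, 5, 6, 5, het = TRUE, element = "N"),
    "CONECT   10   11",
    "CONECT   11   12",
    "CONECT   12   13",
    "CONECT   10   14",
    "END")
}

# SITE record split over two continuation lines, 5 residues, all present
pdb_with_site <- function() {
  atoms <- vapply(1:5, function(i) {
    atom_line(i, "CA", "GLY", "A", i, i, 0, 0)
  }, character(1))
  c("REMARK 800 SITE_IDENTIFIER: AC1",
    "REMARK 800 SITE_DESCRIPTION: TEST SITE",
    "SITE     1 AC1  5 GLY A   1  GLY A   2  GLY A   3  GLY A   4",
    "SITE     2 AC1  5 GLY A   5",
    atoms,
    "END")
}

# tibble of pseudo-atoms from a coordinate matrix
atoms_from_xyz <- function(xyz, res_name = "GLY", atom_name = "CA") {
  n <- nrow(xyz)
  tibble::tibble(
    serial = seq_len(n), atom_name = atom_name, alt_loc = "",
    res_name = res_name, chain_id = "A", res_seq = seq_len(n),
    insertion_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = substr(atom_name, 1, 1), is_hetero = FALSE, occupancy = 1)
}

random_cloud <- function(n, seed) {
  m <- withr::with_seed(seed, matrix(stats::rnorm(n * 3), n, 3))
  colnames(m) <- c("x", "y", "z")
  m
}

unit_cube_corners <- function(edge = 1) {
  as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
}

# a quick small planted fixture for unit tests (smaller than study defaults)
small_fixture <- function(seed = 1, ...) {
  make_planted_structure(fixture_spec(seed = seed, n_shell_atoms = 150L, ...))
}
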