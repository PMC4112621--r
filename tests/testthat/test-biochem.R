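test_that("the interaction table covers the 20 standard residues", {
  tab <- interaction_classes()
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  expect_setequal(unique(tab$res_name), std)
})

test_that("atom classification follows the residue/atom lookup", {
  expect_equal(classify_atom("THR", "OG1"), "HBD")
  expect_equal(classify_atom("SER", "OG"), "HBD")
  expect_length(classify_atom("GLY", "CA"), 0)
  expect_length(classify_atom("GLY", "N"), 0)
  expect_equal(classify_atom("MET", "SD"), "Sulfur")
  expect_equal(classify_atom("MET", "CE"), "vdW")
  expect_equal(classify_atom("LYS", "NZ"), "IonPos")
  expect_equal(classify_atom("ASP", "OD2"), "IonNeg")
  # tyrosine rows are unioned: backbone donor/acceptor plus ring carbons
  expect_setequal(classify_atom("TYR", "OH"), "HBD")
  expect_equal(classify_atom("TYR", "O"), "HBA")
  expect_equal(classify_atom("TYR", "CZ"), "CRing")
  # unknown residue announces itself once and returns nothing
  expect_length(suppressMessages(classify_atom("XXX", "C1")), 0)
})

test_that("interaction profiles equal the brute-force per-atom sum", {
  fx <- small_fixture(seed = 9)
  st <- read_structure(fx$pdb_text, id = "s")
  atoms <- dplyr::filter(st$atoms, !is_hetero)
  # two hand-made pockets over the lining atoms
  lin_serials <- fx$lining$res_seq  # fixture: serial == res_seq
  pockets <- tibble::tibble(
    pocket_id = 1:2,
    facet_ids = list(1L, 2L),
    atom_serials = list(lin_serials, atoms$serial[1:30]),
    voxels = list(integer(0), integer(0)))
  prof <- interaction_profile(pockets, atoms)

  brute <- function(serials, classes) {
    sum(vapply(serials, function(s) {
      a <- atoms[atoms$serial == s, ]
      any(classify_atom(a$res_name, a$atom_name) %in% classes)
    }, logical(1)))
  }
  for (i in 1:2) {
    s <- pockets$atom_serials[[i]]
    expect_equal(prof$n_hba[i], brute(s, "HBA"))
    expect_equal(prof$n_hbd[i], brute(s, "HBD"))
    expect_equal(prof$n_vdw[i], brute(s, "vdW"))
    expect_equal(prof$n_ionic[i], brute(s, c("IonPos", "IonNeg")))
    expect_equal(prof$n_sulfur[i], brute(s, "Sulfur"))
    expect_equal(prof$n_cring[i], brute(s, "CRing"))
  }
})

test_that("the biochemical filter keeps profiled pockets and is identity at zero", {
  pockets <- tibble::tibble(
    pocket_id = 1:3,
    facet_ids = list(1L, 2L, 3L),
    atom_serials = list(1L, 2L, 3L),
    voxels = list(integer(0), integer(0), integer(0)),
    n_hba = c(5L, 0L, 1L), n_hbd = c(8L, 0L, 1L), n_vdw = c(0L, 0L, 0L),
    n_ionic = c(1L, 0L, 0L), n_sulfur = c(0L, 0L, 0L),
    n_cring = c(20L, 0L, 0L))
  kept <- biochemical_filter(pockets)
  expect_equal(kept$pocket_id, 1L)  # all-GLY pocket (row 2) rejected
  expect_equal(biochemical_filter(pockets, 0, 0, 0)$pocket_id, 1:3)
})

test_that("the physical filter compares depth and surface against the ligand", {
  pockets <- tibble::tibble(
    pocket_id = 1:3,
    facet_ids = list(1L, 2L, 3L), atom_serials = list(1L, 2L, 3L),
    voxels = list(integer(0), integer(0), integer(0)),
    depth = c(28.40, 8.0, 10.0), surface = c(116.25, 100, 15))
  dims <- list(n_atoms = 17L, length = 8.97, surface_area = 20.87)
  class(dims) <- "pg_ligand_dims"
  kept <- physical_filter(pockets, dims)
  expect_equal(kept$pocket_id, 1L)  # too-shallow and too-small pockets fall

  zero <- list(n_atoms = 1L, length = 0, surface_area = 0)
  class(zero) <- "pg_ligand_dims"
  expect_equal(physical_filter(pockets, zero)$pocket_id, 1:3)
  expect_warning(physical_filter(pockets, NULL), "skipped")
})

test_that("ligand dimensions use max pairwise distance and hull area", {
  one <- data.frame(x = 0, y = 0, z = 0)
  expect_equal(ligand_dimensions(one)$length, 0)
  expect_equal(ligand_dimensions(one)$surface_area, 0)
  two <- data.frame(x = c(0, 5), y = 0, z = 0)
  expect_equal(ligand_dimensions(two)$length, 5)
  # a planar ring is degenerate: area 0
  ring <- make_toy_ligand(toy_ligand_spec())
  dims <- ligand_dimensions(ring)
  expect_equal(dims$n_atoms, 7)
  expect_equal(dims$surface_area, 0)
  expect_gt(dims$length, 2.7)
  # a tetrahedral set gets the closed-form hull area
  tet <- data.frame(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1))
  expect_equal(ligand_dimensions(tet)$surface_area, 1.5 + sqrt(3) / 2,
               tolerance = 1e-9)
})

test_that("ligand atom typing implements the connectivity rules", {
  # phenol-like toy ligand: 6 ring carbons + O bonded only to C
  lig <- make_toy_ligand(toy_ligand_spec())
  ty <- classify_ligand_atoms(lig)
  expect_equal(sum(ty$type == "ring_member"), 6)
  expect_equal(ty$type[ty$element == "O"], "unprotonated")

  # N bonded to exactly two C -> protonated; O bonded to N -> unprotonated
  spec <- toy_ligand_spec(het_code = "LG2",
                          elements = c("C", "N", "C", "O", "CA"),
                          coords = cbind(c(0, 1.4, 2.8, 1.4, 5),
                                         c(0, 0.5, 0, 1.9, 5), 0),
                          bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  ty2 <- classify_ligand_atoms(make_toy_ligand(spec))
  expect_equal(ty2$type[ty2$element == "N"], "protonated")
  expect_equal(ty2$type[ty2$element == "O"], "unprotonated")
  expect_equal(ty2$type[ty2$element == "CA"], "protonated")  # calcium
  # chain carbons are not ring members
  expect_true(all(ty2$type[ty2$element == "C"] == "other"))

  # no bonds: only element rules apply, with a warning
  bare <- list(atoms = tibble::tibble(serial = 1:2, element = c("C", "CA")),
               bonds = NULL)
  expect_warning(ty3 <- classify_ligand_atoms(bare), "CONECT")
  expect_equal(ty3$type, c("other", "protonated"))
})

test_that("ligand typing is invariant under serial relabelling", {
  spec <- toy_ligand_spec()
  a <- classify_ligand_atoms(make_toy_ligand(spec, serial_start = 1L))
  b <- classify_ligand_atoms(make_toy_ligand(spec, serial_start = 501L))
  expect_equal(a$type, b$type)
  expect_equal(b$serial, a$serial + 500L)
})
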