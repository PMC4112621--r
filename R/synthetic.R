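#' Specification of a synthetic planted-cavity structure
#'
#' Describes a deterministic toy structure for end-to-end testing: pseudo-atoms
#' spread over a sphere (a convex "protein" surface) with an inward dimple — a
#' planted concave cavity — along a chosen direction, plus a small ligand
#' placed at the cavity mouth and a SITE record declaring the cavity-lining
#' residues as ground truth.
#'
#' The cavity is carved by pulling every shell atom within `cavity_angle` of
#' the cavity axis inward by `cavity_depth * f`, where the falloff
#' `f = cos(pi/2 * angle/cavity_angle)` is 1 on the axis and 0 at the rim.
#' Atoms with `f >= lining_fraction` form the recorded lining; they are given
#' real residue/atom names drawn from the interaction-class table so the
#' biochemical filter is exercised honestly, while the rest of the shell is
#' glycine (no interaction classes). The default axis `(1,1,1)` keeps the
#' mouth facets oblique to the grid axes so their extreme boxes have
#' substance on every axis.
#'
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   fixture files.
#' @param shell_radius Sphere radius in Angstrom.
#' @param n_shell_atoms Number of shell pseudo-atoms (>= 20).
#' @param cavity_direction 3-vector, the cavity axis (normalised internally).
#' @param cavity_depth Maximum inward displacement in Angstrom (must be below
#'   `shell_radius`); 0 plants no cavity (a convex control).
#' @param cavity_angle Angular half-width of the cavity cap, degrees.
#' @param lining_fraction Falloff threshold above which an atom counts as
#'   cavity lining.
#' @param lining_residues Tibble of (res_name, atom_name) cycled over lining
#'   atoms; defaults to a donor/acceptor/vdW/ring/ionic/sulfur mix.
#' @param jitter Radial jitter amplitude in Angstrom.
#' @param ligand A [toy_ligand_spec()].
#' @return A list of class `pg_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         shell_radius = 10,
                         n_shell_atoms = 400L,
                         cavity_direction = c(1, 1, 1),
                         cavity_depth = 8,
                         cavity_angle = 45,
                         lining_fraction = 0.7,
                         lining_residues = default_lining_residues(),
                         jitter = 0.15,
                         ligand = toy_ligand_spec()) {
  stopifnot(n_shell_atoms >= 20, cavity_depth >= 0,
            cavity_depth < shell_radius, cavity_angle > 0, cavity_angle < 90,
            lining_fraction > 0, lining_fraction <= 1, jitter >= 0)
  if (sqrt(sum(cavity_direction^2)) == 0) {
    abort("cavity_direction must be a nonzero vector.")
  }
  out <- list(seed = as.integer(seed), shell_radius = shell_radius,
              n_shell_atoms = as.integer(n_shell_atoms),
              cavity_direction = cavity_direction / sqrt(sum(cavity_direction^2)),
              cavity_depth = cavity_depth, cavity_angle = cavity_angle,
              lining_fraction = lining_fraction,
              lining_residues = lining_residues, jitter = jitter,
              ligand = ligand)
  class(out) <- "pg_fixture_spec"
  out
}

default_lining_residues <- function() {
  tibble(res_name = c("THR", "ASN", "SER", "GLN", "ALA", "PHE", "LYS", "CYS"),
         atom_name = c("OG1", "ND2", "OG", "NE2", "CB", "CG", "NZ", "SG"))
}

#' Specification of a toy ligand
#'
#' A planar six-carbon ring with a hydroxyl-like oxygen bonded to one ring
#' carbon (phenol-like), by default: small enough to fit the planted cavity,
#' with connectivity that exercises every ligand typing rule (a carbon
#' cycle; an oxygen bonded only to carbon).
#'
#' @param het_code Heterogen residue code (1-3 characters).
#' @param elements Character vector of elements.
#' @param coords Matrix (n x 3) of template coordinates, Angstrom, centred
#'   near the origin with the ligand plane normal along +z.
#' @param bonds Two-column integer matrix of 1-based atom index pairs.
#' @return A list of class `pg_toy_ligand_spec`.
#' @export
toy_ligand_spec <- function(het_code = "TOY",
                            elements = c(rep("C", 6), "O"),
                            coords = phenol_coords(),
                            bonds = phenol_bonds()) {
  if (length(elements) == 0) abort("Empty ligand spec: no atoms.")
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(ncol(bonds) == 2)
    if (any(bonds < 1 | bonds > length(elements))) {
      abort("Ligand bond references an undeclared atom (dangling bond).")
    }
  }
  out <- list(het_code = toupper(het_code), elements = toupper(elements),
              coords = coords, bonds = bonds)
  class(out) <- "pg_toy_ligand_spec"
  out
}

phenol_coords <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  rbind(ring, c(2.75, 0, 0))  # O on the C1 axis, C-O ~ 1.36 A
}

phenol_bonds <- function() {
  cbind(c(1:6, 1), c(2:6, 1, 7))
}

#' Build a toy ligand at a position in space
#'
#' Instantiates a [toy_ligand_spec()] as HETATM atoms plus CONECT bonds, with
#' the template's z axis rotated onto `axis` and the centroid moved to
#' `center`.
#'
#' @param spec A [toy_ligand_spec()].
#' @param center 3-vector, target centroid (Angstrom).
#' @param axis 3-vector, target plane normal.
#' @param serial_start First atom serial.
#' @param res_seq Residue number given to the ligand.
#' @param chain_id Chain identifier.
#' @return A `pg_ligand` (atoms + bonds), placeable in a `pg_structure`.
#' @export
make_toy_ligand <- function(spec = toy_ligand_spec(), center = c(0, 0, 0),
                            axis = c(0, 0, 1), serial_start = 1L,
                            res_seq = 1L, chain_id = "B") {
  stopifnot(inherits(spec, "pg_toy_ligand_spec"))
  R <- rotation_to(axis)
  xyz <- sweep(spec$coords %*% t(R), 2, center, "+")
  n <- length(spec$elements)
  serials <- serial_start + seq_len(n) - 1L
  atoms <- tibble(
    serial = as.integer(serials),
    atom_name = sprintf("%s%d", spec$elements, seq_len(n)),
    alt_loc = "", res_name = spec$het_code, chain_id = chain_id,
    res_seq = as.integer(res_seq), insertion_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = spec$elements, is_hetero = TRUE, occupancy = 1
  )
  bonds <- if (nrow(spec$bonds) > 0) {
    a <- serials[spec$bonds[, 1]]; b <- serials[spec$bonds[, 2]]
    tibble(serial_a = as.integer(pmin(a, b)), serial_b = as.integer(pmax(a, b)))
  } else {
    tibble(serial_a = integer(), serial_b = integer())
  }
  out <- list(het_code = spec$het_code, atoms = atoms, bonds = bonds)
  class(out) <- "pg_ligand"
  out
}

# rotation taking (0,0,1) onto unit(axis)
rotation_to <- function(axis) {
  z <- axis / sqrt(sum(axis^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  cbind(x, y, z)
}

#' Generate a planted-cavity synthetic structure
#'
#' Realises a [fixture_spec()] as a `pg_structure` plus its PDB text and the
#' ground-truth lining residue set (also declared as SITE record "AC1"). The
#' same spec always yields byte-identical text.
#'
#' @param spec A [fixture_spec()].
#' @param id Structure identifier used in the fixture.
#' @return A list of class `pg_fixture`: `structure` (a `pg_structure`
#'   containing shell atoms, ligand HETATMs, bonds and the SITE record),
#'   `pdb_text` (character vector of PDB lines), `lining` (tibble of
#'   ground-truth residues), `ligand` (the placed `pg_ligand`), `spec`.
#' @examples
#' fx <- make_planted_structure(fixture_spec(seed = 1, n_shell_atoms = 60))
#' nrow(fx$lining)
#' @export
make_planted_structure <- function(spec = fixture_spec(), id = "SYNTH") {
  stopifnot(inherits(spec, "pg_fixture_spec"))
  n <- spec$n_shell_atoms
  d <- spec$cavity_direction

  # Fibonacci sphere: deterministic, near-uniform directions
  i <- seq_len(n) - 0.5
  zc <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - zc^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), zc)

  radii <- withr::with_seed(spec$seed, {
    spec$shell_radius + stats::runif(n, -spec$jitter, spec$jitter)
  })

  ang <- acos(pmin(1, pmax(-1, dirs %*% d)))
  cap <- spec$cavity_angle * pi / 180
  u <- as.numeric(ang) / cap
  f <- ifelse(u < 1, cos(pi * u / 2), 0)
  radii <- radii - spec$cavity_depth * f
  if (any(radii <= 0)) {
    abort("Infeasible fixture geometry: cavity reaches the sphere center.")
  }
  xyz <- dirs * radii

  # cap atoms count as "lining" even at zero depth, so the convex control
  # still declares the site and specificity can be tested against it
  lining_mask <- f >= spec$lining_fraction
  lr <- spec$lining_residues
  res_name <- rep("GLY", n)
  atom_name <- rep("CA", n)
  which_lining <- which(lining_mask)
  if (length(which_lining) > 0) {
    pick <- ((seq_along(which_lining) - 1) %% nrow(lr)) + 1
    res_name[which_lining] <- lr$res_name[pick]
    atom_name[which_lining] <- lr$atom_name[pick]
  }

  atoms <- tibble(
    serial = seq_len(n),
    atom_name = atom_name, alt_loc = "", res_name = res_name,
    chain_id = "A", res_seq = seq_len(n), insertion_code = "",
    x = round(xyz[, 1], 3), y = round(xyz[, 2], 3), z = round(xyz[, 3], 3),
    element = guess_element(atom_name), is_hetero = FALSE, occupancy = 1
  )

  lining <- tibble(res_name = res_name[which_lining],
                   res_seq = as.integer(which_lining),
                   chain_id = rep("A", length(which_lining)),
                   insertion_code = rep("", length(which_lining)))

  mouth_center <- (spec$shell_radius - spec$cavity_depth + 3) * d
  ligand <- make_toy_ligand(spec$ligand, center = mouth_center, axis = d,
                            serial_start = n + 1L, res_seq = 1L,
                            chain_id = "B")
  ligand$atoms <- mutate(ligand$atoms, x = round(.data$x, 3),
                         y = round(.data$y, 3), z = round(.data$z, 3))

  sites <- if (nrow(lining) > 0) {
    tibble(site_id = "AC1", description = "SYNTHETIC PLANTED CAVITY LINING",
           res_name = lining$res_name, res_seq = lining$res_seq,
           chain_id = lining$chain_id, insertion_code = lining$insertion_code)
  } else {
    tibble(site_id = character(), description = character(),
           res_name = character(), res_seq = integer(),
           chain_id = character(), insertion_code = character())
  }

  struct <- list(id = id, atoms = bind_rows(atoms, ligand$atoms),
                 bonds = ligand$bonds, sites = sites)
  class(struct) <- "pg_structure"
  fx <- list(structure = struct, pdb_text = write_structure(struct),
             lining = lining, ligand = ligand, spec = spec)
  class(fx) <- "pg_fixture"
  fx
}

#' @export
print.pg_fixture <- function(x, ...) {
  cat(sprintf("<pg_fixture> %d shell atoms + %d ligand atoms; %d lining residue(s); seed %d\n",
              x$spec$n_shell_atoms, nrow(x$ligand$atoms), nrow(x$lining),
              x$spec$seed))
  invisible(x)
}

#' Write a fixture to disk with its ground-truth sidecar
#'
#' @param fixture A [make_planted_structure()] result.
#' @param dir Output directory (created if needed).
#' @param name Base name for `<name>.pdb` and `<name>.truth.json`.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_fixture <- function(fixture, dir, name = "synthetic") {
  stopifnot(inherits(fixture, "pg_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  truth <- file.path(dir, paste0(name, ".truth.json"))
  writeLines(fixture$pdb_text, pdb)
  sp <- fixture$spec
  jsonlite::write_json(
    list(seed = sp$seed, shell_radius = sp$shell_radius,
         n_shell_atoms = sp$n_shell_atoms,
         cavity_direction = round(sp$cavity_direction, 6),
         cavity_depth = sp$cavity_depth, cavity_angle = sp$cavity_angle,
         lining_fraction = sp$lining_fraction,
         het_code = sp$ligand$het_code,
         lining = fixture$lining),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(pdb = pdb, truth = truth))
}
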