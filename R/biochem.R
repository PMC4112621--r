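INTERACTION_CLASSES <- c("HBD", "HBA", "vdW", "IonPos", "IonNeg", "Sulfur",
                         "CRing", "None")

the <- new.env(parent = emptyenv())

#' The residue/atom interaction-class table
#'
#' Side-chain (and, for tyrosine, backbone) atoms of the 20 standard residues
#' mapped to the biochemical interaction class they can offer a ligand:
#' hydrogen-bond donor (HBD) or acceptor (HBA), van der Waals contact (vdW),
#' positive/negative ionic (IonPos/IonNeg), sulfur, or aromatic carbon ring
#' (CRing). Glycine participates in none. The table ships as a plain TSV
#' resource so corrections are data edits.
#'
#' @return A tibble with columns `res_name`, `atom_name`, `class`. The
#'   glycine placeholder row (`atom_name == "*"`, class `"None"`) records
#'   that the residue is covered but contributes nothing.
#' @export
interaction_classes <- function() {
  if (is.null(the$classes)) {
    path <- system.file("extdata", "interaction_classes.tsv",
                        package = "pocketgrid", mustWork = TRUE)
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    stopifnot(all(tab$class %in% INTERACTION_CLASSES))
    the$classes <- as_tibble(tab)
  }
  the$classes
}

#' Interaction classes of one protein atom
#'
#' Exact lookup of a (residue name, atom name) pair in
#' [interaction_classes()]. An atom may carry several classes; pairs not in
#' the table carry none. Residue names outside the table (non-standard
#' residues) are reported once per session via a message.
#'
#' @param res_name 3-letter residue name (e.g. `"THR"`).
#' @param atom_name PDB atom name (e.g. `"OG1"`).
#' @return Character vector of classes (possibly empty).
#' @examples
#' classify_atom("THR", "OG1")  # "HBD"
#' classify_atom("GLY", "CA")   # character(0)
#' @export
classify_atom <- function(res_name, atom_name) {
  stopifnot(length(res_name) == 1, length(atom_name) == 1)
  tab <- interaction_classes()
  res_name <- toupper(res_name); atom_name <- toupper(atom_name)
  if (!res_name %in% tab$res_name) {
    if (is.null(the$unknown_res)) the$unknown_res <- character(0)
    if (!res_name %in% the$unknown_res) {
      the$unknown_res <- c(the$unknown_res, res_name)
      inform(sprintf("Residue %s is not in the interaction table; its atoms carry no class.",
                     res_name))
    }
    return(character(0))
  }
  cls <- tab$class[tab$res_name == res_name & tab$atom_name == atom_name &
                     tab$class != "None"]
  unique(cls)
}

# long per-atom classification: one row per (atom, class) carried
classify_atoms_long <- function(atoms) {
  tab <- filter(interaction_classes(), .data$class != "None")
  dplyr::inner_join(atoms, tab, by = c("res_name", "atom_name"))
}

#' Per-pocket biochemical interaction profile
#'
#' Counts, for every pocket, the atoms carrying each interaction class
#' (an atom with several classes counts once towards each). These are the
#' per-class atom counts a pocket report tabulates alongside the geometric
#' properties.
#'
#' @param pockets A `pg_pockets` tibble.
#' @param atoms Atom tibble; defaults to the attached attribute.
#' @return `pockets` with integer columns `n_hba`, `n_hbd`, `n_vdw`,
#'   `n_ionic` (positive + negative), `n_sulfur`, `n_cring` added or
#'   replaced.
#' @export
interaction_profile <- function(pockets, atoms = attr(pockets, "atoms")) {
  long <- classify_atoms_long(atoms)
  count_class <- function(serials, classes) {
    sum(unique(long$serial[long$class %in% classes]) %in% serials)
  }
  prof <- lapply(pockets$atom_serials, function(s) {
    tibble(n_hba = count_class(s, "HBA"),
           n_hbd = count_class(s, "HBD"),
           n_vdw = count_class(s, "vdW"),
           n_ionic = count_class(s, c("IonPos", "IonNeg")),
           n_sulfur = count_class(s, "Sulfur"),
           n_cring = count_class(s, "CRing"))
  })
  prof <- bind_rows(prof)
  for (nm in names(prof)) pockets[[nm]] <- as.integer(prof[[nm]])
  pockets
}

#' Biochemical pocket filter
#'
#' Keeps pockets whose interaction profile offers a ligand at least
#' `min_hba` hydrogen-bond acceptor atoms, `min_hbd` donor atoms, and
#' `min_other` atoms from the remaining classes (van der Waals, carbon ring,
#' ionic, sulfur). With all minima zero this is the identity filter.
#'
#' @param pockets A `pg_pockets` tibble (profiled with
#'   [interaction_profile()] if the columns are absent).
#' @param min_hba,min_hbd,min_other Minimum per-class atom counts.
#' @param atoms Atom tibble for profiling; defaults to the attached
#'   attribute.
#' @return The surviving rows of `pockets`, attributes preserved.
#' @export
biochemical_filter <- function(pockets, min_hba = 1L, min_hbd = 1L,
                               min_other = 1L,
                               atoms = attr(pockets, "atoms")) {
  if (!all(c("n_hba", "n_hbd") %in% names(pockets))) {
    pockets <- interaction_profile(pockets, atoms)
  }
  keep <- pockets$n_hba >= min_hba & pockets$n_hbd >= min_hbd &
    (pockets$n_vdw + pockets$n_cring + pockets$n_ionic + pockets$n_sulfur) >= min_other
  subset_pockets(pockets, keep)
}

subset_pockets <- function(pockets, keep) {
  at <- attributes(pockets)
  out <- pockets[keep, , drop = FALSE]
  for (nm in c("hull", "grid", "atoms", "n_candidates")) {
    attr(out, nm) <- at[[nm]]
  }
  class(out) <- class(pockets)
  out
}

#' Physical pocket filter against a ligand's dimensions
#'
#' A pocket can only host the ligand if it is deeper than the ligand is long
#' and its cavity surface exceeds the ligand's surface area; pockets failing
#' either comparison are dropped. With no ligand dimensions the filter warns
#' and passes everything through.
#'
#' @param pockets A `pg_pockets` tibble with `depth` and `surface` columns.
#' @param ligand_dims A [ligand_dimensions()] result (or `NULL`).
#' @return The surviving rows of `pockets`, attributes preserved.
#' @export
physical_filter <- function(pockets, ligand_dims) {
  if (is.null(ligand_dims)) {
    warn("No ligand dimensions supplied; physical filter skipped.")
    return(pockets)
  }
  keep <- pockets$depth > ligand_dims$length &
    pockets$surface > ligand_dims$surface_area
  subset_pockets(pockets, keep)
}

#' Physical dimensions of a ligand
#'
#' `length` is the largest inter-atomic distance; `surface_area` is the
#' convex-hull surface area of the atom centers (0 for fewer than 4
#' non-coplanar atoms, e.g. a planar ring).
#'
#' @param ligand A `pg_ligand` (from [ligand_atoms()] or [make_toy_ligand()]),
#'   or a data frame of atoms with `x`, `y`, `z`.
#' @return A list of class `pg_ligand_dims`: `n_atoms`, `length` (A),
#'   `surface_area` (A^2).
#' @export
ligand_dimensions <- function(ligand) {
  atoms <- if (inherits(ligand, "pg_ligand")) ligand$atoms else ligand
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  len <- if (nrow(xyz) < 2) 0 else max(dist(xyz))
  area <- tryCatch(compute_hull(xyz)$area,
                   pg_degeneracy_error = function(e) 0)
  out <- list(n_atoms = nrow(xyz), length = len, surface_area = area)
  class(out) <- "pg_ligand_dims"
  out
}

#' @export
print.pg_ligand_dims <- function(x, ...) {
  cat(sprintf("<pg_ligand_dims> %d atoms, length %.2f A, surface area %.2f A^2\n",
              x$n_atoms, x$length, x$surface_area))
  invisible(x)
}

#' Type ligand atoms from elements and connectivity
#'
#' Applies the connectivity rules for ligand biochemistry: a carbon lying on
#' a cycle of carbons in the bond graph is a `ring_member`; an oxygen bonded
#' to N, P or Zn, or bonded exclusively to carbon, is `unprotonated`; calcium,
#' or a nitrogen whose only two neighbours are both carbon, is `protonated`;
#' everything else is `other`. With no bonds available only the element rules
#' apply (with a warning).
#'
#' @param ligand A `pg_ligand`, or a list with `atoms` (tibble with `serial`,
#'   `element`) and `bonds` (tibble with `serial_a`, `serial_b`).
#' @return A tibble: `serial`, `element`, `type` (one of `ring_member`,
#'   `unprotonated`, `protonated`, `other`).
#' @export
classify_ligand_atoms <- function(ligand) {
  atoms <- ligand$atoms
  bonds <- ligand$bonds
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  el <- toupper(atoms$element)
  type <- rep("other", nrow(atoms))
  type[el == "CA"] <- "protonated"

  if (is.null(bonds) || nrow(bonds) == 0) {
    warn("Ligand has no CONECT bonds; typing limited to element rules.")
  } else {
    nb <- neighbor_elements(atoms$serial, el, bonds)
    for (i in seq_len(nrow(atoms))) {
      nbe <- nb[[i]]
      if (el[i] == "O" && length(nbe) > 0) {
        if (any(nbe %in% c("N", "P", "ZN")) || all(nbe == "C")) {
          type[i] <- "unprotonated"
        }
      } else if (el[i] == "N" && length(nbe) == 2 && all(nbe == "C")) {
        type[i] <- "protonated"
      }
    }
    ring <- carbon_ring_serials(atoms$serial[el == "C"], bonds)
    type[atoms$serial %in% ring] <- "ring_member"
  }
  tibble(serial = atoms$serial, element = el, type = type)
}

neighbor_elements <- function(serials, elements, bonds) {
  lapply(serials, function(s) {
    nb <- c(bonds$serial_b[bonds$serial_a == s],
            bonds$serial_a[bonds$serial_b == s])
    elements[match(nb, serials)]
  })
}

# serials of carbon atoms lying on a cycle made of carbons: restrict the bond
# graph to C-C edges, drop bridges, keep vertices still carrying an edge
carbon_ring_serials <- function(carbon_serials, bonds) {
  cc <- filter(bonds, .data$serial_a %in% carbon_serials,
               .data$serial_b %in% carbon_serials)
  if (nrow(cc) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(cc$serial_a), to = as.character(cc$serial_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(carbon_serials))
  )
  br <- igraph::bridges(g)
  g2 <- igraph::delete_edges(g, br)
  on_cycle <- igraph::V(g2)$name[igraph::degree(g2) > 0]
  as.integer(on_cycle)
}
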