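#' Build one candidate pocket per hull facet
#'
#' A facet's pocket contains the protein atoms whose centers fall inside the
#' facet's axis-aligned extreme box and lie within `config$atom_depth_cutoff`
#' of the facet plane (these are the surface atoms of the pocket), plus the
#' empty voxels contributed by those atoms via [empty_neighbors()], restricted
#' to the same box. Facets whose box captures no atoms produce no pocket (for
#' a hull built from the same atoms this cannot happen, because a facet's own
#' vertices always qualify).
#'
#' @param atoms Protein atom tibble (needs `serial`, `x`, `y`, `z`).
#' @param hull [compute_hull()] of the same atoms.
#' @param grid [build_grid()] of the same atoms.
#' @param config A [pg_config()].
#' @return A tibble of class `pg_pockets`, one row per non-empty candidate:
#'   `pocket_id`, list-columns `facet_ids`, `atom_serials`, `voxels`, counts
#'   `n_atoms`/`n_empty_voxels`, and `depth` (A), `surface` (A^2), `volume`
#'   (A^3). The hull, grid, atom table and candidate count travel along as
#'   attributes.
#' @export
build_pockets <- function(atoms, hull, grid, config = pg_config()) {
  stopifnot(inherits(hull, "pg_hull"), inherits(grid, "pg_grid"))
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  nfac <- nrow(hull$facets)
  nbrs <- empty_neighbors_all(grid, config$k_max)
  vox_ctr_cache <- new.env(parent = emptyenv())
  D <- facet_distances(hull, axyz)
  tol <- hull$tol

  rows <- vector("list", nfac)
  for (f in seq_len(nfac)) {
    box <- facet_box_matrix(hull, f)
    in_box <- axyz[, 1] >= box[1, 1] - tol & axyz[, 1] <= box[2, 1] + tol &
      axyz[, 2] >= box[1, 2] - tol & axyz[, 2] <= box[2, 2] + tol &
      axyz[, 3] >= box[1, 3] - tol & axyz[, 3] <= box[2, 3] + tol
    sel <- which(in_box & D[, f] <= config$atom_depth_cutoff)
    if (length(sel) == 0) next
    vox <- unique(unlist(nbrs[sel], use.names = FALSE))
    if (length(vox) > 0) {
      ctr <- voxel_centers(grid, vox)
      vin <- ctr[, 1] >= box[1, 1] - tol & ctr[, 1] <= box[2, 1] + tol &
        ctr[, 2] >= box[1, 2] - tol & ctr[, 2] <= box[2, 2] + tol &
        ctr[, 3] >= box[1, 3] - tol & ctr[, 3] <= box[2, 3] + tol
      vox <- sort(vox[vin])
    }
    rows[[f]] <- list(facet_ids = f, atom_serials = sort(atoms$serial[sel]),
                      voxels = as.integer(vox))
  }
  keep <- !vapply(rows, is.null, logical(1))
  rows <- rows[keep]
  pockets <- tibble(
    pocket_id = seq_along(rows),
    facet_ids = lapply(rows, `[[`, "facet_ids"),
    atom_serials = lapply(rows, `[[`, "atom_serials"),
    voxels = lapply(rows, `[[`, "voxels")
  )
  pockets <- add_pocket_props(pockets, atoms, hull, grid)
  attr(pockets, "hull") <- hull
  attr(pockets, "grid") <- grid
  attr(pockets, "atoms") <- atoms
  attr(pockets, "n_candidates") <- nfac
  class(pockets) <- c("pg_pockets", class(tibble()))
  pockets
}

add_pocket_props <- function(pockets, atoms, hull, grid) {
  pockets$n_atoms <- lengths(pockets$atom_serials)
  pockets$n_empty_voxels <- lengths(pockets$voxels)
  pockets$depth <- pocket_depth_impl(pockets, atoms, hull, grid)
  pockets$surface <- pocket_surface_impl(pockets, grid)
  pockets$volume <- pockets$n_empty_voxels * grid$spacing^3
  pockets
}

pocket_depth_impl <- function(pockets, atoms, hull, grid) {
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  rowidx <- match(atoms$serial, atoms$serial)  # identity; serial -> row below
  vapply(seq_len(nrow(pockets)), function(i) {
    sel <- match(pockets$atom_serials[[i]], atoms$serial)
    pts <- axyz[sel, , drop = FALSE]
    vox <- pockets$voxels[[i]]
    if (length(vox) > 0) pts <- rbind(pts, voxel_centers(grid, vox))
    if (nrow(pts) == 0) return(0)
    Dm <- facet_distances(hull, pts, pockets$facet_ids[[i]])
    max(0, apply(Dm, 1, min))
  }, numeric(1))
}

pocket_surface_impl <- function(pockets, grid) {
  face_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  occv <- grid$occupied
  dims <- grid$dims
  vapply(seq_len(nrow(pockets)), function(i) {
    vox <- pockets$voxels[[i]]
    if (length(vox) == 0) return(0)
    idx3 <- unlinear_index(vox, dims)
    nfaces <- 0L
    for (k in 1:6) {
      nb <- sweep(idx3, 2, face_offsets[k, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(ok)) next
      nfaces <- nfaces + sum(occv[nb[ok, , drop = FALSE]])
    }
    nfaces * grid$spacing^2
  }, numeric(1))
}

#' Asymmetric atom overlap between two pockets
#'
#' The fraction of pocket A's atoms that also belong to pocket B:
#' `|A intersect B| / |A|`. Not symmetric — a small pocket contained in a
#' large one overlaps it 100% while the converse can be far less.
#'
#' @param a,b Integer vectors of atom serials (or single rows of a
#'   `pg_pockets` tibble).
#' @return A fraction in `[0, 1]`.
#' @examples
#' pocket_overlap(c(1, 2), c(1, 2, 3, 4))  # 1.0
#' pocket_overlap(c(1, 2, 3, 4), c(1, 2))  # 0.5
#' @export
pocket_overlap <- function(a, b) {
  a <- pocket_serials(a); b <- pocket_serials(b)
  if (length(a) == 0) abort("overlap is undefined for an empty pocket")
  length(intersect(a, b)) / length(unique(a))
}

pocket_serials <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x$atom_serials[[1]]
  } else if (is.list(x)) unlist(x) else x
}

#' Pairwise overlap matrix of a pocket set
#'
#' @param pockets A `pg_pockets` tibble.
#' @return Square matrix `M` with `M[a, b] = |A intersect B| / |A|`.
#' @export
overlap_matrix <- function(pockets) {
  sers <- pockets$atom_serials
  uni <- sort(unique(unlist(sers, use.names = FALSE)))
  B <- matrix(0, nrow(pockets), length(uni))
  for (i in seq_along(sers)) B[i, match(sers[[i]], uni)] <- 1
  inter <- tcrossprod(B)
  sizes <- lengths(sers)
  M <- sweep(inter, 1, pmax(sizes, 1), "/")
  dimnames(M) <- list(pockets$pocket_id, pockets$pocket_id)
  M
}

#' Merge pockets by the overlap criterion
#'
#' Links every pair of pockets whose overlap — in either direction — reaches
#' `cutoff`, takes connected components of the link graph, and unions each
#' component's atoms, empty voxels and contributing facets into one pocket.
#' Because a union can overlap a third pocket more than its parts did, the
#' procedure is repeated until no further links appear, which makes the
#' result idempotent and independent of pocket order.
#'
#' @param pockets A `pg_pockets` tibble from [build_pockets()].
#' @param cutoff Overlap fraction in `(0, 1]` (default from the attached
#'   config is 0.8).
#' @param hull,grid,atoms Geometry context; defaults to the attributes
#'   attached by [build_pockets()].
#' @return A `pg_pockets` tibble of merged pockets with recomputed
#'   properties, ordered and renumbered by the smallest original pocket id in
#'   each component.
#' @export
merge_pockets <- function(pockets, cutoff = 0.8,
                          hull = attr(pockets, "hull"),
                          grid = attr(pockets, "grid"),
                          atoms = attr(pockets, "atoms")) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (nrow(pockets) == 0) return(pockets)
  cur <- pockets
  repeat {
    M <- overlap_matrix(cur)
    link <- pmax(M, t(M)) >= cutoff - 1e-12
    comp <- graph_components(link)
    if (length(unique(comp)) == nrow(cur)) break
    cur <- union_components(cur, comp)
  }
  cur <- add_pocket_props(cur, atoms, hull, grid)
  attr(cur, "hull") <- hull
  attr(cur, "grid") <- grid
  attr(cur, "atoms") <- atoms
  attr(cur, "n_candidates") <- attr(pockets, "n_candidates")
  class(cur) <- c("pg_pockets", class(tibble()))
  cur
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

union_components <- function(pockets, comp) {
  ord <- order(vapply(split(seq_along(comp), comp), min, integer(1)))
  groups <- split(seq_along(comp), comp)[ord]
  tibble(
    pocket_id = seq_along(groups),
    facet_ids = lapply(groups, function(g)
      sort(unique(unlist(pockets$facet_ids[g], use.names = FALSE)))),
    atom_serials = lapply(groups, function(g)
      sort(unique(unlist(pockets$atom_serials[g], use.names = FALSE)))),
    voxels = lapply(groups, function(g)
      sort(unique(unlist(pockets$voxels[g], use.names = FALSE))))
  )
}

#' Geometric properties of pockets
#'
#' `pocket_depth()` is the farthest any pocket point (atom center or empty
#' voxel center) sits below the pocket's contributing facet planes: the
#' maximum over points of the minimum inward plane distance. `pocket_surface()`
#' counts the voxel faces separating a pocket's empty voxels from
#' atom-occupied voxels (the cavity's atom-contact surface) times
#' `spacing^2`. `pocket_volume()` is the empty-voxel count times `spacing^3`.
#'
#' @param pockets A `pg_pockets` tibble.
#' @param hull,grid,atoms Geometry context; defaults to the attributes
#'   attached by [build_pockets()]/[merge_pockets()].
#' @return Numeric vector, one value per pocket.
#' @export
pocket_depth <- function(pockets, hull = attr(pockets, "hull"),
                         grid = attr(pockets, "grid"),
                         atoms = attr(pockets, "atoms")) {
  pocket_depth_impl(pockets, atoms, hull, grid)
}

#' @rdname pocket_depth
#' @export
pocket_surface <- function(pockets, grid = attr(pockets, "grid")) {
  pocket_surface_impl(pockets, grid)
}

#' @rdname pocket_depth
#' @export
pocket_volume <- function(pockets, grid = attr(pockets, "grid")) {
  lengths(pockets$voxels) * grid$spacing^3
}

#' Residues of each pocket
#'
#' @param pockets A `pg_pockets` tibble.
#' @param atoms Atom tibble; defaults to the attached attribute.
#' @return A tibble: pocket_id, res_name, res_seq, chain_id, insertion_code
#'   (distinct residues per pocket).
#' @export
pocket_residues <- function(pockets, atoms = attr(pockets, "atoms")) {
  out <- lapply(seq_len(nrow(pockets)), function(i) {
    sub <- atoms[match(pockets$atom_serials[[i]], atoms$serial), ]
    res <- distinct(sub, .data$res_name, .data$res_seq, .data$chain_id,
                    .data$insertion_code)
    res$pocket_id <- pockets$pocket_id[i]
    res
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(pocket_id = integer(), res_name = character(),
                  res_seq = integer(), chain_id = character(),
                  insertion_code = character()))
  }
  select(out, "pocket_id", "res_name", "res_seq", "chain_id", "insertion_code")
}
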