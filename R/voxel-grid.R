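#' Voxelise a structure's bounding box
#'
#' Builds the occupancy lattice over the axis-aligned bounding box of the
#' atom centers. Voxel `i` (1-based) on an axis covers the half-open interval
#' `[origin + (i-1)*spacing, origin + i*spacing)`; a voxel is occupied when at
#' least one atom center falls inside it. Atom membership is by center only —
#' no van der Waals radii are involved.
#'
#' @param atoms A data frame with numeric `x`, `y`, `z` columns (atom centers,
#'   Angstrom), e.g. the `atoms` tibble of a `pg_structure`.
#' @param spacing Voxel edge length in Angstrom (default 1).
#' @param dims_rounding `"floor"`: `floor(extent/spacing) + 1` voxels per axis
#'   (an exact multiple of the spacing still gets its closing voxel);
#'   `"ceiling"`: `ceiling(extent/spacing)` (minimum 1).
#'
#' @return An object of class `pg_grid`: `origin` (minimum corner), `spacing`,
#'   `dims` (integer 3-vector), `occupied` (logical array of dim `dims`),
#'   `atom_voxel` (integer vector: linear voxel index of each input atom) and
#'   `atom_xyz` (the input coordinates).
#' @examples
#' g <- build_grid(data.frame(x = c(0, 10), y = c(0, 2), z = c(0, 1)))
#' g$dims
#' @export
build_grid <- function(atoms, spacing = 1.0,
                       dims_rounding = c("floor", "ceiling")) {
  dims_rounding <- match.arg(dims_rounding)
  stopifnot(is.data.frame(atoms), all(c("x", "y", "z") %in% names(atoms)),
            spacing > 0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (nrow(xyz) == 0) abort("Cannot build a voxel grid from zero atoms.")
  if (any(!is.finite(xyz))) abort("Non-finite atom coordinates.")
  origin <- unname(apply(xyz, 2, min))
  extent <- unname(apply(xyz, 2, max)) - origin
  dims <- switch(dims_rounding,
                 floor = as.integer(floor(extent / spacing + 1e-9)) + 1L,
                 ceiling = pmax(1L, as.integer(ceiling(extent / spacing - 1e-9))))
  idx3 <- voxel_of(xyz, origin, spacing, dims)
  lin <- linear_index(idx3, dims)
  occupied <- array(FALSE, dim = dims)
  occupied[lin] <- TRUE
  g <- list(origin = origin, spacing = spacing, dims = dims,
            occupied = occupied, atom_voxel = lin, atom_xyz = xyz)
  class(g) <- "pg_grid"
  g
}

# 3-column 1-based voxel coordinates of points; clamped so points exactly on
# the max face belong to the last voxel
voxel_of <- function(xyz, origin, spacing, dims) {
  idx <- floor(sweep(sweep(xyz, 2, origin), 2, spacing, "/")) + 1
  idx <- pmin(pmax(idx, 1), matrix(dims, nrow(idx), 3, byrow = TRUE))
  storage.mode(idx) <- "integer"
  idx
}

linear_index <- function(idx3, dims) {
  as.integer(idx3[, 1] + (idx3[, 2] - 1L) * dims[1] +
               (idx3[, 3] - 1L) * dims[1] * dims[2])
}

unlinear_index <- function(lin, dims) {
  lin0 <- lin - 1L
  ix <- lin0 %% dims[1]
  iy <- (lin0 %/% dims[1]) %% dims[2]
  iz <- lin0 %/% (dims[1] * dims[2])
  cbind(ix = ix + 1L, iy = iy + 1L, iz = iz + 1L)
}

voxel_centers <- function(grid, lin) {
  idx3 <- unlinear_index(lin, grid$dims)
  sweep((idx3 - 0.5) * grid$spacing, 2, grid$origin, "+")
}

#' @export
print.pg_grid <- function(x, ...) {
  cat(sprintf("<pg_grid> %d x %d x %d voxels at %.3g A (%d occupied, %d empty)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              sum(x$occupied), sum(!x$occupied)))
  invisible(x)
}

#' Split a grid's voxels into occupied and empty index sets
#'
#' @param grid A [build_grid()] result.
#' @return A list with sorted integer vectors `occupied` and `empty` (linear
#'   voxel indices); disjoint, and together covering all `prod(dims)` voxels.
#' @export
classify_voxels <- function(grid) {
  stopifnot(inherits(grid, "pg_grid"))
  occ <- which(as.vector(grid$occupied))
  emp <- which(!as.vector(grid$occupied))
  list(occupied = as.integer(occ), empty = as.integer(emp))
}

# offsets of the 26-neighbourhood, fixed order
NEIGHBOR_OFFSETS <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Nearest empty voxel neighbours of an atom
#'
#' Looks at the 26-voxel shell around the voxel containing the atom, keeps the
#' empty in-grid voxels, orders them by distance from their centers to the
#' atom position (ties broken lexicographically by voxel coordinate), and
#' truncates at `k_max`. These voxels are the candidate ligand-atom positions
#' contributed by this atom.
#'
#' @param grid A [build_grid()] result.
#' @param atom A one-row data frame with `x`, `y`, `z`, or a numeric
#'   3-vector.
#' @param k_max Maximum number of voxels returned (>= 0).
#' @return Integer vector of linear voxel indices, nearest first.
#' @export
empty_neighbors <- function(grid, atom, k_max = 26L) {
  stopifnot(inherits(grid, "pg_grid"), k_max >= 0)
  p <- if (is.data.frame(atom)) as.numeric(atom[1, c("x", "y", "z")]) else as.numeric(atom)
  stopifnot(length(p) == 3)
  if (k_max == 0) return(integer(0))
  home <- voxel_of(matrix(p, 1, 3), grid$origin, grid$spacing, grid$dims)
  nb <- sweep(NEIGHBOR_OFFSETS, 2, as.integer(home), "+")
  keep <- nb[, 1] >= 1 & nb[, 1] <= grid$dims[1] &
    nb[, 2] >= 1 & nb[, 2] <= grid$dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= grid$dims[3]
  nb <- nb[keep, , drop = FALSE]
  if (nrow(nb) == 0) return(integer(0))
  lin <- linear_index(nb, grid$dims)
  emp <- !as.vector(grid$occupied)[lin]
  nb <- nb[emp, , drop = FALSE]
  lin <- lin[emp]
  if (length(lin) == 0) return(integer(0))
  ctr <- sweep((nb - 0.5) * grid$spacing, 2, grid$origin, "+")
  d2 <- rowSums(sweep(ctr, 2, p)^2)
  ord <- order(d2, nb[, 1], nb[, 2], nb[, 3])
  head(lin[ord], k_max)
}

# all atoms at once: list of per-atom empty-neighbour index vectors
empty_neighbors_all <- function(grid, k_max = 26L) {
  n <- nrow(grid$atom_xyz)
  lapply(seq_len(n), function(i) empty_neighbors(grid, grid$atom_xyz[i, ], k_max))
}

#' Tidy a voxel grid into one row per voxel
#'
#' @param x A `pg_grid`.
#' @param ... Unused.
#' @return A tibble with linear index, integer voxel coordinates, center
#'   coordinates and occupancy flag.
#' @method tidy pg_grid
#' @export
tidy.pg_grid <- function(x, ...) {
  lin <- seq_len(prod(x$dims))
  idx3 <- unlinear_index(lin, x$dims)
  ctr <- voxel_centers(x, lin)
  tibble(voxel = as.integer(lin), ix = idx3[, 1], iy = idx3[, 2], iz = idx3[, 3],
         x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
         occupied = as.vector(x$occupied))
}
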