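test_that("overlap is the asymmetric shared-atom fraction", {
  A <- c(1, 2); B <- c(1, 2, 3, 4)
  expect_equal(pocket_overlap(A, B), 1.0)   # all of A is in B
  expect_equal(pocket_overlap(B, A), 0.5)   # only half of B is in A
  expect_equal(pocket_overlap(A, A), 1.0)
  expect_equal(pocket_overlap(A, c(7, 8)), 0)
  expect_error(pocket_overlap(integer(0), A), "empty")
})

test_that("overlap matrix matches the brute-force set oracle", {
  withr::with_seed(11, {
    sers <- lapply(1:12, function(i) sort(sample(1:40, sample(3:15, 1))))
  })
  pockets <- tibble::tibble(pocket_id = 1:12, atom_serials = sers,
                            facet_ids = as.list(1:12),
                            voxels = rep(list(integer(0)), 12))
  M <- overlap_matrix(pockets)
  for (i in 1:12) for (j in 1:12) {
    expect_equal(M[i, j],
                 length(intersect(sers[[i]], sers[[j]])) / length(sers[[i]]))
  }
  expect_true(all(diag(M) == 1))
})

make_test_pockets <- function(sers, atoms, hull, grid) {
  p <- tibble::tibble(pocket_id = seq_along(sers),
                      facet_ids = as.list(seq_along(sers)),
                      atom_serials = sers,
                      voxels = rep(list(integer(0)), length(sers)))
  p <- pocketgrid:::add_pocket_props(p, atoms, hull, grid)
  attr(p, "hull") <- hull; attr(p, "grid") <- grid; attr(p, "atoms") <- atoms
  attr(p, "n_candidates") <- length(sers)
  class(p) <- c("pg_pockets", class(tibble::tibble()))
  p
}

test_that("merging unions linked pockets and leaves disjoint ones alone", {
  xyz <- random_cloud(40, 3) * 4
  atoms <- atoms_from_xyz(xyz)
  hull <- compute_hull(atoms); grid <- build_grid(atoms)

  # three identical pockets collapse to one
  p <- make_test_pockets(list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(1L, 2L, 3L)),
                         atoms, hull, grid)
  expect_equal(nrow(merge_pockets(p, 0.8)), 1)

  # pairwise-disjoint pockets are untouched
  p2 <- make_test_pockets(list(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
                          atoms, hull, grid)
  m2 <- merge_pockets(p2, 0.8)
  expect_equal(nrow(m2), 3)
  expect_equal(m2$atom_serials, p2$atom_serials)
})

test_that("merging is idempotent, order-independent and monotone in cutoff", {
  xyz <- random_cloud(50, 5) * 4
  atoms <- atoms_from_xyz(xyz)
  hull <- compute_hull(atoms); grid <- build_grid(atoms)
  withr::with_seed(21, {
    sers <- lapply(1:15, function(i) sort(sample(1:50, sample(3:12, 1))))
  })
  p <- make_test_pockets(sers, atoms, hull, grid)

  m <- merge_pockets(p, 0.6)
  mm <- merge_pockets(m, 0.6)
  expect_equal(nrow(mm), nrow(m))
  expect_equal(mm$atom_serials, m$atom_serials)

  # permuting the candidate order yields the same merged atom sets
  perm <- rev(seq_along(sers))
  pp <- make_test_pockets(sers[perm], atoms, hull, grid)
  mp <- merge_pockets(pp, 0.6)
  norm_sets <- function(x) {
    s <- lapply(unname(x$atom_serials), sort)
    unname(s[order(vapply(s, paste, character(1), collapse = ","))])
  }
  expect_equal(norm_sets(mp), norm_sets(m))

  # lowering the cutoff can only merge more
  counts <- vapply(c(1, 0.8, 0.6, 0.4, 0.2),
                   function(ct) nrow(merge_pockets(p, ct)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidate pockets respect the facet box and depth cutoff", {
  fx <- small_fixture(seed = 6)
  st <- read_structure(fx$pdb_text, id = "s")
  atoms <- dplyr::filter(st$atoms, !is_hetero)
  cfg <- pg_config()
  grid <- build_grid(atoms); hull <- compute_hull(atoms)
  pockets <- build_pockets(atoms, hull, grid, cfg)
  expect_equal(attr(pockets, "n_candidates"), nrow(hull$facets))
  expect_true(all(pockets$n_atoms > 0))

  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in head(seq_len(nrow(pockets)), 10)) {
    f <- pockets$facet_ids[[i]][1]
    box <- pocketgrid:::facet_box_matrix(hull, f)
    rows <- match(pockets$atom_serials[[i]], atoms$serial)
    pts <- axyz[rows, , drop = FALSE]
    expect_true(all(sweep(pts, 2, box[1, ], ">=") |
                      abs(sweep(pts, 2, box[1, ])) < 1e-6))
    expect_true(all(sweep(pts, 2, box[2, ], "<=") |
                      abs(sweep(pts, 2, box[2, ])) < 1e-6))
    d <- pocketgrid:::facet_distances(hull, pts, f)
    expect_true(all(d <= cfg$atom_depth_cutoff + 1e-9))
  }
})

test_that("every merged pocket atom lies in the union of its facet boxes", {
  fx <- small_fixture(seed = 8)
  st <- read_structure(fx$pdb_text, id = "s")
  atoms <- dplyr::filter(st$atoms, !is_hetero)
  grid <- build_grid(atoms); hull <- compute_hull(atoms)
  pockets <- build_pockets(atoms, hull, grid, pg_config())
  merged <- merge_pockets(pockets, 0.8)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in seq_len(min(nrow(merged), 20))) {
    rows <- match(merged$atom_serials[[i]], atoms$serial)
    in_any <- rep(FALSE, length(rows))
    for (f in merged$facet_ids[[i]]) {
      box <- pocketgrid:::facet_box_matrix(hull, f)
      pts <- axyz[rows, , drop = FALSE]
      ok <- pts[, 1] >= box[1, 1] - 1e-6 & pts[, 1] <= box[2, 1] + 1e-6 &
        pts[, 2] >= box[1, 2] - 1e-6 & pts[, 2] <= box[2, 2] + 1e-6 &
        pts[, 3] >= box[1, 3] - 1e-6 & pts[, 3] <= box[2, 3] + 1e-6
      in_any <- in_any | ok
    }
    expect_true(all(in_any))
  }
})

test_that("pocket depth matches constructed plane distances and is isometry-invariant", {
  # slab: one facet over atoms planted 3 A below the top plane
  top <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = 10))
  base <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = 0))
  deep <- cbind(5, 5, 7)  # 3.0 A under the z=10 plane
  atoms <- atoms_from_xyz(rbind(top, base, deep))
  hull <- compute_hull(atoms)
  grid <- build_grid(atoms)
  ftop <- which(abs(hull$normals[, 3] - 1) < 1e-9)[1]
  p <- tibble::tibble(pocket_id = 1L, facet_ids = list(ftop),
                      atom_serials = list(9L), voxels = list(integer(0)))
  expect_equal(pocket_depth(p, hull, grid, atoms), 3.0, tolerance = 1e-9)

  # rigid motion leaves depth unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz2 <- sweep(rbind(top, base, deep) %*% t(R), 2, c(3, -2, 5), "+")
  atoms2 <- atoms_from_xyz(xyz2)
  hull2 <- compute_hull(atoms2)
  # the rotated top facet still sits exactly 3 A above the deep atom
  d2 <- pocketgrid:::facet_distances(hull2, xyz2[9, , drop = FALSE])
  ftop2 <- which(abs(d2[1, ] - 3.0) < 1e-6)
  expect_gte(length(ftop2), 1)
  p2 <- tibble::tibble(pocket_id = 1L, facet_ids = list(ftop2[1]),
                       atom_serials = list(9L), voxels = list(integer(0)))
  expect_equal(pocket_depth(p2, hull2, build_grid(atoms2), atoms2), 3.0,
               tolerance = 1e-9)
})

test_that("voxel-count surface and volume definitions hold on hand-built grids", {
  # a single empty voxel enclosed by occupied neighbours: 6 faces
  occ <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  occ <- occ[!(occ[, 1] == 1 & occ[, 2] == 1 & occ[, 3] == 1), ]
  atoms <- atoms_from_xyz(occ + 0.5)
  grid <- build_grid(atoms)
  expect_equal(grid$dims, c(3L, 3L, 3L))
  hole <- pocketgrid:::linear_index(cbind(2L, 2L, 2L), grid$dims)
  hull <- compute_hull(atoms)
  p <- tibble::tibble(pocket_id = 1L, facet_ids = list(1L),
                      atom_serials = list(1L), voxels = list(hole))
  expect_equal(pocket_surface(p, grid), 6)
  expect_equal(pocket_volume(p, grid), 1)

  # a 2x1x1 empty bar: 10 exposed faces
  occ2 <- as.matrix(expand.grid(x = 0:3, y = 0:2, z = 0:2))
  bar <- (occ2[, 1] %in% c(1, 2)) & occ2[, 2] == 1 & occ2[, 3] == 1
  atoms2 <- atoms_from_xyz(occ2[!bar, ] + 0.5)
  grid2 <- build_grid(atoms2)
  barlin <- pocketgrid:::linear_index(cbind(c(2L, 3L), c(2L, 2L), c(2L, 2L)),
                                      grid2$dims)
  p2 <- tibble::tibble(pocket_id = 1L, facet_ids = list(1L),
                       atom_serials = list(1L), voxels = list(barlin))
  expect_equal(pocket_surface(p2, grid2), 10)
  expect_equal(pocket_volume(p2, grid2), 2)

  # no empty voxels: zero surface, zero volume; volume is additive
  p0 <- tibble::tibble(pocket_id = 1L, facet_ids = list(1L),
                       atom_serials = list(1L), voxels = list(integer(0)))
  expect_equal(pocket_surface(p0, grid2), 0)
  expect_equal(pocket_volume(p0, grid2), 0)
  expect_equal(pocket_volume(p2, grid2), sum(vapply(barlin, function(v) {
    pocket_volume(tibble::tibble(pocket_id = 1L, facet_ids = list(1L),
                                 atom_serials = list(1L), voxels = list(v)),
                  grid2)
  }, numeric(1))))
})
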