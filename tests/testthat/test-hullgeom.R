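tetrahedron <- data.frame(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
                          z = c(0, 0, 0, 1))

test_that("hull of the unit tetrahedron matches closed forms", {
  h <- compute_hull(tetrahedron)
  expect_equal(nrow(h$facets), 4)
  expect_equal(h$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(h$area, 1.5 + sqrt(3) / 2, tolerance = 1e-12)
  expect_setequal(h$vertex_rows, 1:4)
})

test_that("hull of the unit cube matches closed forms", {
  h <- compute_hull(as.data.frame(unit_cube_corners(1)))
  expect_equal(h$volume, 1, tolerance = 1e-12)
  expect_equal(h$area, 6, tolerance = 1e-12)
  expect_equal(nrow(h$facets), 12)  # 6 square faces, 2 triangles each
  expect_equal(length(h$vertex_rows), 8)
})

test_that("degenerate inputs raise degeneracy errors", {
  expect_error(compute_hull(tetrahedron[1:3, ]), class = "pg_degeneracy_error")
  flat <- data.frame(x = runif(10), y = runif(10), z = 0)
  expect_error(compute_hull(flat), class = "pg_degeneracy_error")
  line <- data.frame(x = 1:10, y = 2 * (1:10), z = 3 * (1:10))
  expect_error(compute_hull(line), class = "pg_degeneracy_error")
})

test_that("every input point lies inside or on all facet planes (brute force)", {
  for (seed in 1:20) {
    xyz <- random_cloud(50, seed)
    h <- compute_hull(as.data.frame(xyz))
    # brute-force half-space oracle, independent of the distance helper:
    # for each facet recompute the plane from its vertices and test all points
    for (f in seq_len(nrow(h$facets))) {
      v <- h$points[h$facets[f, ], ]
      nrm <- pracma::cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
      s <- sign(sum(nrm * (colMeans(h$points) - v[1, ])))
      side <- (sweep(h$points, 2, v[1, ]) %*% nrm) * s
      expect_true(all(side >= -1e-7 * max(1, max(abs(h$points)))))
    }
  }
})

test_that("hull agrees with an independent engine on a fixed cloud", {
  xyz <- random_cloud(120, 42)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(xyz, f, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy, scipy.spatial as sp;",
    "p=numpy.loadtxt('", f, "',delimiter=',');",
    "h=sp.ConvexHull(p);",
    "print(h.volume, h.area, len(h.vertices))"
  ))), stdout = TRUE)
  ref <- as.numeric(strsplit(trimws(out[length(out)]), " ")[[1]])
  h <- compute_hull(as.data.frame(xyz))
  expect_equal(h$volume, ref[1], tolerance = 1e-8)
  expect_equal(h$area, ref[2], tolerance = 1e-8)
  expect_equal(length(h$vertex_rows), ref[3])
})

test_that("facet normals follow the edge cross product and point outward", {
  h <- compute_hull(tetrahedron)
  # facet containing the z=0 plane has normal (0,0,-1) outward
  for (f in seq_len(4)) {
    nrm <- facet_normal(h, f)
    v <- h$points[h$facets[f, ], ]
    # orthogonal to both edges
    expect_equal(sum(nrm * (v[2, ] - v[1, ])), 0, tolerance = 1e-12)
    expect_equal(sum(nrm * (v[3, ] - v[1, ])), 0, tolerance = 1e-12)
    # outward: positive side away from the centroid
    expect_lt(sum(nrm * (colMeans(h$points) - v[1, ])), 0)
  }
  # raw (non-unit) normal is parallel to the unit one
  raw <- facet_normal(h, 1, unit = FALSE)
  u <- facet_normal(h, 1)
  expect_equal(raw / sqrt(sum(raw^2)), u, tolerance = 1e-12)
})

test_that("point-to-facet distance matches the plane-equation oracle", {
  for (seed in 1:10) {
    xyz <- random_cloud(30, seed)
    h <- compute_hull(as.data.frame(xyz))
    pts <- random_cloud(20, seed + 100)
    for (f in seq_len(nrow(h$facets))) {
      v <- h$points[h$facets[f, ], ]
      nrm <- pracma::cross(v[2, ] - v[1, ], v[3, ] - v[1, ])
      nrm <- nrm / sqrt(sum(nrm^2))
      for (i in seq_len(nrow(pts))) {
        oracle <- abs(sum(nrm * (pts[i, ] - v[1, ])))
        expect_equal(abs(point_facet_distance(pts[i, ], h, f)), oracle,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("distance is zero at facet vertices and signed inward", {
  h <- compute_hull(tetrahedron)
  for (f in seq_len(4)) {
    v <- h$points[h$facets[f, ], ]
    for (i in 1:3) {
      expect_equal(point_facet_distance(v[i, ], h, f), 0, tolerance = 1e-12)
    }
    # the hull centroid is strictly inside every facet
    expect_gt(point_facet_distance(colMeans(h$points), h, f), 0)
  }
  # explicit example: point at height 0.7 over the z=0 facet
  fz <- which(apply(abs(h$normals - rep(c(0, 0, -1), each = 4)), 1,
                    max) < 1e-9)
  expect_length(fz, 1)
  expect_equal(point_facet_distance(c(0.2, 0.2, 0.7), h, fz), 0.7,
               tolerance = 1e-12)
})

test_that("facet boxes are the tightest axis-aligned boxes of the vertices", {
  h <- compute_hull(tetrahedron)
  fz <- which(apply(abs(h$normals - rep(c(0, 0, -1), each = 4)), 1,
                    max) < 1e-9)
  b <- facet_box(h, fz)
  expect_equal(b$min, c(0, 0, 0))
  expect_equal(b$max, c(1, 1, 0))

  for (seed in 1:5) {
    xyz <- random_cloud(20, seed)
    hh <- compute_hull(as.data.frame(xyz))
    for (f in seq_len(nrow(hh$facets))) {
      v <- hh$points[hh$facets[f, ], ]
      bb <- facet_box(hh, f)
      expect_equal(bb$min, apply(v, 2, min), ignore_attr = TRUE)
      expect_equal(bb$max, apply(v, 2, max), ignore_attr = TRUE)
    }
  }
})

test_that("hull of hull vertices reproduces the hull (idempotence)", {
  xyz <- random_cloud(200, 7)
  h <- compute_hull(as.data.frame(xyz))
  h2 <- compute_hull(as.data.frame(h$points[h$vertex_rows, ]))
  expect_equal(h2$volume, h$volume, tolerance = 1e-10)
  expect_equal(h2$area, h$area, tolerance = 1e-10)
  expect_equal(length(h2$vertex_rows), length(h$vertex_rows))
})
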