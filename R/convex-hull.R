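cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Convex hull of atom centers
#'
#' Computes the triangulated convex hull of a set of 3D points by incremental
#' insertion: starting from an extreme tetrahedron, each remaining point that
#' is visible from some facet replaces the visible region with a fan of new
#' triangles over its horizon edges. All facets are triangles with outward
#' unit normals; coplanar surface patches stay triangulated (they are not
#' merged), so the facet count matches what a triangulating hull engine
#' reports.
#'
#' @param atoms Data frame with `x`, `y`, `z` columns (and optionally
#'   `serial`), or a numeric n-by-3 matrix.
#' @param tol Relative tolerance for visibility/degeneracy tests, as a
#'   fraction of the bounding-box diagonal (default 1e-9).
#'
#' @return An object of class `pg_hull`: `points` (n-by-3 matrix), `serials`,
#'   `facets` (m-by-3 matrix of point row indices, outward orientation),
#'   `normals` (m-by-3 unit outward normals), `offsets` (m, plane offsets so
#'   that inside points have `normal . p <= offset`), `vertex_rows` (row
#'   indices of points on the hull), `volume`, `area`, `tol` (absolute,
#'   Angstrom).
#' @examples
#' tet <- data.frame(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1))
#' h <- compute_hull(tet)
#' c(nrow(h$facets), h$volume)
#' @export
compute_hull <- function(atoms, tol = 1e-9) {
  P <- if (is.matrix(atoms)) atoms else as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(P) <- "double"
  serials <- if (is.data.frame(atoms) && "serial" %in% names(atoms)) {
    atoms$serial
  } else {
    seq_len(nrow(P))
  }
  n <- nrow(P)
  if (n < 4) {
    abort("Convex hull needs at least 4 points.", class = "pg_degeneracy_error")
  }
  diag_len <- sqrt(sum((apply(P, 2, max) - apply(P, 2, min))^2))
  if (diag_len == 0) {
    abort("All points coincide; hull is degenerate.",
          class = "pg_degeneracy_error")
  }
  eps <- tol * diag_len

  # --- initial extreme tetrahedron -----------------------------------------
  i1 <- order(P[, 1], P[, 2], P[, 3])[1]
  d1 <- sqrt(rowSums(sweep(P, 2, P[i1, ])^2))
  i2 <- which.max(d1)
  if (d1[i2] <= eps) {
    abort("All points coincide; hull is degenerate.",
          class = "pg_degeneracy_error")
  }
  e12 <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr <- cbind(rel[, 2] * e12[3] - rel[, 3] * e12[2],
              rel[, 3] * e12[1] - rel[, 1] * e12[3],
              rel[, 1] * e12[2] - rel[, 2] * e12[1])
  a2 <- sqrt(rowSums(cr^2))
  i3 <- which.max(a2)
  if (a2[i3] <= eps * d1[i2]) {
    abort("Points are collinear; hull is degenerate.",
          class = "pg_degeneracy_error")
  }
  n123 <- cross3(e12, P[i3, ] - P[i1, ])
  h <- abs(rel %*% n123) / sqrt(sum(n123^2))
  i4 <- which.max(h)
  if (h[i4] <= eps) {
    abort("Points are coplanar; hull is degenerate.",
          class = "pg_degeneracy_error")
  }
  interior <- colMeans(P[c(i1, i2, i3, i4), ])

  # --- growable facet store ------------------------------------------------
  cap <- max(64L, 8L * n)
  Fv <- matrix(NA_integer_, cap, 3)
  Nm <- matrix(NA_real_, cap, 3)
  off <- rep(NA_real_, cap)
  alive <- rep(FALSE, cap)
  nf <- 0L

  add_facet <- function(a, b, c) {
    nrm <- cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    nl <- sqrt(sum(nrm^2))
    if (nl <= eps * eps) return(invisible(NULL))  # degenerate sliver
    nrm <- nrm / nl
    if (sum(nrm * (interior - P[a, ])) > 0) {  # flip to outward
      tmp <- b; b <- c; c <- tmp
      nrm <- -nrm
    }
    nf <<- nf + 1L
    if (nf > nrow(Fv)) {
      Fv <<- rbind(Fv, matrix(NA_integer_, nrow(Fv), 3))
      Nm <<- rbind(Nm, matrix(NA_real_, nrow(Nm), 3))
      off <<- c(off, rep(NA_real_, length(off)))
      alive <<- c(alive, rep(FALSE, length(alive)))
    }
    Fv[nf, ] <<- c(a, b, c)
    Nm[nf, ] <<- nrm
    off[nf] <<- sum(nrm * P[a, ])
    alive[nf] <<- TRUE
    invisible(NULL)
  }

  add_facet(i1, i2, i3)
  add_facet(i1, i2, i4)
  add_facet(i1, i3, i4)
  add_facet(i2, i3, i4)

  key <- function(u, v) as.numeric(u) * (n + 1) + as.numeric(v)

  for (ip in seq_len(n)) {
    if (ip %in% c(i1, i2, i3, i4)) next
    p <- P[ip, ]
    sc <- Nm[seq_len(nf), , drop = FALSE] %*% p - off[seq_len(nf)]
    vis <- which(alive[seq_len(nf)] & sc > eps)
    if (length(vis) == 0) next
    tri <- Fv[vis, , drop = FALSE]
    eu <- c(tri[, 1], tri[, 2], tri[, 3])
    ev <- c(tri[, 2], tri[, 3], tri[, 1])
    ks <- key(eu, ev)
    horizon <- !(key(ev, eu) %in% ks)
    alive[vis] <- FALSE
    hu <- eu[horizon]; hv <- ev[horizon]
    for (j in seq_along(hu)) add_facet(hu[j], hv[j], ip)
  }

  keep <- which(alive[seq_len(nf)])
  Fv <- Fv[keep, , drop = FALSE]
  Nm <- Nm[keep, , drop = FALSE]
  off <- off[keep]

  A <- P[Fv[, 1], , drop = FALSE]
  B <- P[Fv[, 2], , drop = FALSE]
  C <- P[Fv[, 3], , drop = FALSE]
  cr <- cbind((B[, 2] - A[, 2]) * (C[, 3] - A[, 3]) - (B[, 3] - A[, 3]) * (C[, 2] - A[, 2]),
              (B[, 3] - A[, 3]) * (C[, 1] - A[, 1]) - (B[, 1] - A[, 1]) * (C[, 3] - A[, 3]),
              (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) - (B[, 2] - A[, 2]) * (C[, 1] - A[, 1]))
  area <- sum(sqrt(rowSums(cr^2))) / 2
  A0 <- sweep(A, 2, interior); B0 <- sweep(B, 2, interior); C0 <- sweep(C, 2, interior)
  volume <- sum(A0[, 1] * (B0[, 2] * C0[, 3] - B0[, 3] * C0[, 2]) +
                A0[, 2] * (B0[, 3] * C0[, 1] - B0[, 1] * C0[, 3]) +
                A0[, 3] * (B0[, 1] * C0[, 2] - B0[, 2] * C0[, 1])) / 6

  hull <- list(points = P, serials = serials, facets = Fv, normals = Nm,
               offsets = off, vertex_rows = sort(unique(as.vector(Fv))),
               volume = volume, area = area, tol = eps, interior = interior)
  class(hull) <- "pg_hull"
  hull
}

#' @export
print.pg_hull <- function(x, ...) {
  cat(sprintf("<pg_hull> %d facets over %d hull vertices (of %d points); volume %.2f A^3, area %.2f A^2\n",
              nrow(x$facets), length(x$vertex_rows), nrow(x$points),
              x$volume, x$area))
  invisible(x)
}

#' Outward normal of a hull facet
#'
#' The cross product of the facet's two edge vectors,
#' `(x2 - x1) x (x3 - x1)`, sign-corrected to point away from the hull
#' interior.
#'
#' @param hull A [compute_hull()] result.
#' @param facet_id Facet number (row of `hull$facets`).
#' @param unit Return the unit normal (default) or the raw cross product.
#' @return Numeric 3-vector.
#' @export
facet_normal <- function(hull, facet_id, unit = TRUE) {
  stopifnot(inherits(hull, "pg_hull"),
            facet_id >= 1, facet_id <= nrow(hull$facets))
  v <- hull$facets[facet_id, ]
  nrm <- cross3(hull$points[v[2], ] - hull$points[v[1], ],
                hull$points[v[3], ] - hull$points[v[1], ])
  nl <- sqrt(sum(nrm^2))
  if (nl <= hull$tol^2) {
    abort("Degenerate (collinear) facet.", class = "pg_degeneracy_error")
  }
  if (sum(nrm * hull$normals[facet_id, ]) < 0) nrm <- -nrm
  if (unit) nrm / nl else nrm
}

#' Perpendicular distance from a point to a facet plane
#'
#' Signed so that points on the hull-interior side of the (outward-oriented)
#' facet plane get a non-negative distance; a point on the plane gets 0.
#'
#' @param point Numeric 3-vector, or a one-row data frame with `x`,`y`,`z`.
#' @param hull A [compute_hull()] result.
#' @param facet_id Facet number.
#' @return Distance in Angstrom (non-negative for points inside the hull).
#' @export
point_facet_distance <- function(point, hull, facet_id) {
  stopifnot(inherits(hull, "pg_hull"))
  p <- if (is.data.frame(point)) as.numeric(point[1, c("x", "y", "z")]) else as.numeric(point)
  as.numeric(hull$offsets[facet_id] - hull$normals[facet_id, , drop = FALSE] %*% p)
}

# inward distances of many points to many facets: rows = points, cols = facets
facet_distances <- function(hull, points, facet_ids = seq_len(nrow(hull$facets))) {
  P <- if (is.data.frame(points)) as.matrix(points[, c("x", "y", "z")]) else points
  Nm <- hull$normals[facet_ids, , drop = FALSE]
  off <- hull$offsets[facet_ids]
  -sweep(P %*% t(Nm), 2, off)  # off - n.p
}

#' Axis-aligned extreme box of a facet
#'
#' The per-axis minimum/maximum over the facet's three vertex coordinates —
#' the search volume of the pocket seeded by this facet.
#'
#' @param hull A [compute_hull()] result.
#' @param facet_id Facet number.
#' @return A tibble with columns `axis` ("x","y","z"), `min`, `max`.
#' @export
facet_box <- function(hull, facet_id) {
  m <- facet_box_matrix(hull, facet_id)
  tibble(axis = c("x", "y", "z"), min = unname(m[1, ]), max = unname(m[2, ]))
}

facet_box_matrix <- function(hull, facet_id) {
  v <- hull$points[hull$facets[facet_id, ], , drop = FALSE]
  rbind(min = apply(v, 2, min), max = apply(v, 2, max))
}

#' Tidy a hull into one row per facet
#'
#' @param x A `pg_hull`.
#' @param ... Unused.
#' @return A tibble with facet id, the three vertex serials, the unit outward
#'   normal components and the facet area.
#' @method tidy pg_hull
#' @export
tidy.pg_hull <- function(x, ...) {
  A <- x$points[x$facets[, 1], , drop = FALSE]
  B <- x$points[x$facets[, 2], , drop = FALSE]
  C <- x$points[x$facets[, 3], , drop = FALSE]
  cr <- cbind((B[, 2] - A[, 2]) * (C[, 3] - A[, 3]) - (B[, 3] - A[, 3]) * (C[, 2] - A[, 2]),
              (B[, 3] - A[, 3]) * (C[, 1] - A[, 1]) - (B[, 1] - A[, 1]) * (C[, 3] - A[, 3]),
              (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) - (B[, 2] - A[, 2]) * (C[, 1] - A[, 1]))
  tibble(facet_id = seq_len(nrow(x$facets)),
         v1 = x$serials[x$facets[, 1]],
         v2 = x$serials[x$facets[, 2]],
         v3 = x$serials[x$facets[, 3]],
         nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3],
         area = sqrt(rowSums(cr^2)) / 2)
}

#' Hull summary
#'
#' @param x A `pg_hull`.
#' @param ... Unused.
#' @return One-row tibble: number of points, hull vertices, facets, volume,
#'   area.
#' @method glance pg_hull
#' @export
glance.pg_hull <- function(x, ...) {
  tibble(n_points = nrow(x$points), n_vertices = length(x$vertex_rows),
         n_facets = nrow(x$facets), volume = x$volume, area = x$area)
}
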