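# Triangulated planar meshes for the finite-element GMRF construction.
#
# No triangulation library is assumed: the mesher is a direct
# Bowyer-Watson incremental Delaunay implementation, adequate for the
# few hundred to few thousand points used here (O(n^2) scans, vectorised).

#' Delaunay triangulation of planar points (Bowyer-Watson)
#'
#' @param pts numeric matrix (n x 2) of distinct points.
#' @return integer matrix (m x 3) of vertex indices into `pts`, one row
#'   per triangle, counter-clockwise.
#' @keywords internal
delaunay <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop2("Delaunay triangulation needs at least 3 points")
  if (anyDuplicated(round(pts, 9L)))
    stop2("duplicate coordinates: jitter the points before meshing")

  # super-triangle comfortably containing everything
  ctr <- colMeans(pts)
  rad <- max(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)) * 4 + 1
  super <- rbind(
    ctr + c(0, 2 * rad),
    ctr + c(-1.8 * rad, -rad),
    ctr + c(1.8 * rad, -rad)
  )
  P <- rbind(super, pts)  # points 1:3 are super vertices

  circum <- function(tri_mat) {
    a <- P[tri_mat[, 1L], , drop = FALSE]
    b <- P[tri_mat[, 2L], , drop = FALSE]
    c <- P[tri_mat[, 3L], , drop = FALSE]
    d <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
                c[, 1] * (a[, 2] - b[, 2]))
    if (any(abs(d) < 1e-12 * rad^2))
      stop2("degenerate (collinear) point triple in triangulation; ",
            "jitter the input coordinates")
    a2 <- rowSums(a^2); b2 <- rowSums(b^2); c2 <- rowSums(c^2)
    ux <- (a2 * (b[, 2] - c[, 2]) + b2 * (c[, 2] - a[, 2]) +
             c2 * (a[, 2] - b[, 2])) / d
    uy <- (a2 * (c[, 1] - b[, 1]) + b2 * (a[, 1] - c[, 1]) +
             c2 * (b[, 1] - a[, 1])) / d
    cbind(ux, uy, (ux - a[, 1])^2 + (uy - a[, 2])^2)
  }

  tri <- matrix(c(1L, 2L, 3L), nrow = 1L)
  cc <- circum(tri)

  for (ip in seq_len(n)) {
    p <- P[ip + 3L, ]
    bad <- which((cc[, 1] - p[1])^2 + (cc[, 2] - p[2])^2 <
                   cc[, 3] * (1 + 1e-12))
    # cavity boundary = edges of bad triangles appearing exactly once
    bt <- tri[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1L, 2L)], bt[, c(2L, 3L)], bt[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- key %in% names(which(table(key) == 1L))
    poly <- edges[keep, , drop = FALSE]

    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(poly, ip + 3L)
    tri <- rbind(tri, newt)
    cc <- rbind(cc, circum(newt))
  }

  tri <- tri[rowSums(tri <= 3L) == 0L, , drop = FALSE] - 3L
  if (nrow(tri) == 0L)
    stop2("points are collinear (no triangle survives); ",
          "jitter the input coordinates")
  # orient counter-clockwise
  a <- pts[tri[, 1], , drop = FALSE]; b <- pts[tri[, 2], , drop = FALSE]
  c <- pts[tri[, 3], , drop = FALSE]
  s <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])
  flip <- s < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  tri
}

#' Build a finite-element mesh over municipality centroids
#'
#' Vertices are the municipality centroids, an optional regular interior
#' fill (so no triangle edge greatly exceeds `max_edge_km` inside the
#' hull), and a coarser rectangular ring of boundary-extension points at
#' distance `extension_km` outside the centroid bounding box. The
#' extension pushes the finite-element boundary (where the Neumann
#' condition inflates variances) away from the data; choose it at least
#' as large as the correlation range.
#'
#' @param geo data frame with columns `municipality_id`, `x_km`, `y_km`.
#' @param max_edge_km target interior edge length (km).
#' @param extension_km width of the boundary extension (km).
#' @param interior_fill add regular fill points inside the domain
#'   (default `TRUE`); fill points closer than `0.6 * max_edge_km` to a
#'   centroid are dropped.
#' @return object of class `cs_mesh`: list with `vertices` (V x 2),
#'   `triangles` (M x 3), `projector` (sparse municipalities x V,
#'   barycentric, rows sum to 1), `municipality_id`.
#' @export
build_mesh <- function(geo, max_edge_km, extension_km,
                       interior_fill = TRUE) {
  stopifnot(all(c("municipality_id", "x_km", "y_km") %in% names(geo)),
            max_edge_km > 0, extension_km >= 0)
  cent <- cbind(geo$x_km, geo$y_km)
  if (nrow(cent) < 3L) stop2("need at least 3 municipality centroids")
  rng_x <- range(cent[, 1]); rng_y <- range(cent[, 2])

  verts <- cent
  if (interior_fill) {
    gx <- seq(rng_x[1], rng_x[2], by = max_edge_km)
    gy <- seq(rng_y[1], rng_y[2], by = max_edge_km)
    grid <- as.matrix(expand.grid(gx, gy))
    if (nrow(grid) > 0L) {
      # drop fill points crowding a centroid
      dmin <- apply(grid, 1L, function(g)
        min((cent[, 1] - g[1])^2 + (cent[, 2] - g[2])^2))
      grid <- grid[dmin > (0.6 * max_edge_km)^2, , drop = FALSE]
      verts <- rbind(verts, grid)
    }
  }
  if (extension_km > 0) {
    lo <- c(rng_x[1], rng_y[1]) - extension_km
    hi <- c(rng_x[2], rng_y[2]) + extension_km
    sp <- max(2 * max_edge_km, extension_km / 2)
    xs <- seq(lo[1], hi[1], length.out = max(2L, ceiling((hi[1] - lo[1]) / sp) + 1L))
    ys <- seq(lo[2], hi[2], length.out = max(2L, ceiling((hi[2] - lo[2]) / sp) + 1L))
    ring <- rbind(
      cbind(xs, lo[2]), cbind(xs, hi[2]),
      cbind(lo[1], ys[-c(1L, length(ys))]), cbind(hi[1], ys[-c(1L, length(ys))])
    )
    verts <- rbind(verts, ring)
  }
  # tiny deterministic jitter on non-centroid helpers to avoid exact
  # collinearity of grid/ring points
  if (nrow(verts) > nrow(cent)) {
    idx <- (nrow(cent) + 1L):nrow(verts)
    ang <- (seq_along(idx) * 2.399963)  # golden-angle sequence
    verts[idx, 1] <- verts[idx, 1] + 1e-3 * cos(ang)
    verts[idx, 2] <- verts[idx, 2] + 1e-3 * sin(ang)
  }

  tri <- delaunay(verts)
  mesh <- structure(
    list(vertices = verts, triangles = tri,
         municipality_id = geo$municipality_id),
    class = "cs_mesh")
  mesh$projector <- mesh_projector(mesh, cent)
  mesh
}

#' Structured rectangular mesh (for validation against the exact Matern)
#'
#' @param nx,ny number of vertices along x and y.
#' @param spacing vertex spacing in km.
#' @return a `cs_mesh` without projector/municipality slots.
#' @export
regular_mesh <- function(nx, ny, spacing) {
  stopifnot(nx >= 2L, ny >= 2L, spacing > 0)
  verts <- as.matrix(expand.grid(x = (0:(nx - 1L)) * spacing,
                                 y = (0:(ny - 1L)) * spacing))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(1:(nx - 1L), ny - 1L)
  j <- rep(1:(ny - 1L), each = nx - 1L)
  tri <- rbind(
    cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
    cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  )
  structure(list(vertices = verts, triangles = tri,
                 municipality_id = NULL, projector = NULL),
            class = "cs_mesh")
}

#' Barycentric projector from mesh vertices to arbitrary points
#'
#' Each row carries the barycentric weights of the triangle containing
#' the point, so projecting vertex values reproduces linear functions
#' exactly; rows sum to one. A point coinciding with a vertex gets a
#' single unit weight.
#'
#' @param mesh a `cs_mesh`.
#' @param points numeric matrix (k x 2).
#' @return sparse `dgCMatrix`, k x nrow(mesh$vertices).
#' @export
mesh_projector <- function(mesh, points) {
  points <- as.matrix(points)
  V <- mesh$vertices; tri <- mesh$triangles
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  c <- V[tri[, 3], , drop = FALSE]
  det <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    l2 <- ((p[1] - a[, 1]) * (c[, 2] - a[, 2]) -
             (p[2] - a[, 2]) * (c[, 1] - a[, 1])) / det
    l3 <- ((b[, 1] - a[, 1]) * (p[2] - a[, 2]) -
             (b[, 2] - a[, 2]) * (p[1] - a[, 1])) / det
    l1 <- 1 - l2 - l3
    ok <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    if (length(ok) == 0L)
      stop2("point (", p[1], ", ", p[2], ") lies outside the mesh")
    t0 <- ok[1L]
    w <- pmax(c(l1[t0], l2[t0], l3[t0]), 0)
    w <- w / sum(w)
    nz <- w > 1e-12
    ii <- c(ii, rep.int(k, sum(nz)))
    jj <- c(jj, tri[t0, nz])
    xx <- c(xx, w[nz])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(points), nrow(V)))
}

#' Serialize a mesh to plain-text files
#'
#' Writes `vertices.csv` (x_km, y_km), `triangles.csv` (v1, v2, v3),
#' `municipalities.csv` (id) and, when present, the barycentric
#' projector as coordinate triplets (`projector.txt`, see
#' [write_sparse_triplets()]).
#'
#' @param mesh a `cs_mesh`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mesh <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(x_km = mesh$vertices[, 1],
                       y_km = mesh$vertices[, 2]),
            file.path(dir, "vertices.csv"), row.names = FALSE)
  write.csv(data.frame(v1 = mesh$triangles[, 1], v2 = mesh$triangles[, 2],
                       v3 = mesh$triangles[, 3]),
            file.path(dir, "triangles.csv"), row.names = FALSE)
  if (!is.null(mesh$municipality_id))
    write.csv(data.frame(municipality_id = mesh$municipality_id),
              file.path(dir, "municipalities.csv"), row.names = FALSE)
  if (!is.null(mesh$projector))
    write_sparse_triplets(mesh$projector, file.path(dir, "projector.txt"))
  invisible(dir)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(dir) {
  v <- read.csv(file.path(dir, "vertices.csv"))
  tr <- read.csv(file.path(dir, "triangles.csv"))
  mesh <- structure(list(vertices = cbind(v$x_km, v$y_km),
                         triangles = as.matrix(tr),
                         municipality_id = NULL, projector = NULL),
                    class = "cs_mesh")
  mp <- file.path(dir, "municipalities.csv")
  if (file.exists(mp))
    mesh$municipality_id <- read.csv(mp, colClasses = "character")[[1L]]
  pp <- file.path(dir, "projector.txt")
  if (file.exists(pp)) mesh$projector <- read_sparse_triplets(pp)
  mesh
}

#' Linear finite-element mass and stiffness matrices
#'
#' Returns the lumped (diagonal) mass matrix `C` and the stiffness
#' matrix `G` of piecewise-linear elements on the mesh; the lumping
#' keeps `C^-1` diagonal so the order-2 SPDE precision stays sparse.
#'
#' @param mesh a `cs_mesh`.
#' @return list with sparse matrices `C` (diagonal) and `G`.
#' @keywords internal
fem_matrices <- function(mesh) {
  V <- mesh$vertices; tri <- mesh$triangles
  p1 <- V[tri[, 1], , drop = FALSE]
  p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  area <- 0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                   (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  if (any(area <= 0)) stop2("degenerate or mis-oriented triangle in mesh")
  # opposite-edge vectors e_i = p_{i+2} - p_{i+1} (cyclic)
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1
  E <- list(e1, e2, e3)
  nv <- nrow(V)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in 1:3) for (j in 1:3) {
    ii <- c(ii, tri[, i]); jj <- c(jj, tri[, j])
    xx <- c(xx, rowSums(E[[i]] * E[[j]]) / (4 * area))
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  cdiag <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(tri), j = rep(1L, 3L * nrow(tri)),
    x = rep(area / 3, 3L), dims = c(nv, 1L)))
  list(C = Matrix::Diagonal(nv, cdiag), G = G)
}
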