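# graded 1-d grid: spacing h_in inside [a, b], growing geometrically to h_out
# across an extension of width `ext` on each side
graded_lines <- function(a, b, h_in, h_out, ext) {
  inner <- seq(a, b, length.out = max(2L, ceiling((b - a) / h_in) + 1L))
  grow <- function(from, dir) {
    out <- numeric(0); h <- h_in; x <- from
    while (abs(x - from) < ext) {
      h <- min(h * 1.5, h_out)
      x <- x + dir * h
      out <- c(out, x)
    }
    out
  }
  sort(c(grow(a, -1), inner, grow(b, +1)))
}

#' Build a triangular mesh with barrier-flagged triangles
#'
#' Triangulates the planar (km) projection of the domain plus a coarser
#' boundary extension: a graded rectilinear grid, each cell split into two
#' triangles. Interior cells have spacing `max_edge_inner / sqrt(2)` so every
#' interior edge (including diagonals) is at most `max_edge_inner`; extension
#' cells grow geometrically up to `max_edge_outer`. Triangles whose centroid
#' falls inside a barrier polygon are flagged; the barrier SPDE construction
#' shortens the correlation range on exactly those triangles.
#'
#' The extension pushes the larger-variance boundary artefacts of the SPDE
#' approximation outside the region of interest.
#'
#' @param domain a `domain_spec`.
#' @param max_edge_inner maximum triangle edge length (km) inside the domain.
#' @param max_edge_outer maximum edge length (km) in the extension.
#' @param ext_width extension width (km) on each side.
#' @return a `barrier_mesh`: `nodes` (n x 2 planar km), `triangles` (m x 3
#'   node indices), `barrier_flag`, `inner_flag` (centroid inside the
#'   un-extended box), plus the grid lines used (for fast point location).
#' @export
build_mesh <- function(domain, max_edge_inner = 60, max_edge_outer = 180,
                       ext_width = 150) {
  if (max_edge_inner <= 0 || max_edge_inner > max_edge_outer)
    stop("need 0 < max_edge_inner <= max_edge_outer")
  bnd <- poly_planar(domain, domain$boundary)
  h_in <- max_edge_inner / sqrt(2)
  h_out <- max_edge_outer / sqrt(2)
  xs <- graded_lines(min(bnd[, 1]), max(bnd[, 1]), h_in, h_out, ext_width)
  ys <- graded_lines(min(bnd[, 2]), max(bnd[, 2]), h_in, h_out, ext_width)
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  node_id <- function(i, j) (j - 1L) * nx + i
  cells_i <- rep(seq_len(nx - 1L), times = ny - 1L)
  cells_j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- node_id(cells_i, cells_j); v10 <- node_id(cells_i + 1L, cells_j)
  v01 <- node_id(cells_i, cells_j + 1L); v11 <- node_id(cells_i + 1L, cells_j + 1L)
  # cell k -> triangles 2k-1 (lower: v00 v10 v11), 2k (upper: v00 v11 v01)
  triangles <- matrix(0L, 2L * length(v00), 3L)
  triangles[seq(1, nrow(triangles), 2), ] <- cbind(v00, v10, v11)
  triangles[seq(2, nrow(triangles), 2), ] <- cbind(v00, v11, v01)
  cx <- (nodes[triangles[, 1], 1] + nodes[triangles[, 2], 1] +
           nodes[triangles[, 3], 1]) / 3
  cy <- (nodes[triangles[, 1], 2] + nodes[triangles[, 2], 2] +
           nodes[triangles[, 3], 2]) / 3
  barrier_flag <- rep(FALSE, nrow(triangles))
  for (b in domain$barriers) {
    bp <- poly_planar(domain, b)
    barrier_flag <- barrier_flag | point_in_poly(bp, cx, cy)
  }
  inner_flag <- cx >= min(bnd[, 1]) & cx <= max(bnd[, 1]) &
    cy >= min(bnd[, 2]) & cy <= max(bnd[, 2])
  structure(list(nodes = nodes, triangles = triangles,
                 barrier_flag = barrier_flag, inner_flag = inner_flag,
                 xs = xs, ys = ys, nx = nx, ny = ny,
                 boundary_extension = ext_width),
            class = "barrier_mesh")
}

#' Build a mesh over an arbitrary rectangle (no geographic domain)
#'
#' Utility for tests and small numerical studies: uniform structured
#' triangulation of `[x0, x1] x [y0, y1]` with optional barrier polygons given
#' directly in planar coordinates.
#'
#' @param x0,x1,y0,y1 rectangle bounds.
#' @param max_edge maximum edge length.
#' @param barriers list of planar polygons to flag.
#' @return a `barrier_mesh`.
#' @export
build_rect_mesh <- function(x0, x1, y0, y1, max_edge, barriers = list()) {
  h <- max_edge / sqrt(2)
  xs <- seq(x0, x1, length.out = max(2L, ceiling((x1 - x0) / h) + 1L))
  ys <- seq(y0, y1, length.out = max(2L, ceiling((y1 - y0) / h) + 1L))
  nx <- length(xs); ny <- length(ys)
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  node_id <- function(i, j) (j - 1L) * nx + i
  ci <- rep(seq_len(nx - 1L), times = ny - 1L)
  cj <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- node_id(ci, cj); v10 <- node_id(ci + 1L, cj)
  v01 <- node_id(ci, cj + 1L); v11 <- node_id(ci + 1L, cj + 1L)
  triangles <- matrix(0L, 2L * length(v00), 3L)
  triangles[seq(1, nrow(triangles), 2), ] <- cbind(v00, v10, v11)
  triangles[seq(2, nrow(triangles), 2), ] <- cbind(v00, v11, v01)
  cx <- (nodes[triangles[, 1], 1] + nodes[triangles[, 2], 1] +
           nodes[triangles[, 3], 1]) / 3
  cy <- (nodes[triangles[, 1], 2] + nodes[triangles[, 2], 2] +
           nodes[triangles[, 3], 2]) / 3
  barrier_flag <- rep(FALSE, nrow(triangles))
  for (b in barriers) barrier_flag <- barrier_flag | point_in_poly(b, cx, cy)
  structure(list(nodes = nodes, triangles = triangles,
                 barrier_flag = barrier_flag,
                 inner_flag = rep(TRUE, nrow(triangles)),
                 xs = xs, ys = ys, nx = nx, ny = ny,
                 boundary_extension = 0),
            class = "barrier_mesh")
}

# per-triangle geometry: areas and the P1 gradient coefficients
tri_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  # b_i = y_j - y_k, c_i = x_k - x_j (cyclic)
  b <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2])
  cc <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1])
  area <- 0.5 * abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
  list(b = b, c = cc, area = area)
}

# assemble lumped mass and stiffness over a subset of triangles
assemble_subset <- function(mesh, tris) {
  n <- nrow(mesh$nodes)
  geo <- tri_geometry(mesh)
  tt <- mesh$triangles[tris, , drop = FALSE]
  b <- geo$b[tris, , drop = FALSE]; cc <- geo$c[tris, , drop = FALSE]
  area <- geo$area[tris]
  if (any(area <= 0)) stop("zero-area triangle in mesh")
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (d in 1:3) {
    k <- k + 1L
    ii[[k]] <- tt[, a]; jj[[k]] <- tt[, d]
    xx[[k]] <- (b[, a] * b[, d] + cc[, a] * cc[, d]) / (4 * area)
  }
  G <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  cdiag <- numeric(n)
  for (a in 1:3) {
    tab <- tapply(area / 3, tt[, a], sum)
    cdiag[as.integer(names(tab))] <- cdiag[as.integer(names(tab))] + tab
  }
  list(C = cdiag, G = Matrix::forceSymmetric(G))
}

#' Assemble P1 finite-element operators
#'
#' Standard piecewise-linear finite-element matrices on the triangulation:
#' the lumped mass matrix `C` (diagonal, entries summing to the triangulated
#' area) and the stiffness matrix `G` (sparse symmetric, rows summing to
#' zero). Barrier-flagged triangles are additionally assembled separately
#' (`C_barrier`, `G_barrier`) for the barrier precision construction.
#'
#' @param mesh a `barrier_mesh`.
#' @return a `fem_operators` list: `C` (diagonal vector), `G`, `C_barrier`,
#'   `G_barrier`, `n`.
#' @export
assemble_fem <- function(mesh) {
  all_t <- seq_len(nrow(mesh$triangles))
  full <- assemble_subset(mesh, all_t)
  if (any(mesh$barrier_flag)) {
    bar <- assemble_subset(mesh, which(mesh$barrier_flag))
  } else {
    n <- nrow(mesh$nodes)
    bar <- list(C = numeric(n),
                G = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, n),
                                         symmetric = TRUE))
  }
  structure(list(C = full$C, G = full$G,
                 C_barrier = bar$C, G_barrier = bar$G,
                 n = nrow(mesh$nodes)),
            class = "fem_operators")
}

#' Barycentric projector from mesh nodes to arbitrary points
#'
#' Builds the sparse matrix `A` mapping node values to field values at planar
#' points by barycentric interpolation. Rows for points outside the mesh are
#' zero and flagged invalid.
#'
#' @param mesh a `barrier_mesh`.
#' @param points two-column matrix of planar (km) coordinates.
#' @return a `projector`: sparse matrix `A` (points x nodes) and logical
#'   `valid`.
#' @export
make_projector <- function(mesh, points) {
  points <- as.matrix(points)
  np <- nrow(points)
  ci <- findInterval(points[, 1], mesh$xs, rightmost.closed = TRUE)
  cj <- findInterval(points[, 2], mesh$ys, rightmost.closed = TRUE)
  valid <- ci >= 1L & ci < mesh$nx & cj >= 1L & cj < mesh$ny
  ii <- jj <- xx <- vector("list", np)
  geo <- tri_geometry(mesh)
  for (k in which(valid)) {
    cell <- (cj[k] - 1L) * (mesh$nx - 1L) + ci[k]
    hit <- FALSE
    for (t in c(2L * cell - 1L, 2L * cell)) {
      tri <- mesh$triangles[t, ]
      # barycentric coordinates via the P1 basis-function formula
      a2 <- 2 * geo$area[t]
      p <- mesh$nodes[tri, , drop = FALSE]
      w <- numeric(3)
      for (v in 1:3) {
        w[v] <- (geo$b[t, v] * (points[k, 1] - p[(v %% 3) + 1, 1]) +
                   geo$c[t, v] * (points[k, 2] - p[(v %% 3) + 1, 2])) / a2
      }
      if (all(w >= -1e-9)) {
        w <- pmax(w, 0); w <- w / sum(w)
        ii[[k]] <- rep(k, 3L); jj[[k]] <- tri; xx[[k]] <- w
        hit <- TRUE
        break
      }
    }
    if (!hit) valid[k] <- FALSE
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(np, nrow(mesh$nodes)))
  structure(list(A = A, valid = valid), class = "projector")
}

#' Serialise a mesh to JSON
#' @param mesh a `barrier_mesh`.
#' @param path output path.
#' @export
write_mesh_json <- function(mesh, path) {
  jsonlite::write_json(list(nodes = unname(as.matrix(mesh$nodes)),
                            triangles = unname(mesh$triangles),
                            barrier_flag = mesh$barrier_flag,
                            inner_flag = mesh$inner_flag),
                       path, digits = 10)
  invisible(path)
}
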