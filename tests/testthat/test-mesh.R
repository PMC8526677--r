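test_that("rectangle mesh respects the edge-length bound and covers the square", {
  m <- build_rect_mesh(0, 1, 0, 1, 0.2)
  geo <- seabycatch:::tri_geometry(m)
  edge_len <- function(a, b) sqrt(rowSums((m$nodes[m$triangles[, a], ] -
                                             m$nodes[m$triangles[, b], ])^2))
  max_edge <- max(edge_len(1, 2), edge_len(2, 3), edge_len(3, 1))
  expect_lte(max_edge, 0.2 + 1e-12)
  expect_equal(sum(geo$area), 1, tolerance = 1e-10)
  expect_error(build_mesh(fix_domain, 100, 50), "max_edge_inner")
})

test_that("barrier triangles are flagged by centroid and refinement adds nodes", {
  slit <- cbind(c(0.45, 0.55, 0.55, 0.45), c(0, 0, 0.7, 0.7))
  m <- build_rect_mesh(0, 1, 0, 1, 0.1, barriers = list(slit))
  cx <- rowMeans(matrix(m$nodes[t(m$triangles), 1], ncol = 3, byrow = TRUE))
  cy <- rowMeans(matrix(m$nodes[t(m$triangles), 2], ncol = 3, byrow = TRUE))
  inside <- point_in_poly(slit, cx, cy)
  expect_identical(m$barrier_flag, inside)
  expect_gt(sum(m$barrier_flag), 0)
  m_coarse <- build_rect_mesh(0, 1, 0, 1, 0.2)
  m_fine <- build_rect_mesh(0, 1, 0, 1, 0.1)
  expect_gt(nrow(m_fine$nodes), nrow(m_coarse$nodes))
})

test_that("P1 stiffness of a unit right triangle matches the closed form", {
  mesh <- structure(list(
    nodes = cbind(x = c(0, 1, 0), y = c(0, 0, 1)),
    triangles = matrix(c(1L, 2L, 3L), 1),
    barrier_flag = FALSE, inner_flag = TRUE,
    xs = c(0, 1), ys = c(0, 1), nx = 2L, ny = 2L,
    boundary_extension = 0), class = "barrier_mesh")
  fem <- assemble_fem(mesh)
  # gradients: phi1 = 1-x-y, phi2 = x, phi3 = y on a triangle of area 1/2
  G_exact <- matrix(c(1, -0.5, -0.5, -0.5, 0.5, 0, -0.5, 0, 0.5), 3)
  expect_equal(as.matrix(fem$G), G_exact, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fem$C, rep(1 / 6, 3), tolerance = 1e-12)
})

test_that("FEM operators conserve mass and annihilate constants", {
  expect_lt(max(abs(Matrix::rowSums(fix_fem10$G))), 1e-10)
  expect_equal(sum(fix_fem10$C), 100, tolerance = 1e-8)
  expect_lt(max(abs(fix_fem10$G - Matrix::t(fix_fem10$G))), 1e-12)
})

test_that("projector rows are barycentric weights with partition of unity", {
  m <- fix_mesh10
  # point at a node: unit row
  pr <- make_projector(m, rbind(m$nodes[17, ], c(100, 100)))
  expect_equal(as.vector(pr$A[1, 17]), 1)
  expect_equal(Matrix::rowSums(pr$A)[1], 1, tolerance = 1e-12)
  expect_false(pr$valid[2])
  expect_equal(Matrix::rowSums(pr$A)[2], 0)
  # point at a triangle centroid: three weights of 1/3
  tri <- m$triangles[5, ]
  ctr <- colMeans(m$nodes[tri, ])
  pr2 <- make_projector(m, rbind(ctr))
  expect_equal(sort(as.vector(pr2$A[1, tri])), rep(1 / 3, 3),
               tolerance = 1e-10)
  # partition of unity for random interior points
  set.seed(42)
  pts <- cbind(runif(50, 0.5, 9.5), runif(50, 0.5, 9.5))
  pr3 <- make_projector(m, pts)
  expect_true(all(pr3$valid))
  expect_equal(unname(Matrix::rowSums(pr3$A)), rep(1, 50), tolerance = 1e-10)
  # constant field maps to constant values
  expect_equal(as.vector(pr3$A %*% rep(3.7, nrow(m$nodes))), rep(3.7, 50),
               tolerance = 1e-10)
})
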