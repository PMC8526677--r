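test_that("stationary precision reproduces Matern nu=1 correlations and marginal sd", {
  p <- field_params(3, 1)
  Q <- precision_stationary(fix_fem10, p)
  expect_lt(max(abs(Q - Matrix::t(Q))), 1e-10)
  S <- solve(as.matrix(Q))
  i0 <- nearest_node(fix_mesh10, 5, 5)
  expect_lt(abs(sqrt(S[i0, i0]) - 1), 0.15)
  R <- stats::cov2cor(S)
  d <- sqrt((fix_mesh10$nodes[, 1] - fix_mesh10$nodes[i0, 1])^2 +
              (fix_mesh10$nodes[, 2] - fix_mesh10$nodes[i0, 2])^2)
  # interior nodes within ~1.3 ranges: discretisation tolerance 0.1
  sel <- which(d > 0.5 & d < 4 &
                 fix_mesh10$nodes[, 1] > 1.5 & fix_mesh10$nodes[, 1] < 8.5 &
                 fix_mesh10$nodes[, 2] > 1.5 & fix_mesh10$nodes[, 2] < 8.5)
  expect_lt(max(abs(R[i0, sel] - matern1_correlation(d[sel], 3))), 0.1)
  expect_error(field_params(-1, 1), "positive")
})

test_that("barrier precision reduces to the stationary one without barriers and is SPD", {
  p <- field_params(3, 1)
  Q0 <- precision_stationary(fix_fem10, p)
  Qb <- precision_barrier(fix_fem10, fix_mesh10, p)
  expect_lt(max(abs(Qb - Q0)), 1e-10)
  slit <- cbind(c(4.6, 5.4, 5.4, 4.6), c(0, 0, 7, 7))
  mb <- build_rect_mesh(0, 10, 0, 10, 0.7, barriers = list(slit))
  femb <- assemble_fem(mb)
  Q <- precision_barrier(femb, mb, field_params(4, 1, 0.05))
  ev <- eigen(as.matrix(Q), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("a barrier slit cuts correlation relative to open water at matched distance", {
  slit <- cbind(c(4.6, 5.4, 5.4, 4.6), c(0, 0, 7, 7))
  mb <- build_rect_mesh(0, 10, 0, 10, 0.6, barriers = list(slit))
  femb <- assemble_fem(mb)
  corr_pair <- function(frac) {
    Q <- precision_barrier(femb, mb, field_params(4, 1, frac))
    R <- dense_corr(Q)
    a <- nearest_node(mb, 3.5, 3); b <- nearest_node(mb, 6.5, 3)
    a2 <- nearest_node(mb, 3.5, 9); b2 <- nearest_node(mb, 6.5, 9)
    c(across = R[a, b], open = R[a2, b2])
  }
  cp <- corr_pair(0.1)
  expect_lt(cp["across"], cp["open"])
  # barrier monotonicity: shrinking the barrier range never increases the
  # across-barrier correlation
  fracs <- c(0.5, 0.2, 0.1, 0.05)
  across <- vapply(fracs, function(f) corr_pair(f)["across"], 0)
  expect_true(all(diff(across) <= 1e-10))
})

test_that("field sampling matches the dense-inverse covariance and is seeded", {
  m <- build_rect_mesh(0, 8, 0, 8, 1.1)
  fem <- assemble_fem(m)
  Q <- precision_stationary(fem, field_params(2.5, 1))
  s1 <- sample_field(Q, 5000, seed = 3)
  s2 <- sample_field(Q, 5000, seed = 3)
  expect_identical(s1, s2)
  S <- solve(as.matrix(Q))
  # CLT bound on the per-node mean
  i0 <- nearest_node(m, 4, 4)
  expect_lt(abs(mean(s1[i0, ])), 4 * sqrt(S[i0, i0] / 5000))
  # sample covariance of three nodes within 10% of the dense inverse
  nodes <- c(i0, nearest_node(m, 5, 4), nearest_node(m, 6, 6))
  Semp <- cov(t(s1[nodes, ]))
  expect_lt(max(abs(Semp - S[nodes, nodes])) / max(abs(S[nodes, nodes])),
            0.10)
})

test_that("marginal sd at a fixed interior point is stable under mesh refinement", {
  sd_at <- function(edge) {
    m <- build_rect_mesh(0, 10, 0, 10, edge)
    Q <- precision_stationary(assemble_fem(m), field_params(3, 1))
    S <- solve(as.matrix(Q))
    i0 <- nearest_node(m, 5, 5)
    sqrt(S[i0, i0])
  }
  expect_lt(abs(sd_at(1.2) - sd_at(0.6)) / sd_at(0.6), 0.05)
})

test_that("precision matrices export to Matrix-Market format", {
  Q <- precision_stationary(fix_fem10, field_params(3, 1))
  tf <- tempfile(fileext = ".mtx")
  write_mtx(Q, tf)
  Q2 <- Matrix::readMM(tf)
  expect_lt(max(abs(Q - Q2)), 1e-12)
})
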