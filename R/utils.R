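#' @importFrom stats plogis qlogis rnorm runif rpois rbinom sd var cor
#'   optim uniroot quantile setNames aggregate dnorm dpois rexp complete.cases
#' @importFrom utils head read.csv write.csv
#' @importFrom methods as
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

#' Deterministic fan-out of one master seed into per-stage seeds
#'
#' Stage `i` gets `master * 97 + i`, folded into the 32-bit signed range, so
#' any pipeline stage can be rerun in isolation with the seed it would have
#' received in a full run.
#'
#' @param master master seed (integer).
#' @param stage stage counter (integer).
#' @return an integer seed.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 97 + as.numeric(stage)) %% 2147483647)
}

#' Test whether points fall inside a polygon
#'
#' Thin wrapper over [mgcv::in.out()] with a closed-ring convention: the
#' polygon is a two-column matrix of vertices (last vertex need not repeat the
#' first).
#'
#' @param poly two-column matrix of polygon vertices.
#' @param x,y point coordinates.
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_poly <- function(poly, x, y) {
  poly <- as.matrix(poly)
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  mgcv::in.out(poly, cbind(x, y))
}

# Nautical-mile / km conversion used by the redistribution distance rule.
MILES_TO_KM <- 1.609344

# coerce any symmetric Matrix to sparse dsCMatrix form so that
# Matrix::Cholesky returns a CHMfactor with well-defined system= solves
as_sparse_sym <- function(M) {
  methods::as(methods::as(methods::as(M, "CsparseMatrix"),
                          "symmetricMatrix"), "dMatrix")
}

zero_truncated_mean <- function(lambda) {

  ifelse(lambda < 1e-12, 1, lambda / (1 - exp(-lambda)))
}

# Draw from a zero-truncated Poisson by inverse-CDF on the conditional scale.
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  p0 <- exp(-lambda)
  u <- runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}
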