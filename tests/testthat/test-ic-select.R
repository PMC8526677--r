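test_that("DIC matches a dense quadrature oracle on i.i.d. Bernoulli data", {
  set.seed(1)
  n <- 400; y <- rbinom(n, 1, 0.3)
  fit <- fit_bernoulli(build_design(data.frame(bycatch = y), model_terms(),
                                    "occurrence"))
  ll <- function(a) sum(y * a - log1p(exp(a)))
  grid <- seq(-3, 3, length.out = 4001)
  lp <- vapply(grid, function(a) ll(a) + dnorm(a, 0, 31.6, log = TRUE), 0)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  dbar <- sum(w * vapply(grid, function(a) -2 * ll(a), 0))
  dic_oracle <- 2 * dbar + 2 * ll(sum(w * grid))
  expect_lt(abs(compute_dic(fit, 4000, 1) - dic_oracle), 0.5)
  waic_pkg <- compute_waic(fit, 4000, 1)
  expect_true(is.finite(waic_pkg))
  expect_lt(abs(waic_pkg - dic_oracle), 2)  # agree closely in this regular case
  expect_error(compute_dic(fit, 1), "at least 2")
})

test_that("a degenerate single-point posterior gives p_D near zero", {
  y <- rbinom(80, 1, 0.4)
  fit <- fit_bernoulli(build_design(data.frame(bycatch = y), model_terms(),
                                    "occurrence"))
  # collapse the Gaussian approximation to a point mass at the mode
  fit$chols[[1]] <- Matrix::Cholesky(
    Matrix::sparseMatrix(i = 1, j = 1, x = 1e16, symmetric = TRUE),
    LDL = FALSE, perm = TRUE)
  d_at_mode <- -2 * fit$family$loglik(y, as.vector(fit$design$X %*%
                                                    fit$modes[[1]]))
  expect_equal(compute_dic(fit, 200, 1), d_at_mode, tolerance = 1e-4)
})

test_that("stepwise selection keeps the active covariate, drops noise, and traces monotonically", {
  ss <- selection_study(n_reps = 3, n_sets = 2500, seed = 31)
  expect_true(all(ss$active_selected))
  expect_true(all(ss$n_noise_selected == 0))
  expect_error(stepwise_select(data.frame(bycatch = 1), list(), list()),
               "empty")
  # trace DIC of the selected sub-model decreases by >= 5 at each accepted step
  obs <- gen_observer_data(
    gen_fleet(fix_domain, truth_params(base_positive_frac = 0.02), 2500,
              2000L, seed = 32),
    truth_params(base_positive_frac = 0.02, water_temp_slope = -0.25,
                 year_sd = 0, vessel_sd = 0),
    zero_field_sampler(), fix_domain, coverage = 1, seed = 33)
  sel <- stepwise_select(obs,
                         list(list(term = "water_temp", type = "linear"),
                              list(term = "season", type = "factor")),
                         list(list(term = "haul_time", type = "factor")),
                         seed = 34)
  tr <- sel$trace
  expect_gte(nrow(tr), 2)
  expect_true(all(diff(tr$DIC_z) <= 1e-9))   # greedy: never worsens
  # whichever sub-model changed at a step improved by at least delta
  for (i in seq_len(nrow(tr) - 1)) {
    expect_true(tr$DIC_z[i] - tr$DIC_z[i + 1] >= 5 - 1e-9 ||
                  tr$DIC_y[i] - tr$DIC_y[i + 1] >= 5 - 1e-9)
  }
})

test_that("pure-noise candidates rarely beat the delta-5 rule", {
  ss0 <- selection_study(n_reps = 10, n_sets = 2500, seed = 35,
                         active = FALSE)
  expect_gte(mean(ss0$n_terms_selected == 0), 0.8)
})
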