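# small fitted hurdle reused across prediction tests
pred_fixture <- local({
  truth <- quiet_truth(base_positive_frac = 0.03,
                       water_temp_slope = -0.2,
                       haul_time_effects = c(day = 0.2, night = -0.2))
  fleet <- gen_fleet(fix_domain, truth, 4000, 2000:2002, seed = 51)
  obs <- gen_observer_data(fleet, truth, zero_field_sampler(), fix_domain,
                           coverage = 0.5, seed = 52)
  fit_z <- fit_bernoulli(build_design(obs, model_terms(linears =
                                                         "water_temp"),
                                      "occurrence"))
  fit_y <- fit_ztpoisson(build_design(obs, model_terms(factors =
                                                         "haul_time"),
                                      "positive"))
  list(truth = truth, fleet = fleet, obs = obs, fit_z = fit_z,
       fit_y = fit_y)
})

test_that("posterior draws are reproducible and match the mixture mean", {
  fx <- pred_fixture
  d1 <- posterior_draws(fx$fit_z, fx$fit_y, 1000, seed = 5)
  d2 <- posterior_draws(fx$fit_z, fx$fit_y, 1000, seed = 5)
  expect_identical(d1$z$u, d2$z$u)
  expect_identical(d1$y$u, d2$y$u)
  mix_mean <- latent_mean(fx$fit_z)
  mc_sd <- latent_sd(fx$fit_z, seq_along(mix_mean))
  err <- abs(rowMeans(d1$z$u) - mix_mean)
  expect_true(all(err < 4 * mc_sd / sqrt(1000) + 1e-9))
  expect_error(posterior_draws(fx$fit_z, fx$fit_y, 0), ">= 1")
})

test_that("expected bycatch follows the closed-form hurdle product", {
  # p = 0.5 and lambda = ln 2 give E[y] = 0.5 * ln2 / (1 - 0.5) = ln 2
  expect_equal(0.5 * zero_truncated_mean(log(2)), log(2), tolerance = 1e-12)
  # p -> 0 gives 0, lambda -> 0 gives E -> p * 1
  expect_equal(0 * zero_truncated_mean(1.7), 0)
  expect_equal(zero_truncated_mean(1e-14), 1)
  fx <- pred_fixture
  draws <- posterior_draws(fx$fit_z, fx$fit_y, 50, seed = 6)
  E <- expected_bycatch_per_set(draws, fx$fleet[1:200, ], seed = 7)
  expect_true(all(E >= 0))
  expect_equal(dim(E), c(200L, 50L))
  # manual recomputation for one draw and one set
  pm_z <- seabycatch:::prediction_matrix(fx$fit_z$design, fx$fleet[1:200, ])
  eta_z <- as.vector((pm_z$X %*% draws$z$u[, 3])[10])
  pm_y <- seabycatch:::prediction_matrix(fx$fit_y$design, fx$fleet[1:200, ])
  eta_y <- as.vector((pm_y$X %*% draws$y$u[, 3])[10])
  expect_equal(E[10, 3],
               plogis(eta_z) * zero_truncated_mean(exp(eta_y)),
               tolerance = 1e-12)
})

test_that("aggregation sums within draws first and is exactly additive", {
  # hand-built example: 2 sets, 3 draws
  E <- structure(matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE),
                 valid = c(TRUE, TRUE),
                 class = c("bycatch_matrix", "matrix", "array"))
  sets <- data.frame(set_id = c("a", "b"), zone = c("MAB", "NEC"))
  tot <- aggregate_bycatch(E, sets, "total")
  # per-draw totals: 5, 7, 9
  expect_equal(tot$mean, 7)
  expect_equal(tot$sd, 2)
  expect_equal(tot$cv, 2 / 7)
  zn <- aggregate_bycatch(E, sets, "zone")
  expect_equal(sum(zn$mean), tot$mean)   # additivity of disjoint groups
  # constant expectations across draws: CV = 0
  Ec <- structure(matrix(2, 2, 3), valid = c(TRUE, TRUE),
                  class = c("bycatch_matrix", "matrix", "array"))
  expect_equal(aggregate_bycatch(Ec, sets, "total")$cv, 0)
})

test_that("unseen vessels and out-of-mesh sets are handled per contract", {
  fx <- pred_fixture
  # refit occurrence with a vessel effect so unseen levels exercise the
  # population draw
  fit_z <- fit_bernoulli(build_design(fx$obs, model_terms(vessel = TRUE),
                                      "occurrence"))
  draws <- posterior_draws(fit_z, fx$fit_y, 30, seed = 8)
  new_sets <- fx$fleet[1:20, ]
  new_sets$vessel_id <- "V999"
  expect_message(E <- expected_bycatch_per_set(draws, new_sets, seed = 9),
                 "unseen vessel")
  expect_true(all(is.finite(E)))
})
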