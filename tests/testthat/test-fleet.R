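test_that("fleet zone shares follow the sampling weights", {
  w <- c(MAB = 0.35, NEC = 0.18, SAB = 0.15, SAR = 0.12, NED = 0.08,
         TUS = 0.12)
  fl <- gen_fleet(fix_domain, truth_params(), 1000, 2000:2005, seed = 2,
                  zone_weights = w)
  shares <- prop.table(table(fl$zone))
  for (z in names(w)) {
    bound <- 2.58 * sqrt(w[z] * (1 - w[z]) / 1000)   # 99% binomial band
    expect_lt(abs(shares[[z]] - w[[z]]), bound + 1e-12)
  }
})

test_that("fleet generation validates inputs and is byte-identical for a fixed seed", {
  expect_error(gen_fleet(fix_domain, truth_params(), 0, 2000), "n_sets")
  expect_error(gen_fleet(fix_domain, truth_params(), 10, integer(0)),
               "empty years")
  f1 <- gen_fleet(fix_domain, truth_params(), 200, 2000:2002, seed = 9)
  f2 <- gen_fleet(fix_domain, truth_params(), 200, 2000:2002, seed = 9)
  t1 <- tempfile(); t2 <- tempfile()
  write_sets_csv(f1, t1); write_sets_csv(f2, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})

test_that("generated positions avoid land and day/night labels obey seasonal windows", {
  fl <- gen_fleet(fix_domain, truth_params(), 2000, 2000:2005, seed = 4)
  expect_false(any(in_barrier(fix_domain, fl$lon, fl$lat)))
  expect_true(all(point_in_poly(fix_domain$boundary, fl$lon, fl$lat)))
  # window boundaries: 6.0 h is day in summer (window opens 5:30) but night
  # in winter (opens 7:30)
  expect_equal(seabycatch:::day_night(6.0, "summer"), "day")
  expect_equal(seabycatch:::day_night(6.0, "winter"), "night")
  expect_equal(seabycatch:::day_night(19.0, "fall"), "night")
  expect_equal(seabycatch:::day_night(19.0, "spring"), "day")
})

test_that("observer sampling hits the target positive-set fraction", {
  truth <- truth_params()   # 0.5% positive sets
  fl <- gen_fleet(fix_domain, truth, 20000, 2000:2009, seed = 6)
  obs <- gen_observer_data(fl, truth, zero_field_sampler(), fix_domain,
                           coverage = 1, seed = 7)
  share <- mean(obs$bycatch > 0)
  expect_gt(share, 0.002)
  expect_lt(share, 0.012)
  expect_true(all(obs$bycatch >= 0))
  expect_true(all(obs$n_hooks >= 1))
})

test_that("with all effects zero and no calibration the occurrence probability is exactly one half", {
  truth <- quiet_truth()
  fl <- gen_fleet(fix_domain, truth, 500, 2000, seed = 8)
  obs <- gen_observer_data(fl, truth, zero_field_sampler(), fix_domain,
                           coverage = 1, seed = 9, intercept = 0)
  expect_equal(unname(attr(obs, "p")), rep(0.5, nrow(obs)))
  expect_error(gen_observer_data(fl, truth, zero_field_sampler(),
                                 fix_domain, coverage = 0), "coverage")
})

test_that("hurdle composition: mean bycatch matches p * ztp mean", {
  # one covariate cell (all effects zero), calibrated p, fixed lambda
  truth <- quiet_truth(base_positive_frac = 0.04,
                       log_lambda_intercept = log(1.3), n_hooks_slope = 0,
                       haul_time_effects = c(day = 0, night = 0))
  fl <- gen_fleet(fix_domain, truth, 40000, 2000, seed = 10)
  obs <- gen_observer_data(fl, truth, zero_field_sampler(), fix_domain,
                           coverage = 1, seed = 11)
  expected <- 0.04 * 1.3 / (1 - exp(-1.3))
  se <- sd(obs$bycatch) / sqrt(nrow(obs))
  expect_lt(abs(mean(obs$bycatch) - expected), 4 * se)
})
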