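# small shared scenario fixture: fleet with a planted hotspot, quick hurdle
# fit, baseline scores and mask
mit_fixture <- local({
  truth <- truth_params(base_positive_frac = 0.02, hotspot_slope = 0,
                        hotspot_lat_noise_sd = 0, year_sd = 0)
  years <- 2010:2013
  climate <- gen_climate_series(2006:2013, seed = 71)
  fleet <- gen_fleet(fix_domain, truth, 6000, years, seed = 72)
  sampler <- make_bump_field_sampler(fix_domain, truth, climate, years,
                                     seed = 73)
  obs <- gen_observer_data(fleet, truth, sampler, fix_domain,
                           coverage = 0.5, seed = 74)
  fit_z <- fit_bernoulli(build_design(obs, model_terms(factors = "season"),
                                      "occurrence"))
  fit_y <- fit_ztpoisson(build_design(obs, model_terms(), "positive"))
  draws <- posterior_draws(fit_z, fit_y, 60, seed = 75)
  E <- expected_bycatch_per_set(draws, fleet, seed = 76)
  surface <- hotspot_mask(bycatch_surface(E, fleet, fix_domain))
  list(fleet = fleet, draws = draws, E = E, surface = surface)
})

test_that("hotspot mask flags exactly the top quantile and degenerates safely", {
  surf <- data.frame(lon = rep(1:10, 10) * 0.1, lat = rep(1:10, each = 10) * 0.1,
                     value = as.numeric(1:100))
  surf$x <- surf$lon; surf$y <- surf$lat
  m0 <- hotspot_mask(surf, quantile = 0)
  expect_true(all(m0$hotspot))
  m9 <- hotspot_mask(surf, quantile = 0.9)
  expect_identical(which(m9$hotspot), which(surf$value > 90.1))
  # two-peak surface: both peaks flagged when both exceed the quantile
  surf2 <- surf; surf2$value <- 0
  surf2$value[c(5, 95)] <- c(10, 12)
  m2 <- hotspot_mask(surf2, quantile = 0.9)
  expect_true(all(m2$hotspot[c(5, 95)]))
  surf3 <- surf; surf3$value <- 1
  expect_warning(m3 <- hotspot_mask(surf3), "degenerate")
  expect_false(any(m3$hotspot))
})

test_that("scenario specs validate the destination rule", {
  expect_error(scenario_spec(4, "redistribute", "hotspot_area"),
               "destination")
  expect_error(scenario_spec(1, "remove", "hotspot_area",
                             destination = "spring_season"), "only applies")
  expect_length(default_scenarios(), 6L)
})

test_that("removal reduces bycatch proportionally and never increases it", {
  fx <- mit_fixture
  sp <- scenario_spec(1, "remove", "hotspot_area", n_sets = 200,
                      n_reps = 10)
  res <- run_scenario(fx$fleet, fx$E, fx$draws, sp, fx$surface, fix_domain,
                      seed = 5)
  expect_true(all(res$pct_bycatch <= 0))
  expect_identical(attr(res, "aborted"), 0L)
  # uniform removal of n of N equally scored sets: mean decrease ~ 100 n/N
  Eu <- structure(matrix(1, nrow(fx$fleet), 30),
                  valid = rep(TRUE, nrow(fx$fleet)),
                  class = c("bycatch_matrix", "matrix", "array"))
  spu <- scenario_spec(2, "remove", "summer_spring", n_sets = 500,
                       n_reps = 10)
  pool_frac <- 500 / nrow(fx$fleet)
  resu <- run_scenario(fx$fleet, Eu, fx$draws, spu, fx$surface, fix_domain,
                       seed = 6)
  expect_equal(mean(resu$pct_bycatch), -100 * pool_frac, tolerance = 1e-6)
  # removing sets with zero predicted bycatch changes nothing
  E0 <- Eu; E0[, ] <- 0
  sel_rows <- which(fx$fleet$season %in% c("summer", "spring"))
  E0[sel_rows, ] <- 0; E0[-sel_rows, ] <- 1
  res0 <- run_scenario(fx$fleet, E0, fx$draws, spu, fx$surface, fix_domain,
                       seed = 7)
  expect_equal(res0$pct_bycatch, rep(0, 10))
})

test_that("paired removal always beats redistribution of the same sets", {
  fx <- mit_fixture
  sp_rm <- scenario_spec(1, "remove", "hotspot_area", n_sets = 200,
                         n_reps = 8)
  sp_rd <- scenario_spec(4, "redistribute", "hotspot_area",
                         destination = "neighbor_sites_ge_50mi",
                         n_sets = 200, n_reps = 8)
  r_rm <- run_scenario(fx$fleet, fx$E, fx$draws, sp_rm, fx$surface,
                       fix_domain, seed = 11)
  r_rd <- run_scenario(fx$fleet, fx$E, fx$draws, sp_rd, fx$surface,
                       fix_domain, seed = 11)
  expect_true(all(r_rm$pct_bycatch <= r_rd$pct_bycatch + 1e-9))
  # redistribution loses less catch than removal
  expect_true(all(r_rd$pct_catch > r_rm$pct_catch))
})

test_that("eligible destinations honour the 50-mile rule from hotspot cells", {
  fx <- mit_fixture
  dest <- seabycatch:::eligible_destinations(fx$surface, 50)
  hot <- fx$surface[fx$surface$hotspot, ]
  expect_gt(nrow(hot), 0)
  for (g in names(dest)) {
    cells <- fx$surface[dest[[g]], ]
    if (nrow(cells) == 0) next
    dmin <- vapply(seq_len(nrow(cells)), function(i)
      sqrt(min((cells$x[i] - hot$x)^2 + (cells$y[i] - hot$y)^2)), 0)
    expect_true(all(dmin >= 50 * seabycatch:::MILES_TO_KM))
    expect_true(all(cells$sea))
  }
})

test_that("scenario summaries order by bycatch reduction and cover the mean", {
  fx <- mit_fixture
  sp <- scenario_spec(1, "remove", "hotspot_area", n_sets = 200, n_reps = 8)
  res <- run_scenario(fx$fleet, fx$E, fx$draws, sp, fx$surface, fix_domain,
                      seed = 13)
  tab <- summarize_scenarios(list(res))
  row <- tab[tab$metric == "pct_bycatch", ]
  expect_equal(nrow(row), 1L)
  expect_true(row$lo95 <= row$mean && row$mean <= row$hi95)
  # all-zero surface values: scenarios report 0% change
  E0 <- structure(matrix(0, nrow(fx$fleet), 30),
                  valid = rep(TRUE, nrow(fx$fleet)),
                  class = c("bycatch_matrix", "matrix", "array"))
  res0 <- run_scenario(fx$fleet, E0, fx$draws,
                       scenario_spec(2, "remove", "summer_spring",
                                     n_sets = 100, n_reps = 4),
                       fx$surface, fix_domain, seed = 14)
  expect_true(all(res0$pct_bycatch == 0))
})
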