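#' Fixed-effect recovery study for the occurrence sub-model
#'
#' Repeatedly generates observer-style datasets at the rare-event scale of
#' the emulated fishery (about 0.5 percent positive sets by default) with
#' only a water-temperature slope and a set-time contrast active, fits the
#' Bernoulli sub-model, and records whether the 95 percent credible
#' intervals cover the generating values and whether the negative
#' water-temperature sign is recovered.
#'
#' @param n_reps replicate datasets.
#' @param n_sets observer sets per replicate.
#' @param seed master seed.
#' @param truth generating `truth_params`; the default activates only the
#'   water-temperature slope and the set-time contrast.
#' @return data.frame with one row per replicate: slope estimate and sd,
#'   coverage indicators and the sign indicator.
#' @export
recovery_study <- function(n_reps = 100L, n_sets = 5000L, seed = 1L,
                           truth = truth_params(
                             water_temp_slope = -0.15,
                             season_effects = c(winter = 0, spring = 0,
                                                summer = 0, fall = 0),
                             target_effects = c(MIX = 0, SWO = 0, TUN = 0,
                                                SHX = 0, DOL = 0),
                             set_time_effects = c(day = 0.4, night = -0.4),
                             year_sd = 0, vessel_sd = 0)) {
  domain <- gen_domain(stage_seed(seed, 1L))
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    fleet <- gen_fleet(domain, truth, n_sets, years = 2000L,
                       seed = stage_seed(seed, 100L + r))
    obs <- gen_observer_data(fleet, truth, zero_field_sampler(), domain,
                             coverage = 1, seed = stage_seed(seed, 200L + r))
    des <- build_design(obs, model_terms(factors = "set_time",
                                         linears = "water_temp"),
                        "occurrence")
    fit <- fit_bernoulli(des)
    eff <- effect_estimates(fit)
    sl <- eff$water_temp
    st <- eff$set_time[eff$set_time$level == "day", ]
    out[[r]] <- data.frame(
      rep = r,
      n_pos = sum(obs$bycatch > 0),
      slope = sl$mean, slope_sd = sl$sd,
      cover_slope = abs(sl$mean - truth$water_temp_slope) <= 1.96 * sl$sd,
      sign_ok = sl$mean < 0,
      cover_settime = abs(st$mean - truth$set_time_effects[["day"]]) <=
        1.96 * st$sd)
  }
  do.call(rbind, out)
}

#' Stepwise selection consistency study
#'
#' Generates datasets in which only water temperature affects bycatch
#' occurrence, appends three pure-noise covariates, and runs forward
#' stepwise selection under the DIC reduction-of-5 rule. With
#' `active = FALSE` the temperature effect is switched off, giving the null
#' case in which no candidate should be accepted.
#'
#' @param n_reps replicate datasets.
#' @param n_sets observer sets per replicate.
#' @param seed master seed.
#' @param active whether the water-temperature effect is on.
#' @return data.frame per replicate: `active_selected`, `n_noise_selected`,
#'   `n_terms_selected`.
#' @export
selection_study <- function(n_reps = 100L, n_sets = 2500L, seed = 1L,
                            active = TRUE) {
  domain <- gen_domain(stage_seed(seed, 1L))
  truth <- truth_params(
    base_positive_frac = 0.02,
    water_temp_slope = if (active) -0.25 else 0,
    season_effects = c(winter = 0, spring = 0, summer = 0, fall = 0),
    target_effects = c(MIX = 0, SWO = 0, TUN = 0, SHX = 0, DOL = 0),
    set_time_effects = c(day = 0, night = 0),
    year_sd = 0, vessel_sd = 0)
  cands <- list(list(term = "water_temp", type = "linear"),
                list(term = "noise1", type = "linear"),
                list(term = "noise2", type = "linear"),
                list(term = "noise3", type = "linear"))
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    fleet <- gen_fleet(domain, truth, n_sets, years = 2000L,
                       seed = stage_seed(seed, 100L + r))
    obs <- gen_observer_data(fleet, truth, zero_field_sampler(), domain,
                             coverage = 1, seed = stage_seed(seed, 200L + r))
    obs[c("noise1", "noise2", "noise3")] <-
      with_seed(stage_seed(seed, 300L + r),
                replicate(3, runif(nrow(obs)), simplify = FALSE))
    sel <- stepwise_select(obs, cands, list(),
                           seed = stage_seed(seed, 400L + r))
    chosen <- sel$prob_terms$linears
    out[[r]] <- data.frame(
      rep = r,
      active_selected = "water_temp" %in% chosen,
      n_noise_selected = sum(grepl("^noise", chosen)),
      n_terms_selected = length(chosen))
  }
  do.call(rbind, out)
}

#' End-to-end lagged hotspot-climate recovery study
#'
#' Each replicate draws a fresh climate index, generates observer data whose
#' spatial bycatch-probability bump moves in latitude with the index at lag
#' `truth$hotspot_lag`, fits a Bernoulli sub-model with a year-replicated
#' barrier field, extracts the annual hotspot track and computes the lagged
#' cross-correlation with the index. The generating conditions follow the
#' design rule that the climate-driven hotspot-latitude variation must
#' exceed the residual latitude noise, including the noise of locating the
#' annual hotspot itself: the study runs over the full 26-year period, with
#' positive sets boosted to about 4 percent so each year carries enough
#' events (roughly 18) to localise its field replicate.
#'
#' @param n_reps replicates.
#' @param n_obs observer sets per replicate.
#' @param years study years.
#' @param seed master seed.
#' @param truth generating parameters.
#' @param mesh_edge inner mesh edge length (km).
#' @param max_lag maximum tested lag.
#' @param control fit controls (reduced hyperparameter exploration by
#'   default: the per-replicate fit is repeated many times).
#' @return data.frame per replicate and lag: r, significant, computable.
#' @export
lag_recovery_study <- function(n_reps = 100L, n_obs = 12000L,
                               years = 1992:2017, seed = 1L,
                               truth = truth_params(
                                 base_positive_frac = 0.04,
                                 field_sd = 1.5,
                                 hotspot_slope = 1.5,
                                 hotspot_lat_noise_sd = 0.3,
                                 year_sd = 0, vessel_sd = 0,
                                 season_effects = c(winter = 0, spring = 0,
                                                    summer = 0, fall = 0),
                                 target_effects = c(MIX = 0, SWO = 0,
                                                    TUN = 0, SHX = 0,
                                                    DOL = 0),
                                 set_time_effects = c(day = 0, night = 0),
                                 water_temp_slope = 0),
                               mesh_edge = 150, max_lag = 3L,
                               control = fit_control(optim_maxit = 10L,
                                                     grid_halfwidth = 1L)) {
  domain <- gen_domain(stage_seed(seed, 1L))
  mesh <- build_mesh(domain, mesh_edge, 3 * mesh_edge, 150)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    climate <- gen_climate_series(
      (min(years) - truth$hotspot_lag):max(years),
      phi = truth$climate_phi, seed = stage_seed(seed, 100L + r))
    fleet <- gen_fleet(domain, truth, n_obs, years,
                       seed = stage_seed(seed, 200L + r))
    sampler <- make_bump_field_sampler(domain, truth, climate, years,
                                       seed = stage_seed(seed, 300L + r))
    obs <- gen_observer_data(fleet, truth, sampler, domain, coverage = 1,
                             seed = stage_seed(seed, 400L + r))
    des <- build_design(obs, model_terms(spatial = "year"), "occurrence",
                        mesh = mesh, domain = domain)
    fit <- fit_bernoulli(des, prior_spec(), control)
    zero_years <- setdiff(years, sort(unique(obs$year[obs$bycatch > 0])))
    track <- hotspot_track(fit, domain, zero_years)
    ccf <- ccf_lagged(track, climate, max_lag = max_lag)
    ccf$rep <- r
    out[[r]] <- ccf
  }
  do.call(rbind, out)
}

#' Mitigation scenario ordering study
#'
#' Builds a synthetic fleet with a planted bycatch hotspot and shelf-break
#' tuna concentration, fits a hurdle model with a constant barrier field,
#' hindcasts the fleet, and runs all six scenarios with paired repetition
#' seeds so per-repetition comparisons between scenarios are meaningful.
#'
#' @param seed master seed.
#' @param n_fleet fleet sets.
#' @param n_obs_frac observer coverage.
#' @param n_sets,n_reps scenario size.
#' @param n_draws posterior draws.
#' @return list: `results` (per-scenario `scenario_result`), `summary`
#'   (comparison table).
#' @export
mitigation_ordering_study <- function(seed = 1L, n_fleet = 20000L,
                                      n_obs_frac = 0.25, n_sets = 500L,
                                      n_reps = 100L, n_draws = 200L) {
  domain <- gen_domain(stage_seed(seed, 1L))
  truth <- truth_params(base_positive_frac = 0.02,
                        hotspot_slope = 0, hotspot_lat_noise_sd = 0,
                        year_sd = 0.1)
  years <- 2006:2015
  climate <- gen_climate_series((min(years) - truth$hotspot_lag):max(years),
                                seed = stage_seed(seed, 2L))
  fleet <- gen_fleet(domain, truth, n_fleet, years,
                     seed = stage_seed(seed, 3L))
  sampler <- make_bump_field_sampler(domain, truth, climate, years,
                                     seed = stage_seed(seed, 4L))
  obs <- gen_observer_data(fleet, truth, sampler, domain,
                           coverage = n_obs_frac,
                           seed = stage_seed(seed, 5L))
  mesh <- build_mesh(domain, 150, 450, 150)
  des_z <- build_design(obs, model_terms(factors = "season",
                                         spatial = "const"),
                        "occurrence", mesh = mesh, domain = domain)
  fit_z <- fit_bernoulli(des_z, prior_spec(),
                         fit_control(optim_maxit = 10L, grid_halfwidth = 1L))
  des_y <- build_design(obs, model_terms(), "positive")
  fit_y <- fit_ztpoisson(des_y)
  draws <- posterior_draws(fit_z, fit_y, n_draws,
                           seed = stage_seed(seed, 6L))
  E <- expected_bycatch_per_set(draws, fleet, seed = stage_seed(seed, 7L))
  surface <- hotspot_mask(bycatch_surface(E, fleet, domain))
  scen <- default_scenarios(n_sets = n_sets, n_reps = n_reps)
  results <- lapply(scen, function(sp)
    run_scenario(fleet, E, draws, sp, surface, domain,
                 seed = stage_seed(seed, 10L)))
  list(results = results, summary = summarize_scenarios(results),
       surface = surface)
}
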