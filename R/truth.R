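#' Ground-truth parameters for the synthetic-data generator
#'
#' Collects every quantity the generator needs to emulate the statistical
#' structure of observer-programme longline data: rare positive sets
#' (about 0.5 percent), covariate effects with the directions reported for
#' this fishery (colder water, daytime setting and dolphinfish targeting raise
#' bycatch probability; more hooks and daytime haul-back raise the positive
#' count), a spatially clustered bycatch-probability field blocked by the
#' coastline, and a hotspot latitude driven by a climate index two years
#' earlier.
#'
#' Effects are on the logit scale for the occurrence component and the log
#' scale for the positive-count component. The occurrence intercept is not a
#' free parameter: the generator calibrates it so the marginal positive-set
#' fraction equals `base_positive_frac`.
#'
#' @param base_positive_frac marginal fraction of sets with positive bycatch;
#'   must lie in (0, 0.05).
#' @param water_temp_slope logit change per degree C (negative: colder water,
#'   more bycatch).
#' @param season_effects,target_effects,set_time_effects named numeric vectors
#'   of logit offsets (sum need not be zero; the intercept calibration absorbs
#'   the mean).
#' @param year_sd standard deviation of i.i.d. year effects on the logit scale.
#' @param vessel_sd standard deviation of vessel random effects.
#' @param field_sd marginal standard deviation of the spatial field (logit
#'   scale); `field_range_km` its Matern correlation range.
#' @param hotspot_lag lag (years) between the climate index and hotspot
#'   latitude; `hotspot_slope` degrees latitude per index unit;
#'   `hotspot_lat_noise_sd` residual latitude noise (degrees);
#'   `hotspot_base_lat` mean hotspot latitude; `hotspot_lon` hotspot
#'   longitude; `hotspot_width_km` Gaussian bump width.
#' @param log_lambda_intercept log untruncated Poisson rate at reference
#'   covariates; `n_hooks_slope` log-rate change per hook; `haul_time_effects`
#'   named log-rate offsets.
#' @param climate_phi AR(1) coefficient of the climate index.
#' @return a `truth_params` list.
#' @export
truth_params <- function(base_positive_frac = 0.005,
                         water_temp_slope = -0.15,
                         season_effects = c(winter = 0.3, spring = -0.8,
                                            summer = 0.4, fall = 0.1),
                         target_effects = c(MIX = 0.2, SWO = -0.6, TUN = -0.2,
                                            SHX = 0, DOL = 0.8),
                         set_time_effects = c(day = 0.4, night = -0.4),
                         year_sd = 0.25,
                         vessel_sd = 0.5,
                         field_sd = 1.0,
                         field_range_km = 300,
                         hotspot_lag = 2L,
                         hotspot_slope = 1.5,
                         hotspot_lat_noise_sd = 0.3,
                         hotspot_base_lat = 36,
                         hotspot_lon = -74,
                         hotspot_width_km = 250,
                         log_lambda_intercept = log(1.3),
                         n_hooks_slope = 5e-4,
                         haul_time_effects = c(day = 0.3, night = -0.3),
                         climate_phi = 0.3) {
  if (base_positive_frac <= 0 || base_positive_frac >= 0.05)
    stop("base_positive_frac must lie in (0, 0.05)")
  if (hotspot_lag < 0) stop("hotspot_lag must be >= 0")
  structure(list(
    base_positive_frac = base_positive_frac,
    water_temp_slope = water_temp_slope,
    season_effects = season_effects,
    target_effects = target_effects,
    set_time_effects = set_time_effects,
    year_sd = year_sd,
    vessel_sd = vessel_sd,
    field_sd = field_sd,
    field_range_km = field_range_km,
    hotspot_lag = as.integer(hotspot_lag),
    hotspot_slope = hotspot_slope,
    hotspot_lat_noise_sd = hotspot_lat_noise_sd,
    hotspot_base_lat = hotspot_base_lat,
    hotspot_lon = hotspot_lon,
    hotspot_width_km = hotspot_width_km,
    log_lambda_intercept = log_lambda_intercept,
    n_hooks_slope = n_hooks_slope,
    haul_time_effects = haul_time_effects,
    climate_phi = climate_phi),
    class = "truth_params")
}
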