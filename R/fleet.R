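SEASONS <- c("winter", "spring", "summer", "fall")
TARGETS <- c("MIX", "SWO", "TUN", "SHX", "DOL")

# Daylight windows by season (start, end in decimal hours), used to label a
# generated time-of-day as day or night.
DAY_WINDOWS <- list(spring = c(6.5, 19.5), summer = c(5.5, 19.5),
                    fall = c(7.0, 18.5), winter = c(7.5, 18.0))

day_night <- function(hour, season) {
  w <- DAY_WINDOWS[season]
  lo <- vapply(w, `[`, 0, 1); hi <- vapply(w, `[`, 0, 2)
  unname(ifelse(hour >= lo & hour <= hi, "day", "night"))
}

# rejection-sample n positions uniform over zone minus land
sample_zone_positions <- function(domain, zone, n) {
  poly <- domain$zones[[zone]]
  lon <- numeric(0); lat <- numeric(0)
  while (length(lon) < n) {
    m <- max(2 * (n - length(lon)), 16)
    cl <- runif(m, min(poly[, 1]), max(poly[, 1]))
    ca <- runif(m, min(poly[, 2]), max(poly[, 2]))
    ok <- !in_barrier(domain, cl, ca)
    lon <- c(lon, cl[ok]); lat <- c(lat, ca[ok])
  }
  cbind(lon = lon[seq_len(n)], lat = lat[seq_len(n)])
}

# longitude of the synthetic shelf break at given latitudes (a fixed offset
# east of the coastline), used to concentrate tuna catch
shelf_lon <- function(domain, lat) {
  coast <- domain$coastline
  stats::approx(coast[, "lat"], coast[, "lon"], xout = lat, rule = 2)$y + 1.3
}

#' Generate a logbook-style fleet of longline sets
#'
#' Emulates fleet-wide effort records: positions concentrated in a few zones,
#' uneven seasonal effort, covariates drawn from simple stated distributions,
#' and per-species fish catch from a log-linear model in which tuna catch
#' aggregates along a synthetic shelf-break line. Logbook records carry catch
#' but no bycatch.
#'
#' Default zone weights put about 88 percent of effort in the five
#' heaviest-fished zones, and default season weights make summer the busiest
#' and winter the lightest season, mirroring the effort concentration typical
#' of this fishery.
#'
#' @param domain a `domain_spec`.
#' @param truth a `truth_params`.
#' @param n_sets number of sets (>= 1).
#' @param years integer vector of years to spread effort over.
#' @param seed integer seed.
#' @param zone_weights,season_weights,target_weights named sampling weights.
#' @param n_vessels number of distinct vessels.
#' @return a data.frame of set records (`source = "logbook"`), one row per
#'   set, with per-species catch columns `catch_MIX` .. `catch_DOL`.
#' @export
gen_fleet <- function(domain, truth, n_sets, years, seed = 1L,
                      zone_weights = c(MAB = 0.35, NEC = 0.18, SAB = 0.15,
                                       SAR = 0.12, NED = 0.08, TUS = 0.12),
                      season_weights = c(winter = 0.20, spring = 0.25,
                                         summer = 0.31, fall = 0.24),
                      target_weights = c(MIX = 0.50, SWO = 0.24, TUN = 0.23,
                                         SHX = 0.02, DOL = 0.01),
                      n_vessels = 60L) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  years <- as.integer(years)
  if (length(years) == 0) stop("empty years range")
  stopifnot(all(names(zone_weights) %in% names(domain$zones)))
  with_seed(seed, {
    zone <- sample(names(zone_weights), n_sets, TRUE, zone_weights)
    season <- sample(names(season_weights), n_sets, TRUE, season_weights)
    target <- sample(names(target_weights), n_sets, TRUE, target_weights)
    year <- sample(years, n_sets, TRUE)
    pos <- matrix(0, n_sets, 2, dimnames = list(NULL, c("lon", "lat")))
    for (z in unique(zone)) {
      idx <- which(zone == z)
      pos[idx, ] <- sample_zone_positions(domain, z, length(idx))
    }
    season_t <- c(winter = -4, spring = -1, summer = 3, fall = 0)
    water_temp <- 29 - 0.6 * (pos[, "lat"] - 30) + season_t[season] +
      rnorm(n_sets, sd = 1.5)
    n_hooks <- pmax(50L, as.integer(round(rnorm(n_sets, 717, 150))))
    # skewed vessel activity: a few vessels account for most sets
    vw <- rexp(n_vessels) + 0.1
    vessel_id <- paste0("V", sprintf("%03d", sample.int(n_vessels, n_sets,
                                                        TRUE, vw)))
    set_time <- day_night(runif(n_sets, 0, 24), season)
    haul_time <- day_night(runif(n_sets, 0, 24), season)

    # per-species catch: base rates, boosted when targeted, tuna concentrated
    # along the shelf break
    d_shelf_km <- abs(pos[, "lon"] - shelf_lon(domain, pos[, "lat"])) *
      domain$planar_scale["km_per_deg_lon"]
    base <- c(MIX = 6, SWO = 3, TUN = 3, SHX = 0.6, DOL = 0.6)
    catch <- sapply(TARGETS, function(s) {
      mu <- base[s] * ifelse(target == s, 4, 1)
      if (s == "TUN") mu <- mu * exp(1.2 * exp(-d_shelf_km^2 / (2 * 60^2)))
      rpois(n_sets, mu)
    })
    colnames(catch) <- paste0("catch_", TARGETS)
    out <- data.frame(
      set_id = paste0("L", sprintf("%06d", seq_len(n_sets))),
      source = "logbook", year = year, season = season, zone = zone,
      lon = pos[, "lon"], lat = pos[, "lat"], water_temp = water_temp,
      target = target, set_time = set_time, haul_time = haul_time,
      n_hooks = n_hooks, vessel_id = vessel_id,
      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(catch))
  })
}

#' Year-specific Gaussian-bump field sampler
#'
#' Returns a sampler `f(year, xy)` giving the spatial effect (logit scale) at
#' planar positions `xy` for a given year: a Gaussian bump of amplitude
#' `2 * truth$field_sd` whose centre latitude moves with the climate index at
#' lag `truth$hotspot_lag`, plus residual year-to-year latitude noise. This is
#' the mechanism behind the lagged hotspot-climate relationship the analysis
#' is designed to recover.
#'
#' @param domain a `domain_spec`.
#' @param truth a `truth_params`.
#' @param climate a `climate_series` covering `years - truth$hotspot_lag`.
#' @param years integer years the sampler must serve.
#' @param seed integer seed for the residual latitude noise.
#' @return a function `f(year, xy)`; its `"centers"` attribute records the
#'   per-year bump centre (year, lon, lat).
#' @export
make_bump_field_sampler <- function(domain, truth, climate, years, seed = 1L) {
  years <- as.integer(years)
  lagged <- years - truth$hotspot_lag
  idx <- match(lagged, climate$year)
  if (anyNA(idx))
    stop("climate series does not cover years - hotspot_lag")
  lat_c <- with_seed(seed,
    truth$hotspot_base_lat + truth$hotspot_slope * climate$value[idx] +
      rnorm(length(years), sd = truth$hotspot_lat_noise_sd))
  centers <- data.frame(year = years, lon = truth$hotspot_lon, lat = lat_c)
  ctr_xy <- to_planar(domain, centers$lon, centers$lat)
  amp <- 2 * truth$field_sd
  w2 <- truth$hotspot_width_km^2
  f <- function(year, xy) {
    i <- match(as.integer(year), years)
    if (is.na(i)) stop("year not covered by field sampler")
    d2 <- (xy[, 1] - ctr_xy[i, 1])^2 + (xy[, 2] - ctr_xy[i, 2])^2
    amp * exp(-d2 / (2 * w2))
  }
  attr(f, "centers") <- centers
  f
}

#' Field sampler that is identically zero
#' @return a function `f(year, xy)` returning zeros.
#' @export
zero_field_sampler <- function() {
  function(year, xy) rep(0, nrow(xy))
}

#' Generate observer-style records by sampling the fleet and drawing bycatch
#'
#' Samples a fraction of fleet sets uniformly (emulating observer coverage)
#' and draws seabird bycatch from the generating hurdle model: occurrence
#' `z ~ Bernoulli(p)` with `logit(p)` the sum of covariate effects, a vessel
#' random effect, the year-specific spatial field at the set position and a
#' calibrated intercept; positive counts from a zero-truncated Poisson whose
#' log rate depends on hook number and haul time.
#'
#' The intercept is calibrated by root finding so that the mean of `p` over
#' the sampled sets equals `truth$base_positive_frac`; pass `intercept` to
#' bypass calibration (e.g. `intercept = 0` with all effects zero gives
#' `p = 0.5` exactly).
#'
#' @param fleet logbook data.frame from [gen_fleet()].
#' @param truth a `truth_params`.
#' @param field_sampler function `f(year, xy)` such as from
#'   [make_bump_field_sampler()].
#' @param domain the `domain_spec` used to generate `fleet`.
#' @param coverage fraction of sets observed, in (0, 1].
#' @param seed integer seed.
#' @param intercept optional fixed occurrence intercept (skips calibration).
#' @return observer data.frame (`source = "observer"`) with a `bycatch`
#'   column; attributes `"truth_realisation"` (intercept, year and vessel
#'   effects actually drawn) and `"p"` (per-set occurrence probabilities).
#' @export
gen_observer_data <- function(fleet, truth, field_sampler, domain,
                              coverage = 0.08, seed = 1L, intercept = NULL) {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  with_seed(seed, {
    n_obs <- max(1L, floor(coverage * nrow(fleet)))
    obs <- fleet[sort(sample.int(nrow(fleet), n_obs)), ]
    obs$source <- "observer"
    obs$set_id <- sub("^L", "O", obs$set_id)

    yrs <- sort(unique(obs$year))
    year_eff <- setNames(rnorm(length(yrs), sd = truth$year_sd),
                         as.character(yrs))
    ves <- sort(unique(obs$vessel_id))
    vessel_eff <- setNames(rnorm(length(ves), sd = truth$vessel_sd), ves)
    xy <- to_planar(domain, obs$lon, obs$lat)
    field <- numeric(n_obs)
    for (y in yrs) {
      i <- which(obs$year == y)
      field[i] <- field_sampler(y, xy[i, , drop = FALSE])
    }
    eta0 <- truth$water_temp_slope * (obs$water_temp - 25) +
      truth$season_effects[obs$season] +
      truth$target_effects[obs$target] +
      truth$set_time_effects[obs$set_time] +
      year_eff[as.character(obs$year)] +
      vessel_eff[obs$vessel_id] +
      field
    if (is.null(intercept)) {
      intercept <- uniroot(function(a)
        mean(plogis(a + eta0)) - truth$base_positive_frac,
        c(-30, 10), tol = 1e-10)$root
    }
    p <- plogis(intercept + eta0)
    z <- rbinom(n_obs, 1, p)
    log_lambda <- truth$log_lambda_intercept +
      truth$n_hooks_slope * (obs$n_hooks - 717) +
      truth$haul_time_effects[obs$haul_time]
    obs$bycatch <- 0L
    pos <- which(z == 1L)
    if (length(pos))
      obs$bycatch[pos] <- rztpois(length(pos), exp(log_lambda[pos]))
    obs[paste0("catch_", TARGETS)] <- NULL
    rownames(obs) <- NULL
    attr(obs, "truth_realisation") <- list(
      intercept = intercept, year_effects = year_eff,
      vessel_effects = vessel_eff,
      field_centers = attr(field_sampler, "centers"))
    attr(obs, "p") <- p
    obs
  })
}

#' Write set records as UTF-8 CSV
#' @param records set-record data.frame.
#' @param path output path.
#' @export
write_sets_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
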