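#' Generate a synthetic annual climate-index series
#'
#' AR(1) series with unit marginal variance, standing in for an annual
#' oceanographic index such as the latitudinal position of a western-boundary
#' current front. The default autocorrelation (0.3) gives the moderate
#' year-to-year persistence typical of such indices without inducing strong
#' spurious correlation at neighbouring lags.
#'
#' @param years integer vector of contiguous years (at least 8).
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @return a `climate_series` data.frame with columns `year` and `value`.
#' @export
gen_climate_series <- function(years, phi = 0.3, seed = 1L) {
  years <- as.integer(years)
  if (length(years) < 8) stop("climate series needs at least 8 years")
  if (any(diff(years) != 1L)) stop("years must be contiguous")
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  n <- length(years)
  value <- with_seed(seed, {
    innov_sd <- sqrt(1 - phi^2)  # unit marginal variance
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + rnorm(1, sd = innov_sd)
    x
  })
  structure(data.frame(year = years, value = value),
            class = c("climate_series", "data.frame"))
}

#' Write a climate series as a two-column CSV
#' @param series a `climate_series`.
#' @param path output path.
#' @export
write_climate_csv <- function(series, path) {
  write.csv(as.data.frame(series)[, c("year", "value")], path,
            row.names = FALSE)
  invisible(path)
}
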