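#' Annual bycatch hotspot from a year-replicated spatial fit
#'
#' The hotspot of a year is the in-domain mesh node maximising the posterior
#' mean of that year's spatial-effect replicate. Years flagged as having zero
#' positive bycatch in training return a missing location, matching the
#' convention of dropping zero-bycatch years from hotspot tracks. Exact ties
#' are broken by the lowest node index, so the extraction is deterministic
#' and invariant to adding a constant to the field.
#'
#' @param fit a `latent_fit` whose design has a year-replicated spatial term.
#' @param domain the `domain_spec`.
#' @param year the year to extract.
#' @param zero_bycatch_years integer years with no positive bycatch (hotspot
#'   undefined).
#' @return one-row data.frame: year, lon, lat, value, missing.
#' @export
annual_hotspot <- function(fit, domain, year, zero_bycatch_years = integer()) {
  b <- fit$design$blocks[["field"]]
  if (is.null(b) || b$n_years == 1L)
    stop("fit has no year-replicated spatial term")
  if (!(year %in% b$years)) stop("year outside fitted range")
  if (year %in% zero_bycatch_years) {
    return(data.frame(year = year, lon = NA_real_, lat = NA_real_,
                      value = NA_real_, missing = TRUE))
  }
  nn <- nrow(b$mesh$nodes)
  k <- match(year, b$years)
  cols <- b$cols[(k - 1L) * nn + seq_len(nn)]
  mu <- latent_mean(fit)[cols]
  ll <- from_planar(domain, b$mesh$nodes[, 1], b$mesh$nodes[, 2])
  inside <- point_in_poly(domain$boundary, ll[, 1], ll[, 2]) &
    !in_barrier(domain, ll[, 1], ll[, 2])
  if (!any(inside)) stop("no in-domain mesh nodes")
  cand <- which(inside)
  best <- cand[which.max(mu[cand])]    # which.max returns the first maximum
  data.frame(year = year, lon = ll[best, 1], lat = ll[best, 2],
             value = mu[best], missing = FALSE)
}

#' Hotspot track over all fitted years
#'
#' @inheritParams annual_hotspot
#' @return data.frame with one row per fitted year (class `hotspot_track`).
#' @export
hotspot_track <- function(fit, domain, zero_bycatch_years = integer()) {
  b <- fit$design$blocks[["field"]]
  if (is.null(b) || b$n_years == 1L)
    stop("fit has no year-replicated spatial term")
  out <- do.call(rbind, lapply(b$years, function(y)
    annual_hotspot(fit, domain, y, zero_bycatch_years)))
  class(out) <- c("hotspot_track", "data.frame")
  out
}

#' Lagged cross-correlation between hotspot latitude and a climate index
#'
#' For each lag `k` in `0..max_lag`, computes the Pearson correlation between
#' hotspot latitude in year `t` and the index in year `t - k`, over year
#' pairs where both exist (pairwise deletion of missing hotspot years).
#' A lag is flagged significant when `|r| > 1.96 / sqrt(n)`, the large-sample
#' two-sided 5 percent band; lags with fewer than `min_n` overlapping pairs
#' or zero variance are flagged not computable.
#'
#' @param track a `hotspot_track` (or data.frame with year, lat).
#' @param index a `climate_series`.
#' @param max_lag maximum lag in years.
#' @param min_n minimum overlapping pairs per lag.
#' @return data.frame: lag, r, n, significant, computable.
#' @export
ccf_lagged <- function(track, index, max_lag = 4L, min_n = 8L) {
  out <- lapply(0:max_lag, function(k) {
    ix <- match(track$year - k, index$year)
    ok <- !is.na(ix) & !is.na(track$lat)
    lat <- track$lat[ok]; val <- index$value[ix[ok]]
    n <- sum(ok)
    if (n < min_n || sd(lat) == 0 || sd(val) == 0) {
      return(data.frame(lag = k, r = NA_real_, n = n,
                        significant = FALSE, computable = FALSE))
    }
    r <- cor(lat, val)
    data.frame(lag = k, r = r, n = n,
               significant = abs(r) > 1.96 / sqrt(n), computable = TRUE)
  })
  do.call(rbind, out)
}

#' Write a hotspot track as CSV
#' @param track a `hotspot_track`.
#' @param path output path.
#' @export
write_hotspot_csv <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
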