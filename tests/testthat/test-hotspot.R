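# a minimal fake year-field fit for argmax checks: two years, known fields
fake_field_fit <- function(mesh, field_by_year, years = c(2001L, 2002L)) {
  nn <- nrow(mesh$nodes)
  u <- unlist(field_by_year)
  p <- 1L + length(u)
  design <- list(p = p, blocks = list(
    intercept = list(name = "intercept", type = "fixed", cols = 1L,
                     hyper = character()),
    field = list(name = "field", type = "spde",
                 cols = 1L + seq_along(u), hyper = c("log_range",
                                                     "log_sigma"),
                 mesh = mesh, n_years = length(years), years = years)))
  structure(list(design = design, weights = 1,
                 modes = list(c(-5, u)),
                 theta = matrix(0, 1, 2,
                                dimnames = list(NULL, c("log_range",
                                                        "log_sigma")))),
            class = "latent_fit")
}

test_that("annual hotspot is the argmax node, with deterministic tie-breaking", {
  mesh <- build_mesh(fix_domain, 200, 600, 150)
  nn <- nrow(mesh$nodes)
  ll <- from_planar(fix_domain, mesh$nodes[, 1], mesh$nodes[, 2])
  inside <- point_in_poly(fix_domain$boundary, ll[, 1], ll[, 2]) &
    !in_barrier(fix_domain, ll[, 1], ll[, 2])
  # planted Gaussian bump centred on an interior sea node
  target <- which(inside)[which.min((ll[inside, 1] + 70)^2 +
                                      (ll[inside, 2] - 36)^2)]
  d2 <- rowSums((mesh$nodes - rep(mesh$nodes[target, ],
                                  each = nn))^2)
  bump <- 2 * exp(-d2 / (2 * 200^2))
  flat <- rep(0.25, nn)
  fit <- fake_field_fit(mesh, list(bump, flat))
  h1 <- annual_hotspot(fit, fix_domain, 2001L)
  expect_equal(c(h1$lon, h1$lat), unname(ll[target, ]), tolerance = 1e-9)
  # adding a constant leaves the argmax unchanged
  fit_shift <- fake_field_fit(mesh, list(bump + 7, flat))
  h1b <- annual_hotspot(fit_shift, fix_domain, 2001L)
  expect_equal(h1b[c("lon", "lat")], h1[c("lon", "lat")])
  # exactly tied maxima resolve to the lowest node index, stably
  h2 <- annual_hotspot(fit, fix_domain, 2002L)
  h2b <- annual_hotspot(fit, fix_domain, 2002L)
  expect_identical(h2, h2b)
  expect_equal(which(inside)[1],
               nearest_node(mesh, to_planar(fix_domain, h2$lon,
                                            h2$lat)[1],
                            to_planar(fix_domain, h2$lon, h2$lat)[2]))
  # zero-bycatch years are missing; out-of-range years error
  hm <- annual_hotspot(fit, fix_domain, 2001L, zero_bycatch_years = 2001L)
  expect_true(hm$missing)
  expect_error(annual_hotspot(fit, fix_domain, 1999L), "outside")
})

test_that("lagged cross-correlation detects a pure 2-year shift and flags degenerate inputs", {
  idx <- gen_climate_series(1990:2015, phi = 0.4, seed = 61)
  track <- data.frame(year = 1992:2015,
                      lat = idx$value[match(1992:2015 - 2, idx$year)])
  cc <- ccf_lagged(track, idx, max_lag = 4)
  expect_equal(cc$r[cc$lag == 2], 1, tolerance = 1e-12)
  expect_true(cc$significant[cc$lag == 2])
  # constant latitude: not computable
  track0 <- data.frame(year = 1992:2015, lat = 36)
  cc0 <- ccf_lagged(track0, idx)
  expect_true(all(!cc0$computable))
  expect_true(all(!cc0$significant))
  # insufficient overlap flagged per lag
  short <- data.frame(year = 2010:2015, lat = rnorm(6))
  ccs <- ccf_lagged(short, idx, max_lag = 2)
  expect_true(all(!ccs$computable))
})

test_that("lag-0 false-positive rate of the CCF band is near nominal for white noise", {
  hits <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    sig <- with_seed(1000 + r, {
      track <- data.frame(year = 1992:2013, lat = rnorm(22))
      idx <- data.frame(year = 1992:2013, value = rnorm(22))
      ccf_lagged(track, idx, max_lag = 0)$significant[1]
    })
    hits <- hits + sig
  }
  rate <- hits / n_rep
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.10)
})
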