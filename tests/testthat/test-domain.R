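test_that("domain generation is deterministic in the seed and zones tile the boundary", {
  d1 <- gen_domain(1); d2 <- gen_domain(1); d3 <- gen_domain(2)
  expect_identical(d1$barriers, d2$barriers)
  expect_identical(d1$zones, d2$zones)
  expect_false(identical(d1$barriers$coast, d3$barriers$coast))
  # every zone vertex inside (or on) the boundary box
  bnd <- d1$boundary
  for (z in d1$zones) {
    expect_true(all(z[, 1] >= min(bnd[, 1]) & z[, 1] <= max(bnd[, 1])))
    expect_true(all(z[, 2] >= min(bnd[, 2]) & z[, 2] <= max(bnd[, 2])))
  }
  # zones do not overlap: a probe grid falls in at most one zone
  probe <- expand.grid(lon = seq(-79.9, -64.1, by = 0.7),
                       lat = seq(30.1, 41.9, by = 0.7))
  counts <- Reduce(`+`, lapply(d1$zones, function(z)
    as.integer(point_in_poly(z, probe$lon, probe$lat))))
  expect_true(all(counts <= 1))
})

test_that("planar projection round-trips and zone lookup matches generation", {
  xy <- to_planar(fix_domain, c(-75, -70.2), c(31, 41.5))
  ll <- from_planar(fix_domain, xy[, 1], xy[, 2])
  expect_equal(as.vector(ll[, 1]), c(-75, -70.2), tolerance = 1e-12)
  expect_equal(as.vector(ll[, 2]), c(31, 41.5), tolerance = 1e-12)
  expect_equal(zone_of(fix_domain, -75, 36), "MAB")
  expect_equal(zone_of(fix_domain, -66, 32), "SAR")
})

test_that("domain GeoJSON round-trips through jsonlite", {
  tf <- tempfile(fileext = ".geojson")
  write_domain_geojson(fix_domain, tf)
  gj <- jsonlite::read_json(tf)
  expect_equal(gj$type, "FeatureCollection")
  kinds <- vapply(gj$features, function(f) f$properties$kind, "")
  expect_true(all(c("boundary", "barrier", "zone") %in% kinds))
})
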