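# shared fixtures built once per test run
fix_domain <- gen_domain(1)

# quiet truth with only a few active effects, for targeted checks
quiet_truth <- function(...) {
  args <- list(season_effects = c(winter = 0, spring = 0, summer = 0,
                                  fall = 0),
               target_effects = c(MIX = 0, SWO = 0, TUN = 0, SHX = 0,
                                  DOL = 0),
               set_time_effects = c(day = 0, night = 0),
               water_temp_slope = 0, year_sd = 0, vessel_sd = 0)
  do.call(truth_params, utils::modifyList(args, list(...)))
}

# small open-water square mesh reused by SPDE tests
fix_mesh10 <- build_rect_mesh(0, 10, 0, 10, 0.9)
fix_fem10 <- assemble_fem(fix_mesh10)

# correlation matrix from a dense inverse of a sparse precision
dense_corr <- function(Q) {
  S <- solve(as.matrix(Q))
  stats::cov2cor(S)
}

nearest_node <- function(mesh, x, y) {
  which.min((mesh$nodes[, 1] - x)^2 + (mesh$nodes[, 2] - y)^2)
}
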