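make_obs <- function(n, seed, eta_fun, lambda_fun = function(df) 1.5) {
  with_seed(seed, {
    df <- data.frame(
      water_temp = runif(n, 10, 30),
      season = sample(c("winter", "spring", "summer", "fall"), n, TRUE),
      n_hooks = round(rnorm(n, 717, 150)),
      haul_time = sample(c("day", "night"), n, TRUE),
      vessel_id = paste0("V", sample.int(8, n, TRUE)))
    z <- rbinom(n, 1, plogis(eta_fun(df)))
    df$bycatch <- ifelse(z == 1, seabycatch:::rztpois(n, lambda_fun(df)), 0L)
    df
  })
}

test_that("categorical effects are sum-to-zero coded and RW1 has rank m-1", {
  obs <- make_obs(400, 1, function(df) -1 + 0.5 * (df$season == "summer"))
  des <- build_design(obs, model_terms(factors = "season",
                                       smooths = "water_temp"),
                      "occurrence")
  bs <- des$blocks$season
  expect_equal(length(bs$levels), 4L)
  expect_equal(nrow(bs$Z), 4L)           # 4 level effects ...
  expect_equal(colSums(bs$Z), rep(0, 3), tolerance = 1e-12)  # ... sum to zero
  rw <- des$blocks$water_temp
  # reduced-rank parametrisation of the rank-19 RW1 structure on 20 bins
  expect_equal(length(rw$cols), 19L)
  expect_equal(qr(as.matrix(rw$R))$rank, 19L)
  expect_error(build_design(obs, model_terms(factors = "nope"),
                            "occurrence"), "unknown covariate")
})

test_that("intercept-only occurrence mode matches the analytic MLE at study scale", {
  rec <- data.frame(bycatch = c(rep(1L, 92), rep(0L, 19811 - 92)))
  fit <- fit_bernoulli(build_design(rec, model_terms(), "occurrence"))
  expect_lt(abs(latent_mean(fit) - qlogis(92 / 19811)), 0.02)
  expect_true(fit$converged)
})

test_that("intercept-only positive model solves the truncated-mean equation", {
  # counts with the study's positive mean of 165/92 birds per positive set
  y <- c(rep(1, 45), rep(2, 27), rep(3, 14), rep(4, 6))
  expect_equal(mean(y), 165 / 92, tolerance = 1e-3)
  rec <- data.frame(bycatch = y)
  fit <- fit_ztpoisson(build_design(rec, model_terms(), "positive"))
  lam_hat <- exp(latent_mean(fit))
  lam_oracle <- uniroot(function(l) l / (1 - exp(-l)) - mean(y),
                        c(1e-8, 50))$root
  expect_lt(abs(lam_hat - lam_oracle), 0.01)
  expect_error(build_design(data.frame(bycatch = c(0L, 2L)), model_terms(),
                            "positive"), NA)  # zero rows dropped, not error
  des_bad <- build_design(data.frame(bycatch = c(1L, 2L)), model_terms(),
                          "positive")
  des_bad$y <- c(0, 2)
  expect_error(fit_ztpoisson(des_bad), ">= 1")
})

test_that("all-ones positive counts push lambda to the boundary and are signalled", {
  rec <- data.frame(bycatch = rep(1L, 60))
  expect_warning(fit <- fit_ztpoisson(build_design(rec, model_terms(),
                                                   "positive")),
                 "boundary")
  expect_lt(latent_mean(fit), -5)   # lambda -> 0+
})

test_that("complete separation in the occurrence model is signalled", {
  rec <- data.frame(bycatch = c(rep(1L, 30), rep(0L, 30)),
                    x = c(rep(10, 30), rep(0, 30)))
  des <- build_design(rec, model_terms(linears = "x"), "occurrence")
  # with an essentially flat prior the mode is unbounded; a stringent
  # tolerance keeps the optimiser walking outward until the linear-predictor
  # guard fires
  expect_warning(fit_bernoulli(des, prior_spec(fixed_sd = 1e8),
                               fit_control(max_iter = 200L, tol = 1e-16)),
                 "separation")
})

test_that("Laplace posterior matches a long-run Metropolis oracle on a small model", {
  obs <- make_obs(1200, 7, function(df) -0.5 - 0.15 * (df$water_temp - 20))
  des <- build_design(obs, model_terms(linears = "water_temp"), "occurrence")
  fit <- fit_bernoulli(des)
  X <- as.matrix(des$X); y <- des$y
  lpost <- function(b) sum(y * (X %*% b) - log1p(exp(X %*% b))) +
    sum(dnorm(b, 0, 31.6, log = TRUE))
  # random-walk Metropolis with a proposal scaled to the Laplace sd
  prop_sd <- 1.7 * latent_sd(fit, 1:2)
  set.seed(99)
  n_iter <- 300000L
  b <- latent_mean(fit); lp <- lpost(b); chain <- matrix(0, n_iter, 2)
  for (i in seq_len(n_iter)) {
    prop <- b + rnorm(2, 0, prop_sd)
    lp2 <- lpost(prop)
    if (log(runif(1)) < lp2 - lp) { b <- prop; lp <- lp2 }
    chain[i, ] <- b
  }
  keep <- chain[20001:n_iter, ]
  mc_mean <- colMeans(keep); mc_sd <- apply(keep, 2, sd)
  la_mean <- latent_mean(fit); la_sd <- latent_sd(fit, 1:2)
  expect_lt(max(abs(la_mean - mc_mean) / mc_sd), 0.05)
  expect_lt(max(abs(la_sd - mc_sd) / mc_sd), 0.15)
})

test_that("year-replicated fields permute with the year labels of the data", {
  truth <- quiet_truth(base_positive_frac = 0.04, field_sd = 1.25,
                       hotspot_slope = 0, hotspot_lat_noise_sd = 1.5)
  years <- 2000:2003
  climate <- gen_climate_series(1996:2003, seed = 21)
  fleet <- gen_fleet(fix_domain, truth, 2400, years, seed = 22)
  sampler <- make_bump_field_sampler(fix_domain, truth, climate, years,
                                     seed = 23)
  obs <- gen_observer_data(fleet, truth, sampler, fix_domain, coverage = 1,
                           seed = 24)
  mesh <- build_mesh(fix_domain, 220, 660, 150)
  ctl <- fit_control(optim_maxit = 6L, grid_halfwidth = 1L)
  fit1 <- fit_bernoulli(build_design(obs, model_terms(spatial = "year"),
                                     "occurrence", mesh = mesh,
                                     domain = fix_domain), control = ctl)
  # swap two year labels and refit: the fitted replicates swap too
  perm <- c(2000L, 2001L, 2003L, 2002L)
  obs2 <- obs; obs2$year <- perm[match(obs$year, years)]
  fit2 <- fit_bernoulli(build_design(obs2, model_terms(spatial = "year"),
                                     "occurrence", mesh = mesh,
                                     domain = fix_domain), control = ctl)
  nn <- nrow(mesh$nodes)
  fld <- function(fit, k) {
    b <- fit$design$blocks$field
    latent_mean(fit)[b$cols[(k - 1L) * nn + seq_len(nn)]]
  }
  expect_equal(fld(fit1, 3), fld(fit2, 4), tolerance = 0.05)
  expect_equal(fld(fit1, 4), fld(fit2, 3), tolerance = 0.05)
})
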