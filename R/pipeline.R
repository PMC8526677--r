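#' Configuration of an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline: the master seed (fanned out to
#' per-stage seeds by a fixed counter scheme), problem sizes, ground-truth
#' generator parameters, mesh resolution, the candidate terms offered to
#' stepwise selection, prediction and scenario settings, and the output
#' directory. Defaults give a desk-scale run that exercises every stage.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param years years of the emulated study period.
#' @param n_fleet logbook sets to generate.
#' @param coverage observer coverage fraction.
#' @param truth a `truth_params`.
#' @param mesh_edge_inner,mesh_edge_outer,mesh_ext mesh resolution (km).
#' @param n_draws posterior draws for prediction.
#' @param scenario_sets,scenario_reps mitigation scenario size; `scenario_reps
#'   = 0` skips the mitigation stage.
#' @param subregion_zones zones of the high-bycatch subregion refit with a
#'   year-replicated field for hotspot extraction.
#' @param max_lag maximum climate lag tested.
#' @param select_spatial spatial candidates offered in the final selection
#'   step (`"const"`, `"year"` or both).
#' @param dic_draws posterior draws used for DIC/WAIC during selection.
#' @param control a [fit_control()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "seabycatch_run",
                       years = 2000:2015, n_fleet = 60000L, coverage = 0.08,
                       truth = truth_params(),
                       mesh_edge_inner = 120, mesh_edge_outer = 360,
                       mesh_ext = 200,
                       n_draws = 300L,
                       scenario_sets = 500L, scenario_reps = 100L,
                       subregion_zones = c("SAB", "MAB", "NEC"),
                       max_lag = 4L,
                       select_spatial = "const",
                       dic_draws = 200L,
                       control = fit_control(optim_maxit = 20L)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, years = years,
                 n_fleet = as.integer(n_fleet), coverage = coverage,
                 truth = truth, mesh_edge_inner = mesh_edge_inner,
                 mesh_edge_outer = mesh_edge_outer, mesh_ext = mesh_ext,
                 n_draws = as.integer(n_draws),
                 scenario_sets = as.integer(scenario_sets),
                 scenario_reps = as.integer(scenario_reps),
                 subregion_zones = subregion_zones,
                 max_lag = as.integer(max_lag),
                 select_spatial = select_spatial,
                 dic_draws = as.integer(dic_draws),
                 control = control),
            class = "run_config")
}

config_yaml <- function(config, path) {
  ser <- config
  ser$truth <- unclass(ser$truth)
  ser$control <- unclass(ser$control)
  yaml::write_yaml(lapply(unclass(ser), function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x) || is.list(x)) x
    else as.character(x)), path)
  invisible(path)
}

#' Validate a set-records file
#'
#' Reads a delimited set-record table and reports per-column missingness and
#' rule violations: missing position, non-positive hook counts, and (when a
#' domain is given) positions outside the study domain or on land. Rows
#' failing any required check are excluded and counted by reason.
#'
#' @param path CSV file of set records.
#' @param domain optional `domain_spec` for position checks.
#' @return a list: `n_total`, `n_retained`, `n_excluded`, `reasons` (named
#'   counts), `missingness` (per-column NA counts), and `records` (the
#'   retained rows).
#' @export
validate_inputs <- function(path, domain = NULL) {
  rec <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("unreadable records file: ",
                                           conditionMessage(e)))
  required <- c("set_id", "year", "season", "lon", "lat", "target",
                "n_hooks", "vessel_id")
  miss_col <- setdiff(required, names(rec))
  if (length(miss_col) > 0)
    stop("missing required column(s): ", paste(miss_col, collapse = ", "))
  reasons <- c(missing_position = 0L, bad_hooks = 0L, out_of_domain = 0L,
               missing_required = 0L)
  bad <- rep(FALSE, nrow(rec))
  mp <- is.na(rec$lon) | is.na(rec$lat)
  reasons["missing_position"] <- sum(mp); bad <- bad | mp
  bh <- !is.na(rec$n_hooks) & rec$n_hooks < 1
  reasons["bad_hooks"] <- sum(bh & !bad); bad <- bad | bh
  other_req <- setdiff(required, c("lon", "lat", "n_hooks"))
  mr <- rowSums(is.na(rec[other_req])) > 0
  reasons["missing_required"] <- sum(mr & !bad); bad <- bad | mr
  if (!is.null(domain)) {
    od <- rep(FALSE, nrow(rec))
    idx <- which(!mp)
    od[idx] <- !point_in_poly(domain$boundary, rec$lon[idx], rec$lat[idx]) |
      in_barrier(domain, rec$lon[idx], rec$lat[idx])
    reasons["out_of_domain"] <- sum(od & !bad); bad <- bad | od
  }
  list(n_total = nrow(rec), n_retained = sum(!bad), n_excluded = sum(bad),
       reasons = reasons,
       missingness = colSums(is.na(rec)),
       records = rec[!bad, , drop = FALSE])
}

#' Run the full pipeline: generate, mesh, fit/select, predict, hotspot,
#' mitigate
#'
#' Executes every stage with seeds fanned out from the master seed, writes
#' all artifacts (CSV tables, GeoJSON geometry, mesh JSON, precision matrix
#' in Matrix-Market format, selection trace, aggregate estimates, hotspot
#' track, cross-correlation table, scenario summaries) under
#' `config$out_dir`, and returns a machine-readable report. The report's
#' `checksum` field is the md5 of all artifact checksums, so two runs with
#' the same configuration can be compared bit-for-bit; stage timings are
#' reported but excluded from the checksum. Any stage failure aborts with
#' the stage name; partial outputs are preserved.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly also written to `report.json`.
#' @export
run_pipeline <- function(config) {
  required <- c("seed", "out_dir", "years", "n_fleet", "coverage", "truth",
                "mesh_edge_inner", "mesh_edge_outer", "mesh_ext", "n_draws",
                "scenario_sets", "scenario_reps", "subregion_zones",
                "max_lag", "select_spatial", "dic_draws", "control")
  missing_keys <- setdiff(required, names(config)[!vapply(config, is.null,
                                                          TRUE)])
  if (length(missing_keys) > 0)
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  timings <- list()
  artifacts <- character(0)
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", out, ")", call. = FALSE))
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    res
  }
  pth <- function(f) file.path(out, f)

  # -- simulate ---------------------------------------------------------------
  sim <- t_stage("simulate", {
    domain <- gen_domain(stage_seed(config$seed, 1L))
    climate <- gen_climate_series(
      (min(config$years) - config$truth$hotspot_lag):max(config$years),
      phi = config$truth$climate_phi, seed = stage_seed(config$seed, 2L))
    fleet <- gen_fleet(domain, config$truth, config$n_fleet, config$years,
                       seed = stage_seed(config$seed, 3L))
    sampler <- make_bump_field_sampler(domain, config$truth, climate,
                                       config$years,
                                       seed = stage_seed(config$seed, 4L))
    observer <- gen_observer_data(fleet, config$truth, sampler, domain,
                                  coverage = config$coverage,
                                  seed = stage_seed(config$seed, 5L))
    write_domain_geojson(domain, pth("domain.geojson"))
    write_climate_csv(climate, pth("climate.csv"))
    write_sets_csv(fleet, pth("fleet.csv"))
    write_sets_csv(observer, pth("observer.csv"))
    config_yaml(config, pth("config.yaml"))
    artifacts <- c(artifacts, "domain.geojson", "climate.csv", "fleet.csv",
                    "observer.csv")
    list(domain = domain, climate = climate, fleet = fleet,
         observer = observer, sampler = sampler)
  })

  # -- mesh -------------------------------------------------------------------
  mesh <- t_stage("mesh", {
    m <- build_mesh(sim$domain, config$mesh_edge_inner,
                    config$mesh_edge_outer, config$mesh_ext)
    write_mesh_json(m, pth("mesh.json"))
    fem <- assemble_fem(m)
    Q <- precision_barrier(fem, m, field_params(
      config$truth$field_range_km, config$truth$field_sd))
    write_mtx(Q, pth("precision_barrier.mtx"))
    artifacts <- c(artifacts, "mesh.json", "precision_barrier.mtx")
    m
  })

  # -- fit / select -----------------------------------------------------------
  sel <- t_stage("select", {
    prob_cand <- list(list(term = "water_temp", type = "smooth"),
                      list(term = "season", type = "factor"),
                      list(term = "target", type = "factor"),
                      list(term = "year", type = "factor"),
                      list(term = "set_time", type = "factor"),
                      list(term = "vessel", type = "vessel"))
    prob_cand <- c(prob_cand, lapply(config$select_spatial, function(s)
      list(term = s, type = "spatial")))
    pos_cand <- list(list(term = "n_hooks", type = "smooth"),
                     list(term = "haul_time", type = "factor"))
    s <- stepwise_select(sim$observer, prob_cand, pos_cand,
                         priors = prior_spec(), mesh = mesh,
                         domain = sim$domain,
                         n_draws = config$dic_draws,
                         seed = stage_seed(config$seed, 6L),
                         control = config$control)
    write_trace_csv(s$trace, pth("selection_trace.csv"))
    artifacts <- c(artifacts, "selection_trace.csv")
    s
  })

  # -- predict ----------------------------------------------------------------
  pred <- t_stage("predict", {
    draws <- posterior_draws(sel$prob_fit, sel$pos_fit, config$n_draws,
                             seed = stage_seed(config$seed, 7L))
    E <- expected_bycatch_per_set(draws, sim$fleet,
                                  seed = stage_seed(config$seed, 8L))
    aggs <- list()
    for (g in c("total", "year", "zone", "season", "target")) {
      aggs[[g]] <- aggregate_bycatch(E, sim$fleet, g)
      write.csv(aggs[[g]], pth(paste0("bycatch_", g, ".csv")),
                row.names = FALSE)
      artifacts <- c(artifacts, paste0("bycatch_", g, ".csv"))
    }
    list(draws = draws, E = E, aggs = aggs)
  })

  # -- hotspot / climate ------------------------------------------------------
  hot <- t_stage("hotspot", {
    sub <- sim$observer[sim$observer$zone %in% config$subregion_zones, ]
    terms_t <- sel$prob_terms
    terms_t$spatial <- "year"
    terms_t$factors <- setdiff(terms_t$factors, "year")
    des <- build_design(sub, terms_t, "occurrence", mesh = mesh,
                        domain = sim$domain)
    fit_t <- fit_bernoulli(des, prior_spec(), config$control)
    zero_years <- setdiff(sort(unique(sub$year)),
                          sort(unique(sub$year[sub$bycatch > 0])))
    track <- hotspot_track(fit_t, sim$domain, zero_years)
    ccf <- ccf_lagged(track, sim$climate, max_lag = config$max_lag)
    write_hotspot_csv(track, pth("hotspot_track.csv"))
    write.csv(ccf, pth("ccf.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "hotspot_track.csv", "ccf.csv")
    list(track = track, ccf = ccf, zero_years = zero_years)
  })

  # -- mitigate ---------------------------------------------------------------
  mit <- t_stage("mitigate", {
    if (config$scenario_reps == 0L) {
      report$stages$mitigate <- "skipped (scenario_reps = 0)"
      NULL
    } else {
      surface <- hotspot_mask(bycatch_surface(pred$E, sim$fleet, sim$domain))
      scen <- default_scenarios(n_sets = config$scenario_sets,
                                n_reps = config$scenario_reps)
      results <- lapply(scen, function(sp)
        run_scenario(sim$fleet, pred$E, pred$draws, sp, surface, sim$domain,
                     seed = stage_seed(config$seed, 9L + sp$id)))
      tab <- summarize_scenarios(results)
      write.csv(tab, pth("scenario_summary.csv"), row.names = FALSE)
      artifacts <- c(artifacts, "scenario_summary.csv")
      list(results = results, summary = tab)
    }
  })

  sums <- tools::md5sum(file.path(out, artifacts))
  names(sums) <- artifacts
  report$artifacts <- as.list(sums)
  report$checksum <- tools::md5sum(
    {tf <- tempfile(); writeLines(paste(artifacts, sums), tf); tf})[[1]]
  report$selected_prob_terms <- terms_label(sel$prob_terms)
  report$selected_pos_terms <- terms_label(sel$pos_terms)
  report$total_bycatch <- pred$aggs$total$mean
  report$total_bycatch_cv <- pred$aggs$total$cv
  report$observed_positive_share <-
    mean(sim$observer$bycatch > 0)
  lag2 <- hot$ccf[hot$ccf$lag == min(2, config$max_lag), ]
  report$ccf_lag2_r <- lag2$r
  report$ccf_lag2_significant <- lag2$significant
  if (!is.null(mit)) {
    by_tab <- mit$summary[mit$summary$metric == "pct_bycatch", ]
    report$scenario_bycatch_pct <-
      setNames(as.list(by_tab$mean), paste0("scenario_", by_tab$scenario))
  }
  report$timings <- timings
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(report)
}
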