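# Shared settings for the numbered analysis drivers. Every driver is
# independently runnable: stages are deterministic functions of the master
# seed, so each script regenerates what it needs instead of deserialising
# model objects.

library(seabycatch)

MASTER_SEED <- 20260919L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# study-scale emulation: 26 years, 250k logbook sets, 8% observer coverage
# (~20k observer sets, ~95 positive), 5000-set scenarios; repetitions and
# posterior draws reduced to desk scale
analysis_config <- function() {
  run_config(seed = MASTER_SEED, out_dir = file.path(RESULTS_DIR, "pipeline"),
             years = 1992:2017, n_fleet = 250000L, coverage = 0.08,
             n_draws = 200L, scenario_sets = 5000L, scenario_reps = 100L)
}

simulated_inputs <- function(cfg = analysis_config()) {
  domain <- gen_domain(stage_seed(cfg$seed, 1L))
  climate <- gen_climate_series(
    (min(cfg$years) - cfg$truth$hotspot_lag):max(cfg$years),
    phi = cfg$truth$climate_phi,
    seed = stage_seed(cfg$seed, 2L))
  fleet <- gen_fleet(domain, cfg$truth, cfg$n_fleet, cfg$years,
                     seed = stage_seed(cfg$seed, 3L))
  sampler <- make_bump_field_sampler(domain, cfg$truth, climate, cfg$years,
                                     seed = stage_seed(cfg$seed, 4L))
  observer <- gen_observer_data(fleet, cfg$truth, sampler, domain,
                                coverage = cfg$coverage,
                                seed = stage_seed(cfg$seed, 5L))
  list(cfg = cfg, domain = domain, climate = climate, fleet = fleet,
       sampler = sampler, observer = observer)
}
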