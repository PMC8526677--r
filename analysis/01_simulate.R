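#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the confidential observer-programme and logbook data: a stylised
# East Coast domain with a coastline barrier and six fishing zones, an AR(1)
# climate index, 60,000 logbook sets concentrated in a few zones, and an 8%
# observer sample whose bycatch follows the hurdle model with a climate-
# driven hotspot (lag 2). Writes CSV/GeoJSON under results/data/.

source(file.path("analysis", "common.R"))
out <- file.path(RESULTS_DIR, "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulated_inputs()
write_domain_geojson(sim$domain, file.path(out, "domain.geojson"))
write_climate_csv(sim$climate, file.path(out, "climate.csv"))
write_sets_csv(sim$fleet, file.path(out, "fleet.csv"))
write_sets_csv(sim$observer, file.path(out, "observer.csv"))

n_pos <- sum(sim$observer$bycatch > 0)
cat(sprintf("fleet: %d sets over %d years; observer: %d sets, %d positive (%.2f%%), %d birds\n",
            nrow(sim$fleet), length(sim$cfg$years), nrow(sim$observer),
            n_pos, 100 * mean(sim$observer$bycatch > 0),
            sum(sim$observer$bycatch)))
zs <- sort(prop.table(table(sim$fleet$zone)), decreasing = TRUE)
cat("effort concentration: top five zones hold",
    sprintf("%.1f%%", 100 * sum(zs[1:5])), "of sets\n")

# input validation report on the file we just wrote (all rows should pass)
rep <- validate_inputs(file.path(out, "fleet.csv"), sim$domain)
cat(sprintf("validation: %d rows examined, %d retained, %d excluded\n",
            rep$n_total, rep$n_retained, rep$n_excluded))
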