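#' Hindcast per-set expected-bycatch surface on a grid
#'
#' Averages posterior-mean per-set expected bycatch over the fleet sets
#' falling in each cell of a regular lon/lat grid. Cells with no effort have
#' `NA` value and never enter the hotspot mask.
#'
#' @param E a `bycatch_matrix` for `sets`.
#' @param sets the scored fleet records.
#' @param domain the `domain_spec`.
#' @param cell_deg cell size in degrees.
#' @return data.frame: cell lon/lat centre, x/y (planar km), zone group,
#'   n_sets, value.
#' @export
bycatch_surface <- function(E, sets, domain, cell_deg = 0.5) {
  bnd <- domain$boundary
  lon_b <- seq(min(bnd[, 1]), max(bnd[, 1]), by = cell_deg)
  lat_b <- seq(min(bnd[, 2]), max(bnd[, 2]), by = cell_deg)
  ci <- findInterval(sets$lon, lon_b, all.inside = TRUE)
  cj <- findInterval(sets$lat, lat_b, all.inside = TRUE)
  per_set <- rowMeans(E)
  cells <- expand.grid(i = seq_len(length(lon_b) - 1L),
                       j = seq_len(length(lat_b) - 1L))
  cells$lon <- (lon_b[cells$i] + lon_b[cells$i + 1L]) / 2
  cells$lat <- (lat_b[cells$j] + lat_b[cells$j + 1L]) / 2
  key <- paste(ci, cj); ckey <- paste(cells$i, cells$j)
  agg_n <- table(key)
  agg_v <- tapply(per_set, key, mean)
  cells$n_sets <- as.integer(agg_n[ckey]); cells$n_sets[is.na(cells$n_sets)] <- 0L
  cells$value <- as.numeric(agg_v[ckey])
  xy <- to_planar(domain, cells$lon, cells$lat)
  cells$x <- xy[, 1]; cells$y <- xy[, 2]
  cells$zone <- zone_of(domain, cells$lon, cells$lat)
  cells$group <- domain$zone_groups[cells$zone]
  cells$sea <- !in_barrier(domain, cells$lon, cells$lat) & !is.na(cells$zone)
  cells
}

#' Flag hotspot cells of a bycatch surface
#'
#' Cells with value strictly above the given quantile of the non-missing cell
#' values are flagged as hotspot. A constant surface yields an empty mask
#' with a warning.
#'
#' @param surface data.frame from [bycatch_surface()].
#' @param quantile hotspot quantile (default 0.9: top decile).
#' @return the surface with a logical `hotspot` column.
#' @export
hotspot_mask <- function(surface, quantile = 0.9) {
  vals <- surface$value[!is.na(surface$value)]
  if (length(vals) == 0 || max(vals) == min(vals)) {
    warning("degenerate constant surface: empty hotspot mask")
    surface$hotspot <- FALSE
    return(surface)
  }
  thr <- stats::quantile(vals, quantile, names = FALSE)
  surface$hotspot <- !is.na(surface$value) &
    (if (quantile <= 0) surface$value >= thr else surface$value > thr)
  surface
}

#' Specify a fleet-behaviour scenario
#'
#' The six canonical scenarios: removal of sets from hotspot areas (1), from
#' anywhere in summer-spring (2), or from hotspot areas in summer-through-
#' winter (3); redistribution from hotspots to neighbouring sites at least
#' `min_move_distance` miles from any hotspot cell (4), from summer-winter to
#' spring (5), or from hotspots and summer-winter to spring and distant
#' neighbouring sites (6).
#'
#' @param id scenario id 1..6 (or any label).
#' @param action `"remove"` or `"redistribute"`.
#' @param source `"hotspot_area"`, `"summer_spring"`,
#'   `"hotspot_and_summer_winter"` or `"summer_winter"`.
#' @param destination `NULL` for removal; otherwise
#'   `"neighbor_sites_ge_50mi"`, `"spring_season"` or
#'   `"spring_and_neighbor_sites"`.
#' @param n_sets sets affected per repetition (default 5000).
#' @param n_reps repetitions (default 1000).
#' @param min_move_distance minimum relocation distance from hotspot cells in
#'   miles (default 50).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(id, action = c("remove", "redistribute"),
                          source = c("hotspot_area", "summer_spring",
                                     "hotspot_and_summer_winter",
                                     "summer_winter"),
                          destination = NULL, n_sets = 5000L,
                          n_reps = 1000L, min_move_distance = 50) {
  action <- match.arg(action)
  source <- match.arg(source)
  if (action == "redistribute") {
    if (is.null(destination)) stop("redistribution needs a destination rule")
    destination <- match.arg(destination,
                             c("neighbor_sites_ge_50mi", "spring_season",
                               "spring_and_neighbor_sites"))
  } else if (!is.null(destination)) {
    stop("destination rule only applies to redistribution")
  }
  structure(list(id = id, action = action, source = source,
                 destination = destination, n_sets = as.integer(n_sets),
                 n_reps = as.integer(n_reps),
                 min_move_distance = min_move_distance),
            class = "scenario_spec")
}

#' The six canonical scenarios
#' @param n_sets,n_reps overrides applied to every scenario.
#' @return list of `scenario_spec`.
#' @export
default_scenarios <- function(n_sets = 5000L, n_reps = 1000L) {
  list(
    scenario_spec(1, "remove", "hotspot_area", n_sets = n_sets,
                  n_reps = n_reps),
    scenario_spec(2, "remove", "summer_spring", n_sets = n_sets,
                  n_reps = n_reps),
    scenario_spec(3, "remove", "hotspot_and_summer_winter", n_sets = n_sets,
                  n_reps = n_reps),
    scenario_spec(4, "redistribute", "hotspot_area",
                  destination = "neighbor_sites_ge_50mi", n_sets = n_sets,
                  n_reps = n_reps),
    scenario_spec(5, "redistribute", "summer_winter",
                  destination = "spring_season", n_sets = n_sets,
                  n_reps = n_reps),
    scenario_spec(6, "redistribute", "hotspot_and_summer_winter",
                  destination = "spring_and_neighbor_sites", n_sets = n_sets,
                  n_reps = n_reps))
}

source_rows <- function(fleet, surface, spec) {
  cell_of <- cell_index(fleet, surface)
  in_hot <- surface$hotspot[cell_of]
  in_hot[is.na(in_hot)] <- FALSE
  switch(spec$source,
         hotspot_area = which(in_hot),
         summer_spring = which(fleet$season %in% c("summer", "spring")),
         hotspot_and_summer_winter =
           which(in_hot & fleet$season %in% c("summer", "fall", "winter")),
         summer_winter =
           which(fleet$season %in% c("summer", "fall", "winter")))
}

# map sets to surface cell indices
cell_index <- function(sets, surface) {
  lon_c <- sort(unique(surface$lon)); lat_c <- sort(unique(surface$lat))
  step_lon <- diff(lon_c[1:2]); step_lat <- diff(lat_c[1:2])
  i <- pmin(pmax(round((sets$lon - lon_c[1]) / step_lon) + 1L, 1L),
            length(lon_c))
  j <- pmin(pmax(round((sets$lat - lat_c[1]) / step_lat) + 1L, 1L),
            length(lat_c))
  match(paste(lon_c[i], lat_c[j]), paste(surface$lon, surface$lat))
}

# eligible destination cells: at sea, >= min miles from every hotspot cell,
# split by zone group
eligible_destinations <- function(surface, min_move_miles) {
  hot <- surface[which(surface$hotspot), , drop = FALSE]
  ok <- surface$sea
  if (nrow(hot) > 0) {
    min_km <- min_move_miles * MILES_TO_KM
    d2min <- vapply(seq_len(nrow(surface)), function(i)
      min((surface$x[i] - hot$x)^2 + (surface$y[i] - hot$y)^2), 0)
    ok <- ok & sqrt(d2min) >= min_km
  }
  split(which(ok), surface$group[ok])
}

# k-nearest-neighbour stand-in catch predictor: mean per-species catch among
# same-season, same-target fleet sets nearest to the destination
knn_catch <- function(fleet, fleet_xy, season, target, x, y, k = 25L) {
  rows <- which(fleet$season == season & fleet$target == target)
  if (length(rows) == 0) rows <- which(fleet$target == target)
  if (length(rows) == 0) rows <- seq_len(nrow(fleet))
  d2 <- (fleet_xy[rows, 1] - x)^2 + (fleet_xy[rows, 2] - y)^2
  nn <- rows[order(d2)[seq_len(min(k, length(rows)))]]
  colMeans(fleet[nn, paste0("catch_", TARGETS), drop = FALSE])
}

#' Run one mitigation scenario
#'
#' Per repetition: sample `n_sets` fleet sets without replacement from those
#' matching the source filter (all of them if fewer), then either remove them
#' or relocate each to a uniformly sampled eligible destination cell (at sea,
#' at least `min_move_distance` miles from every hotspot cell, in the same
#' zone group), re-labelling the season to spring where the destination rule
#' says so. Bycatch at new locations/seasons is recomputed with the same
#' posterior draws; catch is predicted by a k-nearest-neighbour stand-in
#' (mean catch of the 25 nearest same-season, same-target sets). Each
#' repetition reports percent changes against the unmodified-fleet baseline;
#' both the set sample and the posterior-draw subsample are refreshed every
#' repetition. Repetitions with no eligible destination are aborted and
#' counted, never silently skipped.
#'
#' @param fleet logbook records with catch columns.
#' @param E baseline `bycatch_matrix` for `fleet`.
#' @param draws the `posterior_draws` used to score `fleet`.
#' @param spec a `scenario_spec`.
#' @param surface hotspot-masked surface from [hotspot_mask()].
#' @param domain the `domain_spec`.
#' @param seed integer seed.
#' @param n_draw_sub posterior-draw subsample size per repetition.
#' @return a `scenario_result`: data.frame of per-repetition percent changes
#'   (`pct_bycatch`, `pct_catch`, `pct_catch_<species>`), with the spec and
#'   the aborted-repetition count as attributes.
#' @export
run_scenario <- function(fleet, E, draws, spec, surface, domain, seed = 1L,
                         n_draw_sub = 50L) {
  stopifnot(inherits(spec, "scenario_spec"))
  pool <- source_rows(fleet, surface, spec)
  valid <- attr(E, "valid"); if (is.null(valid)) valid <- rep(TRUE, nrow(E))
  pool <- intersect(pool, which(valid))
  base_by_draw <- colSums(E[valid, , drop = FALSE])
  catch_cols <- paste0("catch_", TARGETS)
  base_catch <- colSums(fleet[valid, catch_cols])
  base_catch_tot <- sum(base_catch)
  fleet_xy <- to_planar(domain, fleet$lon, fleet$lat)
  dest <- if (spec$action == "redistribute" &&
              spec$destination != "spring_season") {
    eligible_destinations(surface, spec$min_move_distance)
  } else NULL
  move_season <- !is.null(spec$destination) &&
    spec$destination %in% c("spring_season", "spring_and_neighbor_sites")
  move_place <- !is.null(spec$destination) &&
    spec$destination %in% c("neighbor_sites_ge_50mi",
                            "spring_and_neighbor_sites")
  knn_cache <- new.env(parent = emptyenv())
  n_draws <- ncol(E)
  reps <- vector("list", spec$n_reps)
  aborted <- 0L
  for (r in seq_len(spec$n_reps)) {
    one_rep <- function() {
      sel <- if (length(pool) <= spec$n_sets) pool else
        sample(pool, spec$n_sets)
      ds <- sample.int(n_draws, min(n_draw_sub, n_draws), replace = TRUE)
      if (length(sel) == 0) {
        out <- data.frame(rep = r, pct_bycatch = 0, pct_catch = 0)
        for (s in TARGETS) out[[paste0("pct_catch_", s)]] <- 0
        return(out)
      }
      old_by <- colSums(E[sel, ds, drop = FALSE])
      old_catch <- colSums(fleet[sel, catch_cols, drop = FALSE])
      if (spec$action == "remove") {
        new_by <- rep(0, length(ds))
        new_catch <- old_catch * 0
      } else {
        moved <- fleet[sel, , drop = FALSE]
        if (move_place) {
          grp <- domain$zone_groups[moved$zone]
          cells <- integer(nrow(moved))
          for (g in unique(grp)) {
            cand <- dest[[g]]
            if (is.null(cand) || length(cand) == 0) return(NULL)
            rows <- which(grp == g)
            cells[rows] <- cand[sample.int(length(cand), length(rows),
                                           replace = TRUE)]
          }
          moved$lon <- surface$lon[cells]; moved$lat <- surface$lat[cells]
        }
        if (move_season) moved$season <- "spring"
        E_new <- expected_bycatch_per_set(draws, moved,
                                          seed = stage_seed(seed, r))
        new_by <- colSums(E_new[, ds, drop = FALSE])
        # catch predictions are cached per (surface cell, season, target):
        # season-only moves keep their position, so their cell is looked up
        if (!move_place) cells <- cell_index(moved, surface)
        key <- paste(cells, moved$season, moved$target)
        uk <- !duplicated(key)
        for (i in which(uk)) {
          if (is.null(knn_cache[[key[i]]]))
            knn_cache[[key[i]]] <- knn_catch(fleet, fleet_xy,
                                             moved$season[i],
                                             moved$target[i],
                                             surface$x[cells[i]],
                                             surface$y[cells[i]])
        }
        new_catch <- Reduce(`+`, lapply(key, function(kk) knn_cache[[kk]]))
      }
      d_by <- new_by - old_by
      d_catch <- new_catch - old_catch
      pct_by <- ifelse(base_by_draw[ds] > 0, 100 * d_by / base_by_draw[ds], 0)
      out <- data.frame(rep = r,
                        pct_bycatch = mean(pct_by),
                        pct_catch = if (base_catch_tot > 0)
                          100 * sum(d_catch) / base_catch_tot else 0)
      for (s in TARGETS)
        out[[paste0("pct_catch_", s)]] <-
          100 * d_catch[[paste0("catch_", s)]] /
          max(base_catch[[paste0("catch_", s)]], 1)
      out
    }
    res <- with_seed(stage_seed(seed, r), one_rep())
    if (is.null(res)) aborted <- aborted + 1L else reps[[r]] <- res
  }
  out <- do.call(rbind, reps)
  structure(out, spec = spec, aborted = aborted,
            class = c("scenario_result", "data.frame"))
}

#' Summarise scenario results
#'
#' Mean percent change and central 95 percent interval across repetitions for
#' each metric, one block of rows per scenario, ordered by mean bycatch
#' reduction (strongest first).
#'
#' @param results list of `scenario_result`.
#' @return data.frame: scenario, metric, mean, lo95, hi95.
#' @export
summarize_scenarios <- function(results) {
  if (length(results) < 1) stop("need at least one scenario result")
  rows <- lapply(results, function(res) {
    spec <- attr(res, "spec")
    metrics <- setdiff(names(res), "rep")
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(scenario = spec$id, metric = m, mean = mean(res[[m]]),
                 lo95 = quantile(res[[m]], 0.025, names = FALSE),
                 hi95 = quantile(res[[m]], 0.975, names = FALSE),
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  by_order <- tab[tab$metric == "pct_bycatch", ]
  ord <- by_order$scenario[order(by_order$mean)]
  tab$scenario <- factor(tab$scenario, levels = ord)
  tab <- tab[order(tab$scenario, tab$metric), ]
  tab$scenario <- as.character(tab$scenario)
  rownames(tab) <- NULL
  tab
}
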