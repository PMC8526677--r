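#' Published effort and bycatch counts for the monitored fishery
#'
#' Headline counts reported for the 1992-2017 U.S. Atlantic pelagic longline
#' observer programme and logbook database, kept here as plain inputs for
#' arithmetic context checks (effort concentration, zero-bycatch share,
#' scenario share of the database). The underlying set-level data are
#' confidential; only these published totals are recorded.
#'
#' @return a list of named counts.
#' @export
study_counts <- function() {
  list(
    observer_sets = 19811L,
    positive_sets = 92L,
    birds = 165L,
    logbook_sets = 273002L,
    examined_sets = 285589L,
    scenario_sets = 5000L,
    observer_zone_top5 = c(GOM = 9020L, MAB = 3053L, SAB = 2181L,
                           FEC = 2052L, NEC = 1235L),
    logbook_zone_top5 = c(GOM = 95285L, MAB = 48176L, FEC = 39127L,
                          SAB = 33794L, NEC = 20304L))
}

#' Arithmetic shares from published counts
#'
#' Percentage summaries derivable from [study_counts()]: the share of
#' observer sets with zero bycatch, the share of the logbook database
#' affected by a 5000-set scenario, and the effort concentration in the five
#' heaviest-fished zones of each database.
#'
#' @param counts list of counts as from [study_counts()].
#' @return named numeric vector of percentages.
#' @export
count_shares <- function(counts = study_counts()) {
  c(observer_zero_pct =
      100 * (1 - counts$positive_sets / counts$observer_sets),
    scenario_share_pct =
      100 * counts$scenario_sets / counts$logbook_sets,
    observer_top5_pct =
      100 * sum(counts$observer_zone_top5) / counts$observer_sets,
    logbook_top5_pct =
      100 * sum(counts$logbook_zone_top5) / counts$logbook_sets,
    mean_positive_count =
      counts$birds / counts$positive_sets)
}
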