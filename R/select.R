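# fit one sub-model and return fit + criteria
fit_submodel <- function(records, terms, response, priors, mesh, domain,
                         n_draws, seed, control) {
  des <- build_design(records, terms, response, mesh = mesh, domain = domain)
  fit <- if (response == "occurrence") {
    fit_bernoulli(des, priors, control)
  } else {
    fit_ztpoisson(des, priors, control)
  }
  list(fit = fit,
       dic = compute_dic(fit, n_draws, seed),
       waic = compute_waic(fit, n_draws, seed))
}

add_term <- function(terms, cand) {
  if (cand$type == "factor") terms$factors <- c(terms$factors, cand$term)
  else if (cand$type == "linear") terms$linears <- c(terms$linears, cand$term)
  else if (cand$type == "smooth") terms$smooths <- c(terms$smooths, cand$term)
  else if (cand$type == "vessel") terms$vessel <- TRUE
  else if (cand$type == "spatial") terms$spatial <- cand$term
  terms
}

#' Forward stepwise model selection by DIC with the delta-5 rule
#'
#' Starting from intercept-only sub-models, each step tries every remaining
#' candidate term in its sub-model and adds the one with the largest DIC
#' reduction; selection stops when the best reduction falls below `delta`
#' (default 5, the conventional threshold for a significantly better
#' prediction). Spatial-field candidates are tried only after all covariate
#' candidates have settled. The returned trace mirrors the model-ladder
#' layout: one row per accepted model with both sub-models' DIC and WAIC.
#'
#' @param records observer set records (with `bycatch`).
#' @param prob_candidates,pos_candidates lists of candidates for the
#'   occurrence and positive sub-models; each candidate is
#'   `list(term = , type = )` with type one of `"factor"`, `"linear"`,
#'   `"smooth"`, `"vessel"`, `"spatial"` (for spatial, `term` is `"const"`
#'   or `"year"`).
#' @param priors a `prior_spec`.
#' @param mesh,domain needed when spatial candidates are present.
#' @param delta DIC-reduction threshold for accepting a term.
#' @param n_draws posterior draws for DIC/WAIC.
#' @param seed integer seed for criterion draws.
#' @param control a [fit_control()].
#' @return list with `prob_terms`, `pos_terms` (selected `model_terms`),
#'   `prob_fit`, `pos_fit` (final fits), and `trace` (data.frame with
#'   columns model, prob_terms, pos_terms, DIC_z, DIC_y, WAIC_z, WAIC_y).
#' @export
stepwise_select <- function(records, prob_candidates, pos_candidates,
                            priors = prior_spec(), mesh = NULL, domain = NULL,
                            delta = 5, n_draws = 200L, seed = 1L,
                            control = fit_control()) {
  if (length(prob_candidates) + length(pos_candidates) == 0)
    stop("candidate list is empty")
  prob_terms <- model_terms(); pos_terms <- model_terms()
  cur_z <- fit_submodel(records, prob_terms, "occurrence", priors, mesh,
                        domain, n_draws, seed, control)
  cur_y <- fit_submodel(records, pos_terms, "positive", priors, mesh,
                        domain, n_draws, seed, control)
  trace <- data.frame(model = "M0",
                      prob_terms = terms_label(prob_terms),
                      pos_terms = terms_label(pos_terms),
                      DIC_z = cur_z$dic, DIC_y = cur_y$dic,
                      WAIC_z = cur_z$waic, WAIC_y = cur_y$waic,
                      stringsAsFactors = FALSE)
  cands <- c(lapply(prob_candidates, function(cc) c(cc, sub = "prob")),
             lapply(pos_candidates, function(cc) c(cc, sub = "pos")))
  is_spatial <- vapply(cands, function(cc) cc$type == "spatial", TRUE)
  step_no <- 0L
  for (phase in c("covariate", "spatial")) {
    pool <- which(if (phase == "covariate") !is_spatial else is_spatial)
    repeat {
      if (length(pool) == 0) break
      best <- NULL; best_red <- -Inf; best_i <- NA
      for (i in pool) {
        cc <- cands[[i]]
        if (cc$sub == "prob") {
          trial <- fit_submodel(records, add_term(prob_terms, cc),
                                "occurrence", priors, mesh, domain,
                                n_draws, seed, control)
          red <- cur_z$dic - trial$dic
        } else {
          trial <- fit_submodel(records, add_term(pos_terms, cc),
                                "positive", priors, mesh, domain,
                                n_draws, seed, control)
          red <- cur_y$dic - trial$dic
        }
        if (red > best_red) { best_red <- red; best <- trial; best_i <- i }
      }
      if (best_red < delta) break
      cc <- cands[[best_i]]
      if (cc$sub == "prob") { prob_terms <- add_term(prob_terms, cc); cur_z <- best }
      else { pos_terms <- add_term(pos_terms, cc); cur_y <- best }
      step_no <- step_no + 1L
      trace <- rbind(trace, data.frame(
        model = paste0("M", step_no),
        prob_terms = terms_label(prob_terms),
        pos_terms = terms_label(pos_terms),
        DIC_z = cur_z$dic, DIC_y = cur_y$dic,
        WAIC_z = cur_z$waic, WAIC_y = cur_y$waic,
        stringsAsFactors = FALSE))
      # drop the accepted candidate and any other candidate of the same
      # term/sub-model
      pool <- setdiff(pool, which(vapply(cands, function(x)
        x$sub == cc$sub && x$type == cc$type &&
          (x$type %in% c("vessel", "spatial") || x$term == cc$term),
        TRUE)))
      if (cc$type == "spatial")
        pool <- setdiff(pool, which(vapply(cands, function(x)
          x$sub == cc$sub && x$type == "spatial", TRUE)))
    }
  }
  list(prob_terms = prob_terms, pos_terms = pos_terms,
       prob_fit = cur_z$fit, pos_fit = cur_y$fit, trace = trace)
}

#' Write a selection trace as CSV
#' @param trace trace data.frame from [stepwise_select()].
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
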