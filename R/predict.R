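#' Joint posterior draws from both hurdle sub-models
#'
#' Draws `n` latent vectors from each sub-model's Gaussian-mixture
#' approximation (hyperparameter grid point sampled by weight, then the
#' Gaussian at that point). Sub-models are independent given the data, so
#' their draws are paired arbitrarily by index.
#'
#' @param fit_z occurrence-component `latent_fit`.
#' @param fit_y positive-component `latent_fit`.
#' @param n number of draws (default 1000).
#' @param seed integer seed.
#' @return a `posterior_draws` list: `z` and `y` (each with `u`, `k`), the
#'   fits, `n`, `seed`.
#' @export
posterior_draws <- function(fit_z, fit_y, n = 1000L, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  structure(list(z = draw_latent(fit_z, n, stage_seed(seed, 1L)),
                 y = draw_latent(fit_y, n, stage_seed(seed, 2L)),
                 fit_z = fit_z, fit_y = fit_y, n = n,
                 seed = as.integer(seed)),
            class = "posterior_draws")
}

# Build the prediction design matrix for new records against a fitted design.
# Returns X (rows x latent), valid flag (in-mesh), and the columns of unseen
# vessels (0 in X; handled by population draws).
prediction_matrix <- function(design, newdata) {
  n <- nrow(newdata)
  parts <- list()
  valid <- rep(TRUE, n)
  unseen_vessel <- rep(FALSE, n)
  for (b in design$blocks) {
    if (b$type == "fixed") {
      parts[[b$name]] <- Matrix::Matrix(1, n, 1, sparse = TRUE)
    } else if (b$type == "factor") {
      ix <- match(as.character(newdata[[b$name]]), b$levels)
      if (anyNA(ix))
        stop("unseen level in categorical covariate: ", b$name)
      parts[[b$name]] <- Matrix::Matrix(b$Z[ix, , drop = FALSE], sparse = TRUE)
    } else if (b$type == "linear") {
      parts[[b$name]] <- Matrix::Matrix(newdata[[b$name]] - b$center,
                                        n, 1, sparse = TRUE)
    } else if (b$type == "rw1") {
      bin <- findInterval(newdata[[b$name]], b$breaks, all.inside = TRUE)
      parts[[b$name]] <- Matrix::Matrix(b$Z[bin, , drop = FALSE],
                                        sparse = TRUE)
    } else if (b$type == "iid") {
      ix <- match(newdata$vessel_id, b$levels)
      unseen_vessel <- unseen_vessel | is.na(ix)
      ok <- which(!is.na(ix))
      parts[[b$name]] <- Matrix::sparseMatrix(
        i = ok, j = ix[ok], x = 1, dims = c(n, length(b$levels)))
    } else if (b$type == "spde") {
      xy <- to_planar(design$domain, newdata$lon, newdata$lat)
      proj <- make_projector(b$mesh, xy)
      valid <- valid & proj$valid
      nn <- nrow(b$mesh$nodes)
      if (b$n_years == 1L) {
        parts[[b$name]] <- proj$A
      } else {
        yi <- match(newdata$year, b$years)
        if (anyNA(yi)) stop("prediction year outside fitted years")
        Xf <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0),
                                   dims = c(n, nn * b$n_years))
        for (k in sort(unique(yi))) {
          rows <- which(yi == k)
          Xf[rows, (k - 1L) * nn + seq_len(nn)] <-
            proj$A[rows, , drop = FALSE]
        }
        parts[[b$name]] <- Xf
      }
    }
  }
  list(X = do.call(cbind, unname(parts)), valid = valid,
       unseen_vessel = unseen_vessel)
}

# linear predictors for new data under each posterior draw; adds population
# draws for unseen vessels
predict_eta <- function(fit, dr, newdata, seed = 1L) {
  pm <- prediction_matrix(fit$design, newdata)
  eta <- as.matrix(Matrix::crossprod(Matrix::t(pm$X), dr$u))  # n x n_draws
  if (any(pm$unseen_vessel) &&
      any(vapply(fit$design$blocks, function(b) b$type == "iid", TRUE))) {
    has_tau <- "log_tau_vessel" %in% colnames(fit$theta)
    rows <- which(pm$unseen_vessel)
    vess <- unique(newdata$vessel_id[rows])
    eta[rows, ] <- eta[rows, , drop = FALSE] + with_seed(seed, {
      sd_v <- if (has_tau) {
        exp(-fit$theta[dr$k, "log_tau_vessel"] / 2)
      } else rep(0, length(dr$k))
      draw <- matrix(rnorm(length(vess) * length(dr$k)),
                     length(vess)) * rep(sd_v, each = length(vess))
      draw[match(newdata$vessel_id[rows], vess), , drop = FALSE]
    })
    message(length(vess), " unseen vessel(s): effects drawn from the ",
            "population distribution")
  }
  list(eta = eta, valid = pm$valid)
}

#' Per-draw expected bycatch for a collection of sets
#'
#' For each posterior draw and each set, computes the expected bycatch
#' `E[y] = p * lambda / (1 - exp(-lambda))` (occurrence probability times
#' zero-truncated Poisson mean) at the set's covariates and position. Sets
#' outside the mesh are flagged and excluded from totals; unseen vessels get
#' effects drawn from the fitted population distribution (logged via a
#' message).
#'
#' @param draws a `posterior_draws`.
#' @param sets set records (logbook or observer).
#' @param seed seed for unseen-vessel population draws.
#' @return a `bycatch_matrix`: matrix (n_sets x n_draws) of expectations,
#'   with attributes `valid` (logical per set) and `n_excluded`.
#' @export
expected_bycatch_per_set <- function(draws, sets, seed = 1L) {
  pz <- predict_eta(draws$fit_z, draws$z, sets, stage_seed(seed, 3L))
  py <- predict_eta(draws$fit_y, draws$y, sets, stage_seed(seed, 4L))
  p <- plogis(pz$eta)
  lambda <- exp(pmin(py$eta, 30))
  E <- p * zero_truncated_mean(lambda)
  valid <- pz$valid & py$valid
  if (any(!valid))
    message(sum(!valid), " set(s) outside the mesh excluded from totals")
  structure(E, valid = valid, n_excluded = sum(!valid),
            class = c("bycatch_matrix", class(E)))
}

#' Aggregate per-set posterior bycatch expectations
#'
#' Sums expectations within each posterior draw over the members of each
#' group, then summarises across draws (mean, sd, CV = sd/mean). Summing
#' within draw first means group CVs reflect the correlated uncertainty of
#' member sets; totals over disjoint groups add up to the overall total
#' exactly within each draw.
#'
#' @param E a `bycatch_matrix` from [expected_bycatch_per_set()].
#' @param sets the set records scored in `E`.
#' @param group `"year"`, `"zone"`, `"season"`, `"target"` or `"total"`.
#' @return data.frame with group, n_sets, mean, sd, cv.
#' @export
aggregate_bycatch <- function(E, sets,
                              group = c("total", "year", "zone", "season",
                                        "target")) {
  group <- match.arg(group)
  valid <- attr(E, "valid")
  if (is.null(valid)) valid <- rep(TRUE, nrow(E))
  keys <- if (group == "total") rep("total", nrow(sets)) else
    as.character(sets[[group]])
  if (anyNA(keys[valid])) stop("grouping key missing on an included set")
  out <- lapply(sort(unique(keys[valid])), function(g) {
    rows <- which(valid & keys == g)
    per_draw <- colSums(E[rows, , drop = FALSE])
    data.frame(group = g, n_sets = length(rows),
               mean = mean(per_draw), sd = sd(per_draw),
               cv = if (mean(per_draw) > 0) sd(per_draw) / mean(per_draw)
                    else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write per-set bycatch estimates as CSV
#' @param E a `bycatch_matrix`.
#' @param sets matching set records.
#' @param path output path.
#' @export
write_per_set_csv <- function(E, sets, path) {
  df <- data.frame(set_id = sets$set_id,
                   mean = rowMeans(E),
                   sd = apply(E, 1, sd),
                   valid = attr(E, "valid"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
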