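# ---- observation families ---------------------------------------------------

family_bernoulli <- function() {
  list(
    name = "bernoulli",
    loglik = function(y, eta) sum(y * eta - log1p(exp(pmin(eta, 30)))),
    loglik_i = function(y, eta) y * eta - log1p(exp(pmin(eta, 30))),
    grad = function(y, eta) y - plogis(eta),
    weight = function(y, eta) {
      p <- plogis(eta)
      pmax(p * (1 - p), 1e-14)
    })
}

# zero-truncated Poisson with log link on the untruncated rate lambda:
# ll = y*eta - log(expm1(lambda)) - log(y!), score = y - mu with mu the
# truncated mean lambda / (1 - exp(-lambda))
family_ztpoisson <- function() {
  trunc_mean <- function(lambda) lambda / (-expm1(-lambda))
  # log(e^lambda - 1), stable for large lambda
  log_expm1 <- function(lambda) ifelse(lambda > 30, lambda,
                                       log(expm1(lambda)))
  list(
    name = "ztpoisson",
    loglik = function(y, eta) {
      lambda <- exp(pmin(eta, 30))
      sum(y * pmin(eta, 30) - log_expm1(lambda) - lgamma(y + 1))
    },
    loglik_i = function(y, eta) {
      lambda <- exp(pmin(eta, 30))
      y * pmin(eta, 30) - log_expm1(lambda) - lgamma(y + 1)
    },
    grad = function(y, eta) y - trunc_mean(exp(pmin(eta, 30))),
    weight = function(y, eta) {
      lambda <- exp(pmin(eta, 30))
      q <- -expm1(-lambda)
      pmax(lambda * (q - lambda * (1 - q)) / q^2, 1e-14)
    })
}

# ---- prior precision assembly ----------------------------------------------

# default hyperparameter values (log scale) used to initialise optimisation:
# sd priors start at their prior median, the range at its prior median.
default_theta <- function(hyper_names, priors, r0) {
  th <- numeric(length(hyper_names))
  names(th) <- hyper_names
  med_sd <- log(2) / priors$lambda_sd
  for (h in hyper_names) {
    th[h] <- switch(substr(h, 1, 9),
                    "log_range" = log(r0),
                    "log_sigma" = log(med_sd),
                    log(1 / med_sd^2))   # log_tau_*
  }
  th
}

mesh_diameter <- function(mesh) {
  sqrt(diff(range(mesh$nodes[, 1]))^2 + diff(range(mesh$nodes[, 2]))^2)
}

# assemble the latent prior precision (block diagonal) for hyperparameters
# theta; returns list(Q, logdet)
prior_precision <- function(design, priors, theta) {
  blocksQ <- list()
  logdet <- 0
  for (b in design$blocks) {
    nb <- length(b$cols)
    if (b$type %in% c("fixed", "factor", "linear")) {
      blocksQ[[b$name]] <- Matrix::Diagonal(nb, priors$fixed_prec)
      logdet <- logdet + nb * log(priors$fixed_prec)
    } else if (b$type == "rw1") {
      tau <- exp(theta[[b$hyper]])
      Qb <- tau * b$R
      blocksQ[[b$name]] <- Matrix::Matrix(Qb, sparse = TRUE)
      logdet <- logdet + nb * log(tau) +
        as.numeric(determinant(b$R, logarithm = TRUE)$modulus)
    } else if (b$type == "iid") {
      tau <- exp(theta[["log_tau_vessel"]])
      blocksQ[[b$name]] <- Matrix::Diagonal(nb, tau)
      logdet <- logdet + nb * log(tau)
    } else if (b$type == "spde") {
      fp <- field_params(exp(theta[["log_range"]]),
                         exp(theta[["log_sigma"]]))
      Qf <- precision_barrier(b$fem, b$mesh, fp)
      ld1 <- 2 * as.numeric(
        Matrix::determinant(Matrix::Cholesky(Qf, LDL = FALSE, perm = TRUE),
                            logarithm = TRUE, sqrt = TRUE)$modulus)
      if (b$n_years == 1L) {
        blocksQ[[b$name]] <- Qf
        logdet <- logdet + ld1
      } else {
        blocksQ[[b$name]] <- Matrix::bdiag(rep(list(Qf), b$n_years))
        logdet <- logdet + b$n_years * ld1
      }
    }
  }
  list(Q = Matrix::bdiag(blocksQ), logdet = logdet)
}

# PC-style log hyperpriors evaluated on the log scale (Jacobians included)
log_hyper_prior <- function(theta, priors, r0) {
  lp <- 0
  lam <- priors$lambda_sd
  for (h in names(theta)) {
    v <- theta[[h]]
    if (h == "log_range") {
      lam_r <- r0 * log(2)            # P(range < r0) = 0.5
      r <- exp(v)
      lp <- lp + log(lam_r) - 2 * log(r) - lam_r / r + v
    } else if (h == "log_sigma") {
      s <- exp(v)
      lp <- lp + log(lam) - lam * s + v
    } else {                          # log precision of an sd ~ Exp(lam)
      s <- exp(-v / 2)
      lp <- lp + log(lam) - lam * s + log(s / 2)
    }
  }
  lp
}

# ---- inner Newton optimisation ---------------------------------------------

newton_mode <- function(design, family, Qp, u0 = NULL,
                        max_iter = 50L, tol = 1e-6) {
  X <- design$X; y <- design$y
  u <- if (is.null(u0)) rep(0, design$p) else u0
  separation <- FALSE
  converged <- FALSE
  obj <- function(u, eta) family$loglik(y, eta) -
    0.5 * sum(u * as.vector(Qp %*% u))
  eta <- as.vector(X %*% u)
  f_cur <- obj(u, eta)
  for (it in seq_len(max_iter)) {
    g <- family$grad(y, eta)
    w <- family$weight(y, eta)
    grad_u <- as.vector(Matrix::crossprod(X, g)) - as.vector(Qp %*% u)
    if (max(abs(grad_u)) < tol) { converged <- TRUE; break }
    XtW <- Matrix::crossprod(X, Matrix::Diagonal(design$n, w))
    Qpost <- Matrix::forceSymmetric(Qp + XtW %*% X)
    b <- as.vector(XtW %*% eta) + as.vector(Matrix::crossprod(X, g))
    u_new <- as.vector(Matrix::solve(Qpost, b))
    # damped step: halve until the penalised log-likelihood does not decrease
    step <- 1
    repeat {
      u_try <- u + step * (u_new - u)
      eta_try <- as.vector(X %*% u_try)
      f_try <- obj(u_try, eta_try)
      if (is.finite(f_try) && f_try >= f_cur - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    u <- u + step * (u_new - u)
    eta <- as.vector(X %*% u)
    f_cur <- obj(u, eta)
    if (max(abs(eta)) > 30) { separation <- TRUE; break }
  }
  g <- family$grad(y, eta)
  w <- family$weight(y, eta)
  XtW <- Matrix::crossprod(X, Matrix::Diagonal(design$n, w))
  Qpost <- Matrix::forceSymmetric(Qp + XtW %*% X)
  list(u = u, eta = eta, Qpost = Qpost, loglik = family$loglik(y, eta),
       converged = converged, separation = separation, iterations = it)
}

# Laplace-approximate log marginal likelihood at theta (log hyperprior added
# by the caller)
laplace_lml <- function(design, family, priors, theta, u0 = NULL,
                        control = fit_control()) {
  pp <- prior_precision(design, priors, theta)
  nm <- newton_mode(design, family, pp$Q, u0,
                    max_iter = control$max_iter, tol = control$tol)
  ch <- Matrix::Cholesky(as_sparse_sym(nm$Qpost), LDL = FALSE, perm = TRUE)
  logdet_post <- 2 * as.numeric(
    Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  lml <- nm$loglik - 0.5 * sum(nm$u * as.vector(pp$Q %*% nm$u)) +
    0.5 * pp$logdet - 0.5 * logdet_post
  list(lml = lml, mode = nm, chol = ch, Qp = pp$Q)
}

#' Numerical controls for hurdle-model fitting
#'
#' @param max_iter maximum Newton iterations for the latent mode.
#' @param tol convergence tolerance on the maximum latent gradient.
#' @param optim_maxit Nelder-Mead iterations for the hyperparameter mode.
#' @param grid_step step (log scale) between hyperparameter grid points.
#' @param grid_halfwidth number of grid steps on each side of the mode along
#'   each hyperparameter axis (2 gives 5 points per dimension).
#' @return a list of controls.
#' @export
fit_control <- function(max_iter = 50L, tol = 1e-6, optim_maxit = 30L,
                        grid_step = 0.6, grid_halfwidth = 2L) {
  list(max_iter = max_iter, tol = tol, optim_maxit = optim_maxit,
       grid_step = grid_step, grid_halfwidth = grid_halfwidth)
}

# ---- outer fit: hyperparameter exploration + Gaussian mixture ---------------

fit_latent_gaussian <- function(design, priors, family,
                                control = fit_control()) {
  hyper <- unique(unlist(lapply(design$blocks, `[[`, "hyper")))
  hyper <- hyper[nzchar(hyper)]
  r0 <- priors$range_median
  if (is.null(r0)) {
    r0 <- if (!is.null(design$mesh)) mesh_diameter(design$mesh) / 2 else 1
  }
  warm <- NULL
  eval_theta <- function(theta) {
    names(theta) <- hyper
    res <- laplace_lml(design, family, priors, theta, u0 = warm,
                       control = control)
    warm <<- res$mode$u
    res$lml_post <- res$lml + log_hyper_prior(theta, priors, r0)
    res
  }

  if (length(hyper) == 0) {
    res <- eval_theta(numeric(0))
    points <- matrix(numeric(0), nrow = 1)
    fits <- list(res)
    weights <- 1
  } else {
    th0 <- default_theta(hyper, priors, r0)
    neg <- function(th) -eval_theta(th)$lml_post
    opt <- if (length(hyper) == 1) {
      optim(th0, neg, method = "Brent",
            lower = th0 - 6, upper = th0 + 6)
    } else {
      optim(th0, neg, method = "Nelder-Mead",
            control = list(maxit = control$optim_maxit))
    }
    th_star <- opt$par
    # cross design: the mode plus grid_halfwidth steps either way along each
    # hyperparameter axis
    offsets <- list(rep(0, length(hyper)))
    for (d in seq_along(hyper)) {
      for (s in c(-control$grid_halfwidth:-1, 1:control$grid_halfwidth)) {
        o <- rep(0, length(hyper)); o[d] <- s * control$grid_step
        offsets <- c(offsets, list(o))
      }
    }
    points <- matrix(unlist(lapply(offsets, function(o) th_star + o)),
                     nrow = length(offsets), ncol = length(hyper),
                     byrow = TRUE, dimnames = list(NULL, hyper))
    fits <- lapply(seq_len(nrow(points)), function(i)
      eval_theta(points[i, ]))
    lml <- vapply(fits, `[[`, 0, "lml_post")
    weights <- exp(lml - max(lml))
    weights <- weights / sum(weights)
  }

  conv <- vapply(fits, function(f) f$mode$converged, TRUE)
  sep <- vapply(fits, function(f) f$mode$separation, TRUE)
  if (any(sep))
    warning("possible separation: |linear predictor| exceeded 30")
  if (!all(conv | sep))
    warning("Newton optimisation did not reach tolerance at ",
            sum(!(conv | sep)), " hyperparameter point(s)")
  structure(list(
    design = design, family = family, priors = priors,
    theta = points, weights = weights,
    modes = lapply(fits, function(f) f$mode$u),
    etas = lapply(fits, function(f) f$mode$eta),
    chols = lapply(fits, `[[`, "chol"),
    logliks = vapply(fits, function(f) f$mode$loglik, 0),
    lml = vapply(fits, `[[`, 0, "lml_post"),
    converged = all(conv), separation = any(sep),
    range_median = r0),
    class = "latent_fit")
}

#' Fit the Bernoulli occurrence sub-model
#'
#' Laplace approximation of the latent-Gaussian posterior: for each point of
#' a coarse hyperparameter grid (the Laplace-marginal mode plus a cross of
#' points along each hyperparameter axis), the latent joint posterior is
#' optimised by damped Newton iteration to its mode and approximated by a
#' Gaussian there; grid weights are proportional to hyperprior times Laplace
#' marginal likelihood. Convergence requires the maximum latent gradient
#' below `control$tol` within `control$max_iter` iterations; failure and
#' separation (|linear predictor| > 30) are warned about, never silent.
#'
#' @param design a `hurdle_design` with `response = "occurrence"`.
#' @param priors a `prior_spec`.
#' @param control a [fit_control()].
#' @return a `latent_fit`.
#' @export
fit_bernoulli <- function(design, priors = prior_spec(),
                          control = fit_control()) {
  if (!all(design$y %in% c(0, 1))) stop("occurrence response must be 0/1")
  fit_latent_gaussian(design, priors, family_bernoulli(), control)
}

#' Fit the zero-truncated Poisson positive-bycatch sub-model
#'
#' Same machinery as [fit_bernoulli()] with the zero-truncated Poisson
#' log-likelihood `y log(lambda) - lambda - log(1 - exp(-lambda)) - log(y!)`,
#' where the linear predictor is the log of the untruncated rate lambda.
#' A boundary mode (all counts equal to 1 pushes lambda toward 0) is
#' signalled via the separation warning.
#'
#' @param design a `hurdle_design` with `response = "positive"`.
#' @inheritParams fit_bernoulli
#' @return a `latent_fit`.
#' @export
fit_ztpoisson <- function(design, priors = prior_spec(),
                          control = fit_control()) {
  if (any(design$y < 1)) stop("positive sub-model requires responses >= 1")
  fit <- fit_latent_gaussian(design, priors, family_ztpoisson(), control)
  eta_hat <- as.vector(design$X %*% latent_mean(fit))
  if (max(eta_hat) < -5)
    warning("boundary: fitted lambda near zero everywhere (the truncated ",
            "mean cannot fall below 1; are all counts equal to 1?)")
  fit
}

# ---- posterior draws and summaries -----------------------------------------

#' Draw latent vectors from a fitted sub-model
#'
#' Samples a hyperparameter grid point by its weight, then the latent vector
#' from the Gaussian approximation at that point.
#'
#' @param fit a `latent_fit`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return list with `u` (latent draws, p x n) and `k` (grid point index per
#'   draw).
#' @export
draw_latent <- function(fit, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  p <- fit$design$p
  with_seed(seed, {
    k <- sample.int(length(fit$weights), n, TRUE, fit$weights)
    u <- matrix(0, p, n)
    for (g in unique(k)) {
      idx <- which(k == g)
      z <- matrix(rnorm(p * length(idx)), p, length(idx))
      w <- Matrix::solve(fit$chols[[g]], z, system = "Lt")
      eps <- as.matrix(Matrix::solve(fit$chols[[g]], w, system = "Pt"))
      u[, idx] <- fit$modes[[g]] + eps
    }
    list(u = u, k = k)
  })
}

# posterior mean of the latent vector (mixture over grid points)
latent_mean <- function(fit) {
  Reduce(`+`, Map(function(w, m) w * m, fit$weights, fit$modes))
}

# covariance of a set of latent columns at grid point g
block_cov <- function(fit, g, cols) {
  E <- matrix(0, fit$design$p, length(cols))
  E[cbind(cols, seq_along(cols))] <- 1
  S <- as.matrix(Matrix::solve(fit$chols[[g]], E, system = "A"))
  S[cols, , drop = FALSE]
}

# marginal posterior sd of selected latent columns, mixing over grid points
latent_sd <- function(fit, cols) {
  mix_mean <- latent_mean(fit)[cols]
  v <- rep(0, length(cols))
  for (g in seq_along(fit$weights)) {
    dg <- diag(block_cov(fit, g, cols))
    v <- v + fit$weights[g] * (dg + (fit$modes[[g]][cols] - mix_mean)^2)
  }
  sqrt(v)
}

# posterior sd of Z %*% u_block, mixing over grid points
mapped_sd <- function(fit, cols, Z) {
  mu <- latent_mean(fit)
  mix_mean <- as.vector(Z %*% mu[cols])
  v <- rep(0, nrow(Z))
  for (g in seq_along(fit$weights)) {
    S <- block_cov(fit, g, cols)
    dg <- rowSums((Z %*% S) * Z)
    dev <- as.vector(Z %*% fit$modes[[g]][cols]) - mix_mean
    v <- v + fit$weights[g] * (dg + dev^2)
  }
  sqrt(v)
}

#' Posterior summaries of the fitted effects
#'
#' Maps the latent posterior back to interpretable effects: per-level
#' sum-to-zero effects for factors, slopes for linear terms, bin-midpoint
#' values for RW1 smooths, per-vessel effects, and per-node field values.
#'
#' @param fit a `latent_fit`.
#' @return named list of data.frames with `level`/`mid`, `mean`, `sd`.
#' @export
effect_estimates <- function(fit) {
  out <- list()
  mu <- latent_mean(fit)
  for (b in fit$design$blocks) {
    if (b$type == "fixed") {
      out[[b$name]] <- data.frame(level = b$name, mean = mu[b$cols],
                                  sd = latent_sd(fit, b$cols))
    } else if (b$type == "linear") {
      out[[b$name]] <- data.frame(level = b$name, mean = mu[b$cols],
                                  sd = latent_sd(fit, b$cols))
    } else if (b$type == "factor") {
      eff <- as.vector(b$Z %*% mu[b$cols])
      out[[b$name]] <- data.frame(level = b$levels, mean = eff,
                                  sd = mapped_sd(fit, b$cols, b$Z))
    } else if (b$type == "rw1") {
      eff <- as.vector(b$Z %*% mu[b$cols])
      out[[b$name]] <- data.frame(mid = b$mids, mean = eff,
                                  sd = mapped_sd(fit, b$cols, b$Z))
    } else if (b$type == "iid") {
      out[[b$name]] <- data.frame(level = b$levels, mean = mu[b$cols],
                                  sd = NA_real_)
    }
  }
  out
}

# posterior mean hyperparameters (weighted over the grid)
hyper_mean <- function(fit) {
  if (ncol(fit$theta) == 0) return(numeric(0))
  colSums(fit$theta * fit$weights)
}
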