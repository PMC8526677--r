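#' Specify terms of one hurdle sub-model
#'
#' @param factors categorical covariates (sum-to-zero coded).
#' @param linears continuous covariates entered linearly (centred at their
#'   training mean).
#' @param smooths continuous covariates entered as first-order random-walk
#'   (RW1) smooths over `m_bins` equal-width bins.
#' @param vessel include an i.i.d. Gaussian vessel random effect.
#' @param spatial `"none"`, `"const"` (one spatial field) or `"year"` (one
#'   conditionally independent field replicate per year, sharing range and
#'   sigma).
#' @return a `model_terms` list. The intercept is always present.
#' @export
model_terms <- function(factors = character(), linears = character(),
                        smooths = character(), vessel = FALSE,
                        spatial = c("none", "const", "year")) {
  spatial <- match.arg(spatial)
  all_terms <- c(factors, linears, smooths)
  if (anyDuplicated(all_terms))
    stop("each covariate may appear at most once per sub-model")
  structure(list(factors = factors, linears = linears, smooths = smooths,
                 vessel = vessel, spatial = spatial),
            class = "model_terms")
}

# orthonormal basis of the sum-to-zero subspace of R^k
sum_to_zero_basis <- function(k) {
  qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
}

terms_label <- function(terms) {
  parts <- c("intercept", terms$factors, terms$linears, terms$smooths,
             if (terms$vessel) "vessel",
             if (terms$spatial == "const") "field",
             if (terms$spatial == "year") "field_by_year")
  paste(parts, collapse = " + ")
}

#' Build the latent-Gaussian design for one hurdle sub-model
#'
#' Assembles the sparse design matrix mapping the latent vector (intercept,
#' sum-to-zero factor contrasts, linear slopes, RW1 smooth values, vessel
#' effects, spatial field node weights) to the linear predictor, together
#' with block descriptors carrying prior structure and everything needed to
#' rebuild prediction rows (factor levels, bin breaks, centring constants).
#'
#' For `response = "occurrence"` the response is the 0/1 bycatch indicator
#' over all records; for `response = "positive"` the design is built only
#' from records with positive bycatch and the response is the count.
#'
#' Categorical effects are coded on an orthonormal sum-to-zero basis, so the
#' reported per-level effects always sum to zero. RW1 smooths use `m_bins`
#' equal-width half-open bins `[a, b)` over the training range (boundary
#' values clamped into the end bins) and carry an intrinsic first-difference
#' prior, made proper by the same sum-to-zero reparametrisation.
#'
#' @param records set-record data.frame.
#' @param terms a `model_terms`.
#' @param response `"occurrence"` or `"positive"`.
#' @param mesh,domain required when `terms$spatial != "none"`.
#' @param m_bins number of RW1 bins.
#' @return a `hurdle_design` list.
#' @export
build_design <- function(records, terms,
                         response = c("occurrence", "positive"),
                         mesh = NULL, domain = NULL, m_bins = 20L) {
  response <- match.arg(response)
  if (nrow(records) == 0) stop("records must be nonempty")
  if (response == "positive") {
    records <- records[records$bycatch >= 1, , drop = FALSE]
    if (nrow(records) == 0) stop("no positive-bycatch records")
    y <- as.numeric(records$bycatch)
  } else {
    y <- as.integer(records$bycatch >= 1)
  }
  n <- nrow(records)
  blocks <- list()
  Xparts <- list()
  col0 <- 0L

  add_block <- function(name, type, ncols, X, hyper = character(),
                        extra = list()) {
    blocks[[name]] <<- c(list(name = name, type = type,
                              cols = col0 + seq_len(ncols), hyper = hyper),
                         extra)
    Xparts[[name]] <<- X
    col0 <<- col0 + ncols
  }

  add_block("intercept", "fixed", 1L,
            Matrix::Matrix(1, n, 1, sparse = TRUE))

  for (f in terms$factors) {
    if (is.null(records[[f]])) stop("unknown covariate name: ", f)
    lev <- sort(unique(as.character(records[[f]])))
    if (length(lev) < 2) stop("factor ", f, " has fewer than 2 levels")
    Z <- sum_to_zero_basis(length(lev))
    I <- Matrix::sparseMatrix(i = seq_len(n),
                              j = match(as.character(records[[f]]), lev),
                              x = 1, dims = c(n, length(lev)))
    add_block(f, "factor", ncol(Z),
              methods::as(I %*% Z, "CsparseMatrix"),
              extra = list(levels = lev, Z = Z))
  }

  for (v in terms$linears) {
    if (is.null(records[[v]])) stop("unknown covariate name: ", v)
    ctr <- mean(records[[v]])
    add_block(v, "linear", 1L,
              Matrix::Matrix(records[[v]] - ctr, n, 1, sparse = TRUE),
              extra = list(center = ctr))
  }

  for (s in terms$smooths) {
    if (is.null(records[[s]])) stop("unknown covariate name: ", s)
    breaks <- seq(min(records[[s]]), max(records[[s]]),
                  length.out = m_bins + 1L)
    bin <- findInterval(records[[s]], breaks, all.inside = TRUE)
    Z <- sum_to_zero_basis(m_bins)
    I <- Matrix::sparseMatrix(i = seq_len(n), j = bin, x = 1,
                              dims = c(n, m_bins))
    D <- diff(diag(m_bins))            # RW1 structure, rank m - 1
    R <- crossprod(D)
    add_block(s, "rw1", m_bins - 1L,
              methods::as(I %*% Z, "CsparseMatrix"),
              hyper = paste0("log_tau_", s),
              extra = list(breaks = breaks, Z = Z,
                           R = crossprod(Z, R %*% Z),
                           mids = (head(breaks, -1) + breaks[-1]) / 2))
  }

  if (terms$vessel) {
    lev <- sort(unique(records$vessel_id))
    I <- Matrix::sparseMatrix(i = seq_len(n),
                              j = match(records$vessel_id, lev),
                              x = 1, dims = c(n, length(lev)))
    add_block("vessel", "iid", length(lev), I,
              hyper = "log_tau_vessel", extra = list(levels = lev))
  }

  if (terms$spatial != "none") {
    if (is.null(mesh) || is.null(domain))
      stop("spatial terms need a mesh and a domain")
    xy <- to_planar(domain, records$lon, records$lat)
    proj <- make_projector(mesh, xy)
    if (!all(proj$valid)) stop("records outside the mesh")
    fem <- assemble_fem(mesh)
    nn <- nrow(mesh$nodes)
    if (terms$spatial == "const") {
      add_block("field", "spde", nn, proj$A,
                hyper = c("log_range", "log_sigma"),
                extra = list(fem = fem, mesh = mesh, n_years = 1L))
    } else {
      yrs <- sort(unique(records$year))
      Xf <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0),
                                 dims = c(n, nn * length(yrs)))
      for (k in seq_along(yrs)) {
        rows <- which(records$year == yrs[k])
        Xf[rows, (k - 1L) * nn + seq_len(nn)] <-
          proj$A[rows, , drop = FALSE]
      }
      add_block("field", "spde", nn * length(yrs), Xf,
                hyper = c("log_range", "log_sigma"),
                extra = list(fem = fem, mesh = mesh, n_years = length(yrs),
                             years = yrs))
    }
  }

  X <- do.call(cbind, unname(Xparts))
  structure(list(y = y, X = X, blocks = blocks, n = n, p = col0,
                 terms = terms, response = response,
                 records = records, domain = domain, mesh = mesh),
            class = "hurdle_design")
}

#' Prior settings for hurdle-model fits
#'
#' Fixed effects get independent `N(0, 31.6^2)` priors (effectively flat on
#' the logit/log scales). Hyperpriors are penalised-complexity style: the
#' field range has `P(range < range_median) = 0.5` (default: half the mesh
#' diameter), the field sigma and the RW1/vessel standard deviations have
#' exponential tails with `P(sd > pc_u_sd) = pc_alpha_sd`.
#'
#' @param fixed_sd prior sd of fixed effects.
#' @param range_median median of the range prior (km); `NULL` means half the
#'   mesh diameter, resolved at fit time.
#' @param pc_u_sd,pc_alpha_sd tail parameters for the sd priors.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(fixed_sd = 31.6, range_median = NULL,
                       pc_u_sd = 1, pc_alpha_sd = 0.1) {
  structure(list(fixed_prec = 1 / fixed_sd^2,
                 range_median = range_median,
                 lambda_sd = -log(pc_alpha_sd) / pc_u_sd),
            class = "prior_spec")
}
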