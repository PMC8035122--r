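# Penalized objective machinery shared by the fitting entry points.
# With the local quadratic approximation the exact gradient of the smooth
# penalized objective at theta is score(theta) - N E(theta) theta, and the
# curvature model is I(theta) + N E(theta); E is rebuilt at every accepted
# step (the expansion point follows the iterate).
pen_objective_fns <- function(model, data, terms, eta, c_bar,
                              information = "fisher") {
  N <- data$N
  has_pen <- length(terms) > 0 && any(unlist(eta) > 0)
  objective <- function(theta) {
    groups <- fa_model_unpack(theta, model)
    for (g in groups) if (any(g$Psi <= 0)) return(-Inf)
    ll <- tryCatch(fa_loglik(theta, model, data), error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    if (has_pen) ll <- ll - N * penalty_value_terms(theta, terms, eta, c_bar)
    ll
  }
  derivs <- function(theta) {
    if (information == "fisher") {
      sf <- fa_score_fisher(theta, model, data)
      g <- sf$score
      H <- sf$fisher
    } else {
      g <- fa_score(theta, model, data)
      H <- fa_information(theta, model, data, kind = information)
    }
    if (has_pen) {
      E <- penalty_matrix_terms(theta, terms, eta, c_bar, model$m)
      g <- g - N * as.numeric(E %*% theta)
      H <- H + N * E
    }
    list(grad = g, curv = H)
  }
  list(objective = objective, derivs = derivs)
}

check_admissible <- function(theta, model) {
  groups <- fa_model_unpack(theta, model)
  ok <- all(is.finite(theta))
  for (g in groups) {
    if (any(g$Psi <= 0)) ok <- FALSE
    ev <- eigen(g$Phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) ok <- FALSE
  }
  ok
}

#' Unpenalized maximum-likelihood fit
#'
#' Fits the factor model by maximum likelihood with the trust-region
#' algorithm. The result seeds penalized fits and provides the adaptive-lasso
#' weights \eqn{1/|\hat\theta^{MLE}|^a}.
#'
#' @param data an [fa_data()] summary (or a raw data frame, converted with
#'   [fa_data()]).
#' @param model an [fa_model()] specification.
#' @param start optional starting vector; default [fa_start()].
#' @param information curvature used by the optimizer: `"fisher"` (default)
#'   or `"hessian"` (single group).
#' @param max_iter iteration cap.
#' @param trace record the per-iteration log (objective, gradient norm,
#'   radius, agreement ratio) in `$convergence$trace`; write it as JSON
#'   lines with [fa_trace_json()].
#' @return An `fa_fit` object with `admissible` flag; non-convergence is
#'   reported in `$convergence`, not silently accepted.
#' @export
fa_fit_mle <- function(data, model, start = NULL, information = "fisher",
                       max_iter = 500L, trace = FALSE) {
  if (is.data.frame(data) || is.matrix(data)) data <- fa_data(data)
  if (model$m > min(data$N, model$G * model$p * (model$p + 1) / 2))
    stop("more free parameters than available moments or observations",
         call. = FALSE)
  if (is.null(start)) start <- fa_start(model, data)
  fns <- pen_objective_fns(model, data, list(), numeric(0), 1e-8,
                           information = information)
  opt <- tr_maximize(start, fns$objective, fns$derivs, N = data$N,
                     max_iter = max_iter, trace = trace)
  fit <- fa_fit_result(opt, model, data, penalty = NULL, terms = list(),
                       eta = numeric(0), weights = NULL,
                       information = information)
  if (trace) fit$convergence$trace <- opt$trace
  fit
}

#' Write an optimizer trace as JSON lines
#'
#' @param fit an `fa_fit` produced with `trace = TRUE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
fa_trace_json <- function(fit, path) {
  tr <- fit$convergence$trace
  if (is.null(tr)) stop("fit carries no trace; refit with trace = TRUE",
                        call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tr))) {
    writeLines(jsonlite::toJSON(as.list(tr[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

# Penalized fit at fixed eta (resolved terms); internal core.
fit_penalized_core <- function(data, model, penalty, terms, eta, start,
                               information = "fisher", max_iter = 500L) {
  fns <- pen_objective_fns(model, data, terms, eta, penalty$c_bar,
                           information = information)
  tr_maximize(start, fns$objective, fns$derivs, N = data$N,
              max_iter = max_iter)
}

#' Penalized fit at fixed tuning parameters
#'
#' Maximizes the penalized log-likelihood
#' \eqn{\ell_p(\theta) = \ell(\theta) - N P_\eta(\theta)} (with the smooth
#' locally approximated penalty) by the trust-region algorithm.
#'
#' @inheritParams fa_fit_mle
#' @param penalty a [penalty_config()] with numeric `eta` (or pass `eta`).
#' @param eta optional tuning vector overriding `penalty$eta`.
#' @param mle optional unpenalized `fa_fit` supplying start values and
#'   adaptive weights; computed when absent and needed.
#' @return An `fa_fit` object including effective degrees of freedom, GBIC
#'   and the posterior covariance.
#' @export
fa_fit_penalized <- function(data, model, penalty, eta = NULL, mle = NULL,
                             start = NULL, information = "fisher",
                             max_iter = 500L) {
  if (is.data.frame(data) || is.matrix(data)) data <- fa_data(data)
  if (!is.null(eta)) {
    penalty$eta <- eta
    penalty$auto <- FALSE
  }
  if (penalty$auto)
    stop("eta is 'auto'; use fa_fit() or fa_auto_tune()", call. = FALSE)
  weights <- penalty$weights
  needs_w <- "alasso" %in% c(penalty$sparsity, penalty$fuse_loadings,
                             penalty$fuse_intercepts)
  if (needs_w && is.null(weights)) {
    if (is.null(mle)) mle <- fa_fit_mle(data, model, information = information)
    weights <- alasso_weights(mle$theta, model, penalty)
  }
  if (is.null(start)) {
    start <- if (!is.null(mle)) mle$theta else {
      mle <- fa_fit_mle(data, model, information = information)
      if (needs_w && is.null(weights))
        weights <- alasso_weights(mle$theta, model, penalty)
      mle$theta
    }
  }
  terms <- pen_terms(model, penalty, weights)
  eta_res <- resolve_eta(penalty, terms)
  opt <- fit_penalized_core(data, model, penalty, terms, eta_res, start,
                            information, max_iter)
  fa_fit_result(opt, model, data, penalty, terms, eta_res, weights,
                information)
}

# Assemble the fa_fit object: loglik, edf, GBIC, posterior covariance.
fa_fit_result <- function(opt, model, data, penalty, terms, eta, weights,
                          information = "fisher") {
  theta <- opt$theta
  ll <- fa_loglik(theta, model, data)
  has_pen <- length(terms) > 0 && any(eta > 0)
  ed <- influence_edf_core(theta, model, data, terms, eta,
                           if (is.null(penalty)) 1e-8 else penalty$c_bar)
  gbic_val <- gbic(ll, ed$edf_total, data$N)
  Vt <- ed$Vtheta
  se <- sqrt(pmax(diag(Vt), 0))
  fit <- structure(list(
    theta = theta, model = model, data = data, penalty = penalty,
    terms = terms, eta = eta, weights = weights,
    loglik = ll, edf = ed$edf_total, edf_per = ed$edf_per,
    influence = ed$A, gbic = gbic_val,
    Vtheta = Vt, se = se,
    information = information,
    admissible = check_admissible(theta, model),
    flags = ed$flags,
    convergence = list(converged = opt$converged, reason = opt$reason,
                       iterations = opt$iterations,
                       grad_max = max(abs(opt$grad)))
  ), class = "fa_fit")
  fit
}
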