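# Symmetric square root (and inverse root) by eigendecomposition, flooring
# non-positive eigenvalues; `floored` reports whether a correction happened.
sym_sqrt <- function(M, tol = 1e-10) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  floor_at <- tol * max(abs(eg$values), .Machine$double.eps)
  floored <- any(eg$values < floor_at)
  vals <- pmax(eg$values, floor_at)
  list(sqrt = eg$vectors %*% (sqrt(vals) * t(eg$vectors)),
       inv_sqrt = eg$vectors %*% ((1 / sqrt(vals)) * t(eg$vectors)),
       inv = eg$vectors %*% ((1 / vals) * t(eg$vectors)),
       floored = floored)
}

influence_edf_core <- function(theta, model, data, terms, eta, c_bar) {
  Fi <- fa_information(theta, model, data, kind = "fisher")
  N <- data$N
  E <- if (length(terms)) penalty_matrix_terms(theta, terms, eta, c_bar,
                                               model$m)
       else matrix(0, model$m, model$m)
  Fp <- Fi + N * E
  sq <- sym_sqrt(Fi)
  Fp_inv <- tryCatch(chol2inv(chol(Fp)), error = function(e) sym_sqrt(Fp)$inv)
  A <- sq$sqrt %*% Fp_inv %*% sq$sqrt
  A <- (A + t(A)) / 2
  edf_per <- pmin(pmax(diag(Fp_inv %*% Fi), 0), 1)
  list(A = A, edf_total = sum(diag(A)), edf_per = edf_per,
       Vtheta = (Fp_inv + t(Fp_inv)) / 2, Fisher = Fi, Fp_inv = Fp_inv,
       flags = list(fisher_floored = sq$floored))
}

#' Influence matrix and effective degrees of freedom
#'
#' With \eqn{F} the expected Fisher information at the penalized optimum and
#' \eqn{F_p = F + N E_\eta}, the influence (hat) matrix of the fitting
#' problem is \eqn{A = F^{1/2} F_p^{-1} F^{1/2}} (square roots by
#' eigendecomposition). The total effective degrees of freedom is
#' \eqn{tr(A)}; per-parameter edf are \eqn{diag(F_p^{-1}F)}, each in
#' \eqn{[0,1]}. At \eqn{\eta = 0}, \eqn{A = I} and edf equals the number of
#' free parameters; as \eqn{\eta \to \infty} the edf tends to `m` minus the
#' number of penalized elements.
#'
#' @param fit an `fa_fit` object, or pass `theta`, `model`, `data`, etc.
#' @return A list with `A`, `edf_total`, `edf_per`.
#' @export
influence_edf <- function(fit) {
  stopifnot(inherits(fit, "fa_fit"))
  ed <- influence_edf_core(fit$theta, fit$model, fit$data, fit$terms, fit$eta,
                           if (is.null(fit$penalty)) 1e-8
                           else fit$penalty$c_bar)
  ed[c("A", "edf_total", "edf_per")]
}

#' Generalized Bayesian information criterion
#'
#' \eqn{GBIC = -2\ell(\hat\theta) + \log(N)\,edf}; with `k = 2` the
#' AIC-flavoured generalized information criterion is returned instead.
#'
#' @param loglik log-likelihood value at the estimate.
#' @param edf total effective degrees of freedom.
#' @param N total sample size.
#' @param k penalty per edf: `log(N)` (default) or `2`.
#' @return scalar criterion value.
#' @export
gbic <- function(loglik, edf, N, k = log(N)) {
  stopifnot(is.finite(loglik), is.finite(edf), N > 0)
  -2 * loglik + k * edf
}

#' Tuning criterion (unbiased risk estimator)
#'
#' The approximate-AIC criterion minimized over the tuning parameters:
#' \eqn{V(\eta) = \frac1N\|K - A_\eta K\|^2 + \frac{2\gamma}{N}tr(A_\eta)-1}
#' with \eqn{K = F^{1/2}\theta + F^{-1/2} g(\theta)} built from the
#' unpenalized score and Fisher information at the current estimate, and
#' \eqn{A_\eta} the influence matrix.
#'
#' @param theta parameter vector (current penalized estimate).
#' @param model an [fa_model()] specification.
#' @param data an [fa_data()] summary.
#' @param penalty a [penalty_config()]; its `gamma` and `c_bar` are used.
#' @param eta numeric tuning vector (one entry per active term).
#' @param weights adaptive weights (alasso).
#' @return scalar value of the criterion.
#' @export
ubre <- function(theta, model, data, penalty, eta, weights = NULL) {
  terms <- pen_terms(model, penalty, weights)
  st <- ubre_state(theta, model, data)
  ubre_value(eta, st, terms, penalty$c_bar, penalty$gamma, theta)
}

# Precomputed pieces of V(eta) that do not depend on eta.
ubre_state <- function(theta, model, data) {
  sf <- fa_score_fisher(theta, model, data)
  Fi <- sf$fisher
  g <- sf$score
  sq <- sym_sqrt(Fi)
  K <- as.numeric(sq$sqrt %*% theta + sq$inv_sqrt %*% g)
  list(Fi = Fi, sqrt = sq$sqrt, K = K, sqrtK = as.numeric(sq$sqrt %*% K),
       N = data$N, m = model$m, floored = sq$floored)
}

ubre_value <- function(eta, st, terms, c_bar, gamma, theta_tilde) {
  E <- penalty_matrix_terms(theta_tilde, terms, eta, c_bar, st$m)
  Fp <- st$Fi + st$N * E
  Fp_inv <- tryCatch(chol2inv(chol(Fp)), error = function(e) sym_sqrt(Fp)$inv)
  # A K = F^{1/2} Fp^{-1} (F^{1/2} K);  tr(A) = tr(Fp^{-1} F)
  AK <- st$sqrt %*% (Fp_inv %*% st$sqrtK)
  resid <- st$K - as.numeric(AK)
  trA <- sum(Fp_inv * st$Fi)
  sum(resid^2) / st$N + 2 * gamma * trA / st$N - 1
}

#' Stopping rule of the automatic tuning procedure
#'
#' The two-step scheme stops when
#' \eqn{|\ell^{(t+1)} - \ell^{(t)}| / (0.1 + |\ell^{(t+1)}|) < 10^{-7}}.
#'
#' @param l_new,l_old successive log-likelihood values.
#' @param tol threshold, default `1e-7`.
#' @return logical.
#' @export
auto_tune_stop <- function(l_new, l_old, tol = 1e-7) {
  abs(l_new - l_old) / (0.1 + abs(l_new)) < tol
}

# Newton minimization of V over rho = log(eta), with numeric central-difference
# derivatives, ridge safeguarding, step halving and box [log 1e-8, log 1e8].
minimize_ubre <- function(rho0, Vfun, max_iter = 50L) {
  lo <- log(1e-8); hi <- log(1e8)
  rho <- pmin(pmax(rho0, lo), hi)
  d <- length(rho)
  h <- 1e-4
  V0 <- Vfun(rho)
  for (it in seq_len(max_iter)) {
    gr <- numeric(d)
    He <- matrix(0, d, d)
    Vp <- numeric(d); Vm <- numeric(d)
    for (j in seq_len(d)) {
      ej <- rep(0, d); ej[j] <- h
      Vp[j] <- Vfun(rho + ej); Vm[j] <- Vfun(rho - ej)
      gr[j] <- (Vp[j] - Vm[j]) / (2 * h)
      He[j, j] <- (Vp[j] - 2 * V0 + Vm[j]) / h^2
    }
    if (d > 1L) {
      for (j in seq_len(d - 1L)) for (k in (j + 1L):d) {
        ej <- rep(0, d); ej[j] <- h
        ek <- rep(0, d); ek[k] <- h
        He[j, k] <- He[k, j] <-
          (Vfun(rho + ej + ek) - Vp[j] - Vp[k] + 2 * V0 -
             Vm[j] - Vm[k] + Vfun(rho - ej - ek)) / (2 * h^2)
      }
    }
    if (max(abs(gr)) < 1e-7) break
    # eigenvalue-safeguarded Newton direction (flip/floor small curvature)
    eh <- eigen((He + t(He)) / 2, symmetric = TRUE)
    vals <- pmax(abs(eh$values), 1e-6 * max(abs(eh$values), 1e-12))
    step <- -as.numeric(eh$vectors %*% (crossprod(eh$vectors, gr) / vals))
    # step halving with gradient-descent fallback
    ok <- FALSE
    for (half in 0:24) {
      cand <- pmin(pmax(rho + step / 2^half, lo), hi)
      Vc <- Vfun(cand)
      if (is.finite(Vc) && Vc < V0 - 1e-14) { rho <- cand; V0 <- Vc
        ok <- TRUE; break }
    }
    if (!ok) {
      step <- -gr / max(abs(gr))
      for (half in 0:24) {
        cand <- pmin(pmax(rho + step / 2^half, lo), hi)
        Vc <- Vfun(cand)
        if (is.finite(Vc) && Vc < V0 - 1e-14) { rho <- cand; V0 <- Vc
          ok <- TRUE; break }
      }
    }
    if (!ok) break
  }
  list(rho = rho, value = V0)
}

#' Automatic multiple-tuning-parameter estimation
#'
#' Alternates (i) a trust-region update of the model parameters at the
#' current tuning vector with (ii) Newton minimization of the unbiased-risk
#' criterion \eqn{V(\eta)} over \eqn{\log\eta}, until the relative
#' log-likelihood change falls below \eqn{10^{-7}} (see [auto_tune_stop()]).
#' Only lasso and alasso penalties are supported (the penalty matrix must be
#' separable from \eqn{\eta}); scad/mcp require [fa_grid()].
#'
#' @inheritParams fa_fit_penalized
#' @param max_outer outer-iteration cap.
#' @return An `fa_fit` with estimated `eta`.
#' @export
fa_auto_tune <- function(data, model, penalty = penalty_config(), mle = NULL,
                         information = "fisher", max_outer = 100L) {
  if (is.data.frame(data) || is.matrix(data)) data <- fa_data(data)
  bad <- setdiff(unique(c(penalty$sparsity, penalty$fuse_loadings,
                          penalty$fuse_intercepts)),
                 c("lasso", "alasso", "none"))
  if (length(bad))
    stop("automatic tuning requires lasso/alasso penalties; got ",
         paste(bad, collapse = "/"), ". Use fa_grid().", call. = FALSE)
  if (is.null(mle)) mle <- fa_fit_mle(data, model, information = information)
  weights <- penalty$weights
  if (is.null(weights) &&
      "alasso" %in% c(penalty$sparsity, penalty$fuse_loadings,
                      penalty$fuse_intercepts)) {
    weights <- alasso_weights(mle$theta, model, penalty)
  }
  terms <- pen_terms(model, penalty, weights)
  if (!length(terms)) stop("no active penalty term", call. = FALSE)
  d <- length(terms)
  c_bar <- penalty$c_bar
  gamma <- penalty$gamma
  theta <- mle$theta
  ll_old <- mle$loglik

  # initial eta: coarse bracket on a shared log-scale value, then Newton
  st <- ubre_state(theta, model, data)
  Vfun <- function(rho) ubre_value(exp(rho), st, terms, c_bar, gamma, theta)
  grid0 <- log(10^seq(-5, 0, by = 1))
  V0s <- vapply(grid0, function(r) Vfun(rep(r, d)), numeric(1))
  rho <- rep(grid0[[which.min(V0s)]], d)
  rho <- minimize_ubre(rho, Vfun)$rho

  outer <- 0L
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    outer <- it
    eta <- stats::setNames(exp(rho), names(terms))
    opt <- fit_penalized_core(data, model, penalty, terms, eta, theta,
                              information = information)
    theta <- opt$theta
    ll_new <- fa_loglik(theta, model, data)
    st <- ubre_state(theta, model, data)
    Vfun <- function(rho) ubre_value(exp(rho), st, terms, c_bar, gamma, theta)
    # a few Newton steps per outer pass suffice: the damped alternation
    # re-minimizes at every iteration anyway
    rho_star <- minimize_ubre(rho, Vfun, max_iter = 5L)$rho
    # relaxation: a half-step on log(eta) stabilizes the two-step scheme
    # (undamped alternation can enter a period-2 cycle between a fused and an
    # unfused configuration when a difference penalty is near its breakpoint)
    rho <- 0.5 * rho + 0.5 * rho_star
    if (auto_tune_stop(ll_new, ll_old)) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  eta <- stats::setNames(exp(rho), names(terms))
  opt <- fit_penalized_core(data, model, penalty, terms, eta, theta,
                            information = information)
  penalty$eta <- eta
  penalty$auto <- FALSE
  fit <- fa_fit_result(opt, model, data, penalty, terms, eta, weights,
                       information)
  fit$convergence$outer_iterations <- outer
  fit$convergence$auto_converged <- converged
  fit$mle <- mle
  fit
}

#' Grid search over tuning parameters
#'
#' Fits the penalized model over a grid of tuning values (warm-starting each
#' fit from the previous solution along the path) and selects the fit with
#' the lowest GBIC.
#'
#' @inheritParams fa_fit_penalized
#' @param eta_grid numeric vector (single tuning parameter) or matrix/list of
#'   tuning vectors, one grid point per element.
#' @return The GBIC-minimizing `fa_fit`, with the search path in `$path`
#'   (tibble with `eta`, `loglik`, `edf`, `gbic`, `converged`).
#' @export
fa_grid <- function(data, model, penalty, eta_grid, mle = NULL,
                    information = "fisher") {
  if (is.data.frame(data) || is.matrix(data)) data <- fa_data(data)
  if (is.null(mle)) mle <- fa_fit_mle(data, model, information = information)
  weights <- penalty$weights
  if (is.null(weights) &&
      "alasso" %in% c(penalty$sparsity, penalty$fuse_loadings,
                      penalty$fuse_intercepts)) {
    weights <- alasso_weights(mle$theta, model, penalty)
  }
  terms <- pen_terms(model, penalty, weights)
  pts <- if (is.list(eta_grid)) eta_grid
         else if (is.matrix(eta_grid)) split(eta_grid, row(eta_grid))
         else as.list(eta_grid)
  ord <- order(vapply(pts, function(x) sum(x), numeric(1)))
  pts <- pts[ord]
  fits <- vector("list", length(pts))
  rows <- vector("list", length(pts))
  start <- mle$theta
  for (k in seq_along(pts)) {
    eta_k <- pts[[k]]
    if (length(eta_k) == 1L) eta_k <- rep(eta_k, length(terms))
    eta_k <- stats::setNames(as.numeric(eta_k), names(terms))
    opt <- tryCatch(fit_penalized_core(data, model, penalty, terms, eta_k,
                                       start, information = information),
                    error = function(e) e)
    if (inherits(opt, "error")) {
      rows[[k]] <- tibble::tibble(point = k,
                                  eta = paste(signif(eta_k, 4),
                                              collapse = ","),
                                  loglik = NA_real_, edf = NA_real_,
                                  gbic = NA_real_, converged = FALSE,
                                  error = conditionMessage(opt))
      next
    }
    start <- opt$theta
    pk <- penalty; pk$eta <- eta_k; pk$auto <- FALSE
    fit_k <- fa_fit_result(opt, model, data, pk, terms, eta_k, weights,
                           information)
    fits[[k]] <- fit_k
    rows[[k]] <- tibble::tibble(point = k,
                                eta = paste(signif(eta_k, 4), collapse = ","),
                                loglik = fit_k$loglik, edf = fit_k$edf,
                                gbic = fit_k$gbic,
                                converged = fit_k$convergence$converged,
                                error = NA_character_)
  }
  path <- dplyr::bind_rows(rows)
  ok <- which(!is.na(path$gbic))
  if (!length(ok)) stop("all grid-point fits failed; see the path table for ",
                        "diagnostics", call. = FALSE)
  best <- fits[[ok[which.min(path$gbic[ok])]]]
  best$path <- path
  best$mle <- mle
  best
}

#' Posterior covariance and intervals for a penalized fit
#'
#' The Bayesian covariance of the penalized estimator is
#' \eqn{V_\theta = F_p^{-1} = (F + N E_{\hat\eta})^{-1}}; 95% intervals are
#' \eqn{\hat\theta \pm 1.96\sqrt{diag(V_\theta)}}. The frequentist sandwich
#' \eqn{F_p^{-1} F F_p^{-1}} is available via `type = "sandwich"`.
#'
#' @param fit an `fa_fit`.
#' @param level confidence level.
#' @param type `"bayesian"` (default) or `"sandwich"`.
#' @return A list with `Vtheta` and an `intervals` tibble.
#' @export
posterior_uncertainty <- function(fit, level = 0.95,
                                  type = c("bayesian", "sandwich")) {
  type <- match.arg(type)
  ed <- influence_edf_core(fit$theta, fit$model, fit$data, fit$terms, fit$eta,
                           if (is.null(fit$penalty)) 1e-8
                           else fit$penalty$c_bar)
  V <- if (type == "bayesian") ed$Vtheta
       else ed$Fp_inv %*% ed$Fisher %*% ed$Fp_inv
  V <- (V + t(V)) / 2
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(V), 0))
  intervals <- tibble::tibble(
    name = fit$model$map$name,
    estimate = fit$theta,
    std.error = se,
    conf.low = fit$theta - z * se,
    conf.high = fit$theta + z * se)
  list(Vtheta = V, intervals = intervals)
}

#' Fit a penalized factor model
#'
#' Single entry point: parses the penalty configuration and dispatches to the
#' unpenalized MLE (`penalty = NULL` or all-`"none"`), the automatic tuning
#' procedure (`eta = "auto"`) or a fixed-tuning penalized fit.
#'
#' @param data a data frame (rows = subjects) or an [fa_data()] summary.
#' @param model an [fa_model()] specification or measurement-syntax string.
#' @param penalty a [penalty_config()], or `NULL` for maximum likelihood.
#' @param group optional group column name (data frames only).
#' @param information `"fisher"` or `"hessian"`.
#' @param ... passed to the underlying fitting routine.
#' @return An `fa_fit` object.
#' @examples
#' set.seed(1)
#' pop <- sim_population("sim1")
#' dat <- sim_generate(pop, N = 500, seed = 7)
#' model <- fa_model(pop$model_syntax, data_header = colnames(dat))
#' fit <- fa_fit(dat, model, penalty_config("alasso", a = 2, gamma = 4.5))
#' glance(fit)
#' @export
fa_fit <- function(data, model, penalty = penalty_config(), group = NULL,
                   information = "fisher", ...) {
  if (is.character(model)) {
    hdr <- if (is.data.frame(data)) names(data) else
      if (inherits(data, "fa_data")) data$var_names else NULL
    G <- if (inherits(data, "fa_data")) length(data$groups)
         else if (!is.null(group)) length(unique(data[[group]])) else 1L
    model <- fa_model(model, data_header = hdr, ngroups = G)
  }
  if (is.data.frame(data) || is.matrix(data))
    data <- fa_data(data, vars = model$var_names, group = group)
  no_pen <- is.null(penalty) ||
    all(c(penalty$sparsity, penalty$fuse_loadings,
          penalty$fuse_intercepts) == "none")
  if (no_pen) return(fa_fit_mle(data, model, information = information, ...))
  if (penalty$auto)
    return(fa_auto_tune(data, model, penalty, information = information, ...))
  fa_fit_penalized(data, model, penalty, information = information, ...)
}
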