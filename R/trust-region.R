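#' Solve the trust-region subproblem
#'
#' Minimizes the quadratic model \eqn{q(s) = g^T s + \frac12 s^T H s} subject
#' to \eqn{\|s\|_2 \le \Delta} by the eigendecomposition (More-Sorensen)
#' approach: an interior Newton step when `H` is positive definite and the
#' step fits in the ball, otherwise the boundary solution of the secular
#' equation, with the hard case handled explicitly.
#'
#' @param g gradient vector.
#' @param H symmetric curvature matrix (may be indefinite).
#' @param radius trust-region radius \eqn{\Delta > 0}.
#' @return A list with `s` (the step), `value` (model value at `s`),
#'   `on_boundary` (logical).
#' @export
solve_tr_subproblem <- function(g, H, radius) {
  stopifnot(radius > 0)
  m <- length(g)
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- eg$values
  gt <- as.numeric(crossprod(eg$vectors, g))
  step_for <- function(nu) -gt / (lam + nu)
  norm_for <- function(nu) sqrt(sum(step_for(nu)^2))
  lmin <- lam[m]

  if (lmin > 0) {
    st <- step_for(0)
    if (sqrt(sum(st^2)) <= radius) {
      s <- as.numeric(eg$vectors %*% st)
      return(list(s = s, value = sum(g * s) + 0.5 * sum(s * (H %*% s)),
                  on_boundary = FALSE))
    }
  }
  # boundary solution: find nu > max(0, -lmin) with ||s(nu)|| = radius
  nu_lo <- max(0, -lmin)
  active <- abs(lam - lmin) < 1e-12 * max(1, abs(lmin))
  hard <- all(abs(gt[active]) < 1e-12 * max(1, sqrt(sum(gt^2))))
  if (hard) {
    # pseudo-inverse step in the complement of the lowest eigenspace
    st <- ifelse(active, 0, -gt / (lam - lmin))
    nrm <- sqrt(sum(st^2))
    if (nrm <= radius) {
      tau <- sqrt(max(0, radius^2 - nrm^2))
      st <- st + tau * as.numeric(active) / sqrt(sum(active))
      s <- as.numeric(eg$vectors %*% st)
      return(list(s = s, value = sum(g * s) + 0.5 * sum(s * (H %*% s)),
                  on_boundary = TRUE))
    }
  }
  # ||s(nu)|| is decreasing in nu; bracket then root-find on
  # 1/||s(nu)|| - 1/radius (well conditioned near the pole).
  eps <- 1e-12 * max(1, abs(lmin))
  lo <- nu_lo + eps
  while (norm_for(lo) < radius && lo > 1e-300) lo <- nu_lo + (lo - nu_lo) / 10
  hi <- max(1, nu_lo * 2 + 1)
  while (norm_for(hi) > radius) hi <- hi * 10
  f <- function(nu) 1 / norm_for(nu) - 1 / radius
  nu <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                 error = function(e) hi)
  st <- step_for(nu)
  # rescale exactly onto the boundary to guard against root tolerance
  st <- st * (radius / sqrt(sum(st^2)))
  s <- as.numeric(eg$vectors %*% st)
  list(s = s, value = sum(g * s) + 0.5 * sum(s * (H %*% s)),
       on_boundary = TRUE)
}

# Generic trust-region maximizer.
#   objective(theta) -> scalar value to MAXIMIZE, or -Inf/NA if infeasible
#   derivs(theta)    -> list(grad, curv) of the objective; curv is the
#                       NEGATIVE curvature model (positive semi-definite for
#                       concave objectives), i.e. H in q(s) = -g's + s'Hs/2.
# Standard radius rules: expand when r > 0.75 and the step hit the boundary,
# shrink by 4 when r < 0.25, reject when r <= 0.
tr_maximize <- function(theta0, objective, derivs, N,
                        delta0 = 1, delta_max = 100, max_iter = 500,
                        grad_tol = 1e-6, obj_tol = 1e-9,
                        trace = FALSE) {
  theta <- theta0
  f0 <- objective(theta)
  if (!is.finite(f0)) stop("starting values are infeasible", call. = FALSE)
  delta <- delta0
  conv <- FALSE
  reason <- "maxiter"
  iters <- 0L
  rejects <- 0L
  log_rows <- if (trace) list() else NULL
  d <- derivs(theta)
  for (it in seq_len(max_iter)) {
    iters <- it
    gmax <- max(abs(d$grad))
    if (gmax < grad_tol * N) { conv <- TRUE; reason <- "gradient"; break }
    sub <- solve_tr_subproblem(-d$grad, d$curv, delta)
    pred <- -sub$value                      # predicted increase, >= 0
    if (pred <= 0 || !is.finite(pred)) { conv <- TRUE; reason <- "gradient"
      break }
    f1 <- suppressWarnings(tryCatch(objective(theta + sub$s),
                                    error = function(e) -Inf))
    if (!is.finite(f1)) f1 <- -Inf
    r <- (f1 - f0) / pred
    if (trace) log_rows[[length(log_rows) + 1L]] <-
        data.frame(iter = it, objective = f0, grad_max = gmax,
                   delta = delta, ratio = r)
    if (r > 0) {
      theta <- theta + sub$s
      rel_change <- abs(f1 - f0) / (abs(f0) + 1e-10)
      f0 <- f1
      d <- derivs(theta)
      rejects <- 0L
      if (rel_change < obj_tol) { conv <- TRUE; reason <- "objective"; break }
      if (r > 0.75 && sub$on_boundary) delta <- min(2 * delta, delta_max)
      else if (r < 0.25) delta <- delta / 4
    } else {
      delta <- delta / 4
      rejects <- rejects + 1L
      if (delta < 1e-14) { reason <- "stalled"; break }
    }
  }
  list(theta = theta, value = f0, grad = d$grad, converged = conv,
       reason = reason, iterations = iters, delta = delta,
       trace = if (trace) do.call(rbind, log_rows) else NULL)
}
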