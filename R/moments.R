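#' Model-implied moments
#'
#' Computes the per-group implied covariance matrix
#' \eqn{\Sigma_g = \Lambda_g \Phi_g \Lambda_g^T + \Psi_g} and, when a mean
#' structure is present, the implied mean
#' \eqn{\mu_g = \tau_g + \Lambda_g \kappa_g}.
#'
#' @param theta numeric parameter vector.
#' @param model an [fa_model()] specification.
#' @return A list per group with elements `Sigma` and `mu` (`mu` is a zero
#'   vector when the model has no mean structure).
#' @export
implied_moments <- function(theta, model) {
  groups <- fa_model_unpack(theta, model)
  lapply(groups, function(g) {
    Sigma <- g$Lambda %*% g$Phi %*% t(g$Lambda) + diag(g$Psi, model$p)
    Sigma <- (Sigma + t(Sigma)) / 2
    mu <- if (model$meanstructure) as.numeric(g$tau + g$Lambda %*% g$kappa)
          else rep(0, model$p)
    list(Sigma = Sigma, mu = mu)
  })
}

# Cholesky-based inverse + log-determinant; NULL if not positive definite.
chol_inv_logdet <- function(Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(inv = chol2inv(R), logdet = 2 * sum(log(diag(R))))
}

#' Log-likelihood of the factor model
#'
#' Multivariate-normal log-likelihood evaluated from sufficient statistics:
#' for a single group
#' \eqn{\ell = -\frac{N}{2}\{\log|\Sigma| + tr(S\Sigma^{-1}) + p\log 2\pi\}};
#' with groups and a mean structure \eqn{S} is replaced by
#' \eqn{W_g = S_g + (\bar x_g-\mu_g)(\bar x_g-\mu_g)^T}.
#'
#' @inheritParams implied_moments
#' @param data an [fa_data()] summary.
#' @return scalar log-likelihood (`-Inf` with a warning attribute suppressed
#'   is never returned; a singular implied covariance raises an error naming
#'   the group).
#' @export
fa_loglik <- function(theta, model, data) {
  mom <- implied_moments(theta, model)
  ll <- 0
  for (g in seq_along(mom)) {
    ci <- chol_inv_logdet(mom[[g]]$Sigma)
    if (is.null(ci)) {
      stop("implied covariance matrix singular or not positive definite in ",
           "group ", g, call. = FALSE)
    }
    dg <- data$groups[[g]]
    W <- dg$S
    if (model$meanstructure) {
      d <- dg$xbar - mom[[g]]$mu
      W <- W + tcrossprod(d)
    }
    ll <- ll - (dg$N / 2) * (ci$logdet + sum(W * ci$inv) +
                               model$p * log(2 * pi))
  }
  ll
}

# Derivatives of (Sigma_g, mu_g) w.r.t. the group's free parameters.
# Returns Gmat (p^2 x m_g, columns vec(dSigma/dtheta_k)) and dMu (p x m_g).
fa_dmoments_group <- function(gpars, model, map_g) {
  p <- model$p
  Lambda <- gpars$Lambda
  C <- Lambda %*% gpars$Phi            # p x r
  mk <- length(map_g$id)
  Gmat <- matrix(0, p * p, mk)
  dMu <- if (model$meanstructure) matrix(0, p, mk) else NULL
  seqp <- seq_len(p)
  for (k in seq_len(mk)) {
    i <- map_g$row[[k]]; j <- map_g$col[[k]]
    switch(map_g$mat[[k]],
           lambda = {
             cj <- C[, j]
             idx <- i + (seqp - 1L) * p          # row i of dSigma
             Gmat[idx, k] <- cj
             idx2 <- (i - 1L) * p + seqp         # column i
             Gmat[idx2, k] <- Gmat[idx2, k] + cj
             if (model$meanstructure && gpars$kappa[[j]] != 0)
               dMu[i, k] <- gpars$kappa[[j]]
           },
           psi = { Gmat[(i - 1L) * p + i, k] <- 1 },
           phi = {
             Li <- Lambda[, i]; Lj <- Lambda[, j]
             Gmat[, k] <- if (i == j) tcrossprod(Li)
                          else tcrossprod(Li, Lj) + tcrossprod(Lj, Li)
           },
           tau = { dMu[i, k] <- 1 },
           kappa = { dMu[, k] <- Lambda[, i] })
  }
  list(Gmat = Gmat, dMu = dMu)
}

# Score and Fisher information in one pass (shared unpacking, inverses and
# moment derivatives); the workhorse behind the optimizer.
fa_score_fisher <- function(theta, model, data) {
  groups <- fa_model_unpack(theta, model)
  sc <- numeric(model$m)
  Fi <- matrix(0, model$m, model$m)
  p <- model$p
  for (g in seq_len(model$G)) {
    gp <- groups[[g]]
    Sigma <- gp$Lambda %*% gp$Phi %*% t(gp$Lambda) + diag(gp$Psi, p)
    ci <- chol_inv_logdet((Sigma + t(Sigma)) / 2)
    if (is.null(ci)) stop("implied covariance matrix singular in group ", g,
                          call. = FALSE)
    B <- ci$inv
    dg <- data$groups[[g]]
    map_g <- model$mapg[[g]]
    dm <- fa_dmoments_group(gp, model, map_g)
    W <- dg$S
    if (model$meanstructure) {
      mu <- as.numeric(gp$tau + gp$Lambda %*% gp$kappa)
      d <- dg$xbar - mu
      W <- W + tcrossprod(d)
    }
    Tm <- B %*% (W - Sigma) %*% B
    s <- (dg$N / 2) * as.numeric(crossprod(dm$Gmat, as.numeric(Tm)))
    mk <- length(map_g$id)
    # Tmat[, k] = vec(B M_k B) for symmetric M_k, via two stacked products
    BM <- B %*% matrix(dm$Gmat, p, p * mk)
    BMt <- matrix(aperm(array(BM, c(p, p, mk)), c(2L, 1L, 3L)), p, p * mk)
    Tmat <- matrix(B %*% BMt, p * p, mk)
    Fg <- (dg$N / 2) * crossprod(dm$Gmat, Tmat)
    if (model$meanstructure) {
      s <- s + dg$N * as.numeric(crossprod(dm$dMu, B %*% d))
      Fg <- Fg + dg$N * crossprod(dm$dMu, B %*% dm$dMu)
    }
    sc[map_g$id] <- s
    Fi[map_g$id, map_g$id] <- (Fg + t(Fg)) / 2
  }
  list(score = sc, fisher = Fi)
}

#' Score vector of the log-likelihood
#'
#' Analytic gradient of [fa_loglik()]: for parameter \eqn{\theta_k} the
#' covariance part is
#' \eqn{\frac{N_g}{2} tr[\Sigma^{-1}(W-\Sigma)\Sigma^{-1}
#' \partial\Sigma/\partial\theta_k]} and the mean part
#' \eqn{N_g (\bar x-\mu)^T \Sigma^{-1} \partial\mu/\partial\theta_k}.
#'
#' @inheritParams fa_loglik
#' @return numeric vector of length `model$m`.
#' @export
fa_score <- function(theta, model, data) {
  fa_score_fisher(theta, model, data)$score
}

#' Information matrix of the factor model
#'
#' `kind = "fisher"` returns the expected Fisher information with blocks
#' \eqn{\frac{N_g}{2} tr[\Sigma^{-1}\partial_i\Sigma\,\Sigma^{-1}
#' \partial_j\Sigma] + N_g\,\partial_i\mu^T\Sigma^{-1}\partial_j\mu}.
#' `kind = "hessian"` (single group only) returns the observed information
#' \eqn{-\partial^2\ell/\partial\theta\partial\theta^T}, computed by central
#' finite differences of the analytic score.
#'
#' @inheritParams fa_loglik
#' @param kind `"fisher"` (default) or `"hessian"`.
#' @return symmetric `m x m` matrix.
#' @export
fa_information <- function(theta, model, data, kind = c("fisher", "hessian")) {
  kind <- match.arg(kind)
  if (kind == "hessian") {
    if (model$G > 1L)
      stop("kind = \"hessian\" is only supported for single-group models; ",
           "use kind = \"fisher\"", call. = FALSE)
    h <- 1e-5 * pmax(abs(theta), 1)
    H <- matrix(0, model$m, model$m)
    for (k in seq_len(model$m)) {
      tp <- theta; tp[k] <- tp[k] + h[k]
      tm <- theta; tm[k] <- tm[k] - h[k]
      H[, k] <- (fa_score(tp, model, data) - fa_score(tm, model, data)) /
        (2 * h[k])
    }
    return(-(H + t(H)) / 2)
  }
  fa_score_fisher(theta, model, data)$fisher
}
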