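# Small fixture builders shared across test files. Everything is generated in
# code; no data files.

# one-factor model with p indicators, unit-variance identification
toy_model <- function(p = 4, penalize = "loadings") {
  vn <- paste0("x", seq_len(p))
  fa_model(paste("f1 =~", paste(vn, collapse = " + ")),
           data_header = vn, penalize = penalize)
}

toy_pop_sigma <- function(lambda, psi, phi = 1) {
  tcrossprod(lambda) * phi + diag(psi)
}

# data summary straight from population moments (exact S, no sampling noise)
toy_data_exact <- function(Sigma, N = 200, xbar = NULL) {
  fa_data_from_stats(Sigma, N, xbar = xbar)
}

# random admissible parameter vector for a model (loadings moderate, psi
# bounded away from 0, phi a correlation-like PD matrix)
random_theta <- function(model) {
  groups <- lapply(seq_len(model$G), function(g) {
    Lambda <- model$lambda_fixed
    Lambda[model$lambda_status == 1L] <-
      stats::runif(sum(model$lambda_status), -0.9, 0.9)
    r <- model$r
    A <- matrix(stats::runif(r * r, -0.3, 0.3), r, r)
    Phi <- crossprod(A) + diag(r)
    if (!model$phi_diag_free) Phi <- stats::cov2cor(Phi)
    list(Lambda = Lambda,
         Psi = stats::runif(model$p, 0.4, 1.5),
         Phi = Phi,
         tau = stats::runif(model$p, -0.5, 0.5),
         kappa = stats::runif(model$r, -0.3, 0.3))
  })
  fa_model_pack(groups, model)
}

# central finite-difference gradient of f at x
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

sim1_alasso <- function() penalty_config("alasso", a = 2, gamma = 4.5)
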