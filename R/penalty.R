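#' Penalty configuration
#'
#' Describes the penalty applied to a model: the type of each active term
#' (sparsity of the loadings; for multiple groups also shrinkage of the
#' pairwise cross-group differences of loadings and of intercepts), the
#' tuning parameters, the extra shape parameter `a`, the influence factor
#' `gamma` used by the automatic tuning criterion, and the approximation
#' constant `c_bar` that replaces \eqn{|t|} by \eqn{\sqrt{t^2+\bar c}}.
#'
#' @param sparsity penalty type for loading sparsity: `"lasso"`, `"alasso"`,
#'   `"scad"`, `"mcp"` or `"none"`.
#' @param fuse_loadings,fuse_intercepts penalty types for the cross-group
#'   difference terms (multi-group models); `"none"` disables a term.
#' @param eta `"auto"` for automatic tuning (lasso/alasso only), or a numeric
#'   vector of fixed nonnegative tuning parameters named after the active
#'   terms (a single unnamed value is recycled).
#' @param a shape parameter: adaptive-lasso exponent (`a > 0`), scad
#'   concavity (`a > 2`) or mcp concavity (`a > 1`). Defaults: 1 (alasso),
#'   3.7 (scad), 3 (mcp).
#' @param gamma influence factor \eqn{\gamma \ge 1}: multiplies the model
#'   complexity term of the tuning criterion, pushing the automatic selector
#'   toward sparser solutions.
#' @param c_bar local approximation constant \eqn{\bar c > 0}.
#' @param weights optional adaptive weights for the alasso, named list with
#'   entries `sparsity`, `fuse_loadings`, `fuse_intercepts`; defaults to
#'   \eqn{1/|\hat\theta^{MLE}|^a} computed from the unpenalized fit.
#' @return An object of class `fa_penalty`.
#' @export
penalty_config <- function(sparsity = "alasso",
                           fuse_loadings = sparsity,
                           fuse_intercepts = sparsity,
                           eta = "auto", a = NULL, gamma = 1,
                           c_bar = 1e-8, weights = NULL) {
  types <- c("lasso", "alasso", "scad", "mcp", "none")
  sparsity <- match.arg(sparsity, types)
  fuse_loadings <- match.arg(fuse_loadings, types)
  fuse_intercepts <- match.arg(fuse_intercepts, types)
  if (is.null(a)) {
    a <- c(lasso = NA_real_, alasso = 1, scad = 3.7, mcp = 3,
           none = NA_real_)[[sparsity]]
  }
  for (ty in c(sparsity, fuse_loadings, fuse_intercepts)) {
    if (ty == "scad" && a <= 2) stop("scad requires a > 2", call. = FALSE)
    if (ty == "mcp" && a <= 1) stop("mcp requires a > 1", call. = FALSE)
    if (ty == "alasso" && (is.na(a) || a <= 0))
      stop("alasso requires a > 0", call. = FALSE)
  }
  if (c_bar <= 0) stop("c_bar must be positive", call. = FALSE)
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  auto <- identical(eta, "auto")
  if (auto) {
    nonauto <- setdiff(unique(c(sparsity, fuse_loadings, fuse_intercepts)),
                       c("lasso", "alasso", "none"))
    if (length(nonauto)) {
      stop("automatic tuning is only available for lasso/alasso penalties; ",
           "use a grid search for ", paste(nonauto, collapse = "/"),
           call. = FALSE)
    }
  } else {
    eta <- stats::setNames(as.numeric(eta), names(eta))
    if (any(eta < 0) || anyNA(eta)) stop("tuning parameters must be ",
                                         "nonnegative numbers", call. = FALSE)
  }
  structure(list(sparsity = sparsity, fuse_loadings = fuse_loadings,
                 fuse_intercepts = fuse_intercepts,
                 eta = if (auto) "auto" else eta, auto = auto,
                 a = a, gamma = gamma, c_bar = c_bar, weights = weights),
            class = "fa_penalty")
}

#' @export
print.fa_penalty <- function(x, ...) {
  cat("fa_penalty: sparsity =", x$sparsity)
  if (x$fuse_loadings != "none" || x$fuse_intercepts != "none")
    cat(", fuse_loadings =", x$fuse_loadings,
        ", fuse_intercepts =", x$fuse_intercepts)
  cat("\n  eta =", if (x$auto) "auto" else paste(signif(x$eta, 4),
                                                 collapse = ", "),
      " a =", x$a, " gamma =", x$gamma, "\n")
  invisible(x)
}

# scalar penalty value P(u) at u = ||.||_1 (or its smooth surrogate), and its
# first derivative P'(u); vectorized over u.
pen_fun <- function(u, type, eta, a = NA, w = 1) {
  switch(type,
         lasso = eta * u,
         alasso = eta * w * u,
         scad = ifelse(u <= eta, eta * u,
                ifelse(u <= a * eta,
                       -(u^2 - 2 * a * eta * u + eta^2) / (2 * (a - 1)),
                       (a + 1) * eta^2 / 2)),
         mcp = ifelse(u <= a * eta, eta * u - u^2 / (2 * a), a * eta^2 / 2),
         stop("unknown penalty type: ", type, call. = FALSE))
}

pen_deriv <- function(u, type, eta, a = NA, w = 1) {
  switch(type,
         lasso = rep(eta, length(u)),
         alasso = rep_len(eta * w, length(u)),
         scad = ifelse(u <= eta, eta,
                ifelse(u <= a * eta, (a * eta - u) / (a - 1), 0)),
         mcp = ifelse(u <= a * eta, eta - u / a, 0),
         stop("unknown penalty type: ", type, call. = FALSE))
}

#' Local-approximation shrink weight
#'
#' The diagonal entry of the penalty matrix for one penalized parameter at
#' expansion point \eqn{\tilde\theta_q}:
#' \eqn{m_q = P'_{\eta}(\sqrt{\tilde\theta_q^2+\bar c}) /
#' \sqrt{\tilde\theta_q^2+\bar c}}.
#'
#' @param theta_tilde_q expansion value of the penalized parameter.
#' @param type penalty type (`"lasso"`, `"alasso"`, `"scad"`, `"mcp"`).
#' @param eta nonnegative tuning parameter.
#' @param a shape parameter (alasso exponent, scad/mcp concavity).
#' @param w adaptive weight (alasso only).
#' @param c_bar approximation constant.
#' @return nonnegative scalar (vectorized over `theta_tilde_q`).
#' @export
shrink_weight <- function(theta_tilde_q, type, eta, a = NA, w = 1,
                          c_bar = 1e-8) {
  if (any(eta < 0)) stop("tuning parameter must be nonnegative", call. = FALSE)
  u <- sqrt(theta_tilde_q^2 + c_bar)
  pen_deriv(u, type, eta, a, w) / u
}

#' Selector matrices for penalized parameters
#'
#' Builds the diagonal selector matrices \eqn{R_q} (one per sparsity-penalized
#' loading, a single 1 on the diagonal) and, for multi-group models, the
#' pairwise difference maps \eqn{D_q^\Lambda} and \eqn{D_q^\tau} whose rows
#' compute the cross-group differences of the q-th penalized loading or
#' intercept (one row per group pair, `choose(G, 2)` rows).
#'
#' @param model an [fa_model()] specification.
#' @return A list with `R` (list of m x m matrices indexed by the penalized
#'   loading's flat position), `D_lambda` and `D_tau` (lists of
#'   `choose(G,2) x m` matrices indexed by the within-group parameter), and
#'   the index bookkeeping used internally (`pen_idx`, `pairs_lambda`,
#'   `pairs_tau`).
#' @export
build_selectors <- function(model) {
  m <- model$m
  map <- model$map
  pen1 <- which(map$group == 1L & map$pen)          # within-group positions
  pen_idx <- lapply(seq_len(model$G), function(g)
    map$id[map$group == g & map$pen])
  R <- lapply(unlist(pen_idx), function(q) {
    Rq <- matrix(0, m, m); Rq[q, q] <- 1; Rq
  })
  names(R) <- as.character(unlist(pen_idx))
  gp <- if (model$G > 1L) utils::combn(model$G, 2) else NULL
  mk_D <- function(within_pos) {
    lapply(within_pos, function(q0) {
      D <- matrix(0, if (is.null(gp)) 0 else ncol(gp), m)
      if (!is.null(gp)) {
        for (k in seq_len(ncol(gp))) {
          D[k, (gp[1, k] - 1L) * model$m1 + q0] <- 1
          D[k, (gp[2, k] - 1L) * model$m1 + q0] <- -1
        }
      }
      D
    })
  }
  lam_pos <- pen1
  tau_pos <- which(map$group == 1L & map$mat == "tau")
  sel <- list(R = R,
              D_lambda = mk_D(lam_pos),
              D_tau = mk_D(tau_pos),
              pen_idx = pen_idx,
              lam_pos = lam_pos, tau_pos = tau_pos,
              group_pairs = gp)
  sel
}

# Resolved penalty terms: everything needed to evaluate the penalty and its
# local quadratic approximation without touching the model again.
# Each term: list(kind, type, a, and either idx+w (sparsity) or
# pairs (2 x npair global index matrix, grouped per within-group parameter via
# pair_of) + w per within-group parameter.
pen_terms <- function(model, penalty, weights = NULL) {
  terms <- list()
  map <- model$map
  if (penalty$sparsity != "none" && model$qstar > 0) {
    idx <- map$id[map$pen]
    w <- rep(1, length(idx))
    if (penalty$sparsity == "alasso") {
      wraw <- weights$sparsity %||% penalty$weights$sparsity
      if (is.null(wraw)) stop("alasso sparsity term needs adaptive weights ",
                              "(supply an unpenalized fit)", call. = FALSE)
      w <- wraw
    }
    terms$sparsity <- list(kind = "sparsity", type = penalty$sparsity,
                           a = penalty$a, idx = idx, w = w)
  }
  if (model$G > 1L) {
    gp <- utils::combn(model$G, 2)
    mk_pairs <- function(within_pos) {
      do.call(cbind, lapply(within_pos, function(q0)
        rbind((gp[1, ] - 1L) * model$m1 + q0,
              (gp[2, ] - 1L) * model$m1 + q0,
              match(q0, within_pos))))
    }
    lam_pos <- which(map$group == 1L & map$pen)
    tau_pos <- which(map$group == 1L & map$mat == "tau")
    if (penalty$fuse_loadings != "none" && length(lam_pos)) {
      w <- rep(1, length(lam_pos))
      if (penalty$fuse_loadings == "alasso") {
        wraw <- weights$fuse_loadings %||% penalty$weights$fuse_loadings
        if (is.null(wraw)) stop("alasso difference term needs adaptive ",
                                "weights", call. = FALSE)
        w <- wraw
      }
      terms$fuse_loadings <- list(kind = "fuse", type = penalty$fuse_loadings,
                                  a = penalty$a, pairs = mk_pairs(lam_pos),
                                  npar = length(lam_pos), w = w)
    }
    if (penalty$fuse_intercepts != "none" && length(tau_pos)) {
      w <- rep(1, length(tau_pos))
      if (penalty$fuse_intercepts == "alasso") {
        wraw <- weights$fuse_intercepts %||% penalty$weights$fuse_intercepts
        if (is.null(wraw)) stop("alasso difference term needs adaptive ",
                                "weights", call. = FALSE)
        w <- wraw
      }
      terms$fuse_intercepts <- list(kind = "fuse",
                                    type = penalty$fuse_intercepts,
                                    a = penalty$a, pairs = mk_pairs(tau_pos),
                                    npar = length(tau_pos), w = w)
    }
  }
  terms
}

# Default adaptive weights 1/|theta_mle|^a per term (pairwise differences for
# the fuse terms).
alasso_weights <- function(theta_mle, model, penalty) {
  map <- model$map
  a <- penalty$a
  out <- list()
  out$sparsity <- 1 / abs(theta_mle[map$id[map$pen]])^a
  if (model$G > 1L) {
    gp <- utils::combn(model$G, 2)
    dmean <- function(within_pos) {
      vapply(within_pos, function(q0) {
        d <- abs(theta_mle[(gp[1, ] - 1L) * model$m1 + q0] -
                   theta_mle[(gp[2, ] - 1L) * model$m1 + q0])
        1 / mean(d)^a
      }, numeric(1))
    }
    out$fuse_loadings <- dmean(which(map$group == 1L & map$pen))
    out$fuse_intercepts <- dmean(which(map$group == 1L & map$mat == "tau"))
  }
  out
}

# Smooth (approximated) penalty value: sum over terms of
# P_eta(sqrt(t^2 + c_bar)) with t the selected parameter or the sum of smooth
# absolute pairwise differences for the fuse terms.
penalty_value_terms <- function(theta, terms, eta, c_bar) {
  val <- 0
  for (j in seq_along(terms)) {
    tr <- terms[[j]]
    ej <- eta[[j]]
    if (tr$kind == "sparsity") {
      u <- sqrt(theta[tr$idx]^2 + c_bar)
      val <- val + sum(pen_fun(u, tr$type, ej, tr$a, tr$w))
    } else {
      d <- theta[tr$pairs[1, ]] - theta[tr$pairs[2, ]]
      us <- sqrt(d^2 + c_bar)
      u <- as.numeric(rowsum(us, tr$pairs[3, ]))  # ordered by parameter index
      val <- val + sum(pen_fun(u, tr$type, ej, tr$a, tr$w))
    }
  }
  val
}

#' Evaluate the (approximated) penalty
#'
#' Total penalty \eqn{\sum_j \sum_q P^T_{\eta_j,q}(\cdot)} with each
#' \eqn{L_1} norm replaced by its smooth surrogate
#' \eqn{\sqrt{t^2 + \bar c}}; the exact non-differentiable penalty is
#' recovered as \eqn{\bar c \to 0}.
#'
#' @param theta parameter vector.
#' @param model an [fa_model()] specification.
#' @param penalty an [penalty_config()] object with numeric `eta`.
#' @param weights adaptive weights as produced internally from an unpenalized
#'   fit (only needed for alasso).
#' @return scalar penalty value.
#' @export
penalty_value <- function(theta, model, penalty, weights = NULL) {
  terms <- pen_terms(model, penalty, weights)
  eta <- resolve_eta(penalty, terms)
  penalty_value_terms(theta, terms, eta, penalty$c_bar)
}

# named eta vector aligned with terms
resolve_eta <- function(penalty, terms) {
  if (penalty$auto) stop("eta is 'auto'; resolved tuning values required",
                         call. = FALSE)
  eta <- penalty$eta
  if (is.null(names(eta)) || !any(nzchar(names(eta)))) {
    if (length(eta) == 1L) eta <- rep(eta, length(terms))
    if (length(eta) != length(terms))
      stop("need one tuning parameter per active penalty term (",
           paste(names(terms), collapse = ", "), ")", call. = FALSE)
    names(eta) <- names(terms)
  }
  miss <- setdiff(names(terms), names(eta))
  if (length(miss)) stop("missing tuning parameter(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  eta[names(terms)]
}

# Penalty matrix E(eta; theta_tilde): local quadratic representation of the
# approximated penalty. Rows/cols of unpenalized parameters are zero. For the
# difference terms each pair (i, j) contributes +m on (i,i),(j,j) and -m on
# (i,j),(j,i) so that N E theta reproduces the penalty gradient.
penalty_matrix_terms <- function(theta_tilde, terms, eta, c_bar, m) {
  E <- matrix(0, m, m)
  for (j in seq_along(terms)) {
    tr <- terms[[j]]
    ej <- eta[[j]]
    if (ej == 0) next
    if (tr$kind == "sparsity") {
      mq <- shrink_weight(theta_tilde[tr$idx], tr$type, ej, tr$a, tr$w, c_bar)
      diag(E)[tr$idx] <- diag(E)[tr$idx] + mq
    } else {
      d <- theta_tilde[tr$pairs[1, ]] - theta_tilde[tr$pairs[2, ]]
      us <- sqrt(d^2 + c_bar)
      u <- as.numeric(rowsum(us, tr$pairs[3, ]))  # ||D_q theta||_1 approx
      dP <- pen_deriv(u, tr$type, ej, tr$a, tr$w)
      mq <- dP[tr$pairs[3, ]] / us
      for (k in seq_len(ncol(tr$pairs))) {
        i1 <- tr$pairs[1, k]; i2 <- tr$pairs[2, k]
        E[i1, i1] <- E[i1, i1] + mq[[k]]
        E[i2, i2] <- E[i2, i2] + mq[[k]]
        E[i1, i2] <- E[i1, i2] - mq[[k]]
        E[i2, i1] <- E[i2, i1] - mq[[k]]
      }
    }
  }
  E
}

#' Build the penalty matrix at an expansion point
#'
#' Returns the block penalty matrix \eqn{E(\eta;\tilde\theta)} whose local
#' quadratic form represents the approximated penalty: the sparsity term
#' contributes the shrink weights on the diagonal of the penalized loadings,
#' and each cross-group difference term a paired +/- pattern on the involved
#' coordinates.
#'
#' @inheritParams penalty_value
#' @param theta_tilde expansion point.
#' @return `m x m` symmetric matrix.
#' @export
build_penalty_matrix <- function(theta_tilde, model, penalty, weights = NULL) {
  terms <- pen_terms(model, penalty, weights)
  eta <- resolve_eta(penalty, terms)
  penalty_matrix_terms(theta_tilde, terms, eta, penalty$c_bar, model$m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
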