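#' Population presets for the Monte-Carlo studies
#'
#' `"sim1"` is a single-group model with p = 9 variables and r = 3 correlated
#' factors (unit variances, correlations 0.3); primary loadings are 0.85,
#' 0.75, 0.65 per factor, three variables carry a 0.30 cross-loading, and the
#' unique variances make the observed variances equal to one
#' (\eqn{\psi_i = 1 - (\Lambda\Phi\Lambda^T)_{ii}}). All 21 free loadings are
#' penalized; 12 are truly nonzero and 9 truly zero.
#'
#' `"sim2-null"`, `"sim2-small"`, `"sim2-medium"`, `"sim2-large"` are
#' two-group, two-factor models with p = 12 variables, marker variables x1
#' and x7 (loadings fixed at 0.85, intercepts at zero), invariant structural
#' parameters (\eqn{vech(\Phi) = (1, 0.3, 1)}, \eqn{\kappa = (0,0)}), and a
#' group-2 deviation of 0.1 / 0.2 / 0.3 on the primary loading and intercept
#' of x6 and x12 in the small / medium / large scenarios.
#'
#' @param name preset name.
#' @return A list with the true per-group matrices, the estimation-model
#'   syntax, the parsed [fa_model()] and the true parameter vector `theta0`.
#' @export
sim_population <- function(name = c("sim1", "sim2-null", "sim2-small",
                                    "sim2-medium", "sim2-large")) {
  name <- match.arg(name)
  if (name == "sim1") {
    p <- 9; r <- 3
    Lambda <- matrix(0, p, r)
    Lambda[1:3, 1] <- c(0.85, 0.75, 0.65)
    Lambda[4:6, 2] <- c(0.85, 0.75, 0.65)
    Lambda[7:9, 3] <- c(0.85, 0.75, 0.65)
    Lambda[9, 1] <- 0.30; Lambda[3, 2] <- 0.30; Lambda[6, 3] <- 0.30
    Phi <- matrix(0.3, r, r); diag(Phi) <- 1
    syntax <- paste(
      "f1 =~ x1 + x2 + x3 + x5 + x6 + x8 + x9",
      "f2 =~ x2 + x3 + x4 + x5 + x6 + x8 + x9",
      "f3 =~ x2 + x3 + x5 + x6 + x7 + x8 + x9", sep = "\n")
    vn <- paste0("x", 1:p)
    model <- fa_model(syntax, data_header = vn, ngroups = 1L)
    groups <- list(pop_group(Lambda, Phi, tau = rep(0, p),
                             kappa = rep(0, r), name))
  } else {
    p <- 12; r <- 2
    delta <- c("sim2-null" = 0, "sim2-small" = 0.1, "sim2-medium" = 0.2,
               "sim2-large" = 0.3)[[name]]
    L1 <- matrix(0, p, r)
    L1[1:6, 1] <- c(0.85, 0.85, 0.85, 0.75, 0.75, 0.75)
    L1[7:12, 2] <- c(0.85, 0.85, 0.85, 0.75, 0.75, 0.75)
    L2 <- L1
    L2[6, 1] <- L2[6, 1] - delta
    L2[12, 2] <- L2[12, 2] - delta
    tau1 <- rep(0, p)
    tau2 <- tau1; tau2[6] <- -delta; tau2[12] <- -delta
    Phi <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
    vn <- paste0("x", 1:p)
    syntax <- paste(
      paste("f1 =~ 0.85*x1 +", paste(vn[c(2:6, 8:12)], collapse = " + ")),
      paste("f2 =~ 0.85*x7 +", paste(vn[c(2:6, 8:12)], collapse = " + ")),
      sep = "\n")
    model <- fa_model(syntax, data_header = vn, ngroups = 2L)
    groups <- list(pop_group(L1, Phi, tau1, c(0, 0), name),
                   pop_group(L2, Phi, tau2, c(0, 0), name))
  }
  theta0 <- fa_model_pack(groups, model)
  pen_ids <- model$map$id[model$map$pen]
  list(name = name, p = model$p, r = model$r, G = model$G,
       groups = groups, model_syntax = syntax, model = model,
       var_names = vn, theta0 = theta0,
       pen_ids = pen_ids,
       nonzero_ids = pen_ids[theta0[pen_ids] != 0],
       zero_ids = pen_ids[theta0[pen_ids] == 0])
}

pop_group <- function(Lambda, Phi, tau, kappa, preset) {
  Psi <- 1 - diag(Lambda %*% Phi %*% t(Lambda))
  if (any(Psi <= 0))
    stop("invalid preset '", preset, "': implied unique variance <= 0",
         call. = FALSE)
  list(Lambda = Lambda, Psi = Psi, Phi = Phi, tau = tau, kappa = kappa)
}

#' Generate a dataset from a population preset
#'
#' Draws i.i.d. multivariate-normal observations per group from the implied
#' moments of the preset.
#'
#' @param pop a [sim_population()] preset.
#' @param N total sample size; for several groups either a single value split
#'   evenly or a vector of per-group sizes.
#' @param seed integer seed (mandatory, for reproducibility).
#' @return A data frame of observed variables, plus a `group` column when the
#'   preset has several groups.
#' @export
sim_generate <- function(pop, N, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  G <- pop$G
  Ng <- if (length(N) == G) N else {
    stopifnot(length(N) == 1L)
    rep(floor(N / G), G) + c(rep(1L, N %% G), rep(0L, G - N %% G))
  }
  out <- vector("list", G)
  for (g in seq_len(G)) {
    pg <- pop$groups[[g]]
    Sigma <- pg$Lambda %*% pg$Phi %*% t(pg$Lambda) + diag(pg$Psi)
    mu <- pg$tau + as.numeric(pg$Lambda %*% pg$kappa)
    X <- MASS::mvrnorm(Ng[[g]], mu = mu, Sigma = Sigma)
    colnames(X) <- pop$var_names
    df <- as.data.frame(X)
    if (G > 1L) df$group <- g
    out[[g]] <- df
  }
  do.call(rbind, out)
}

#' Align estimated factor signs with the population
#'
#' Factor models are identified only up to a sign reversal of each factor
#' (single-group, unit-variance identification). Each factor's sign is
#' flipped so the estimated loadings agree in sign with the population
#' primaries; factor covariances and means are flipped consistently. The
#' operation is idempotent.
#'
#' @param theta_hat estimated parameter vector.
#' @param pop a [sim_population()] preset.
#' @return The aligned parameter vector.
#' @export
align_signs <- function(theta_hat, pop) {
  model <- pop$model
  est <- fa_model_unpack(theta_hat, model)
  for (g in seq_len(model$G)) {
    L0 <- pop$groups[[g]]$Lambda
    s <- vapply(seq_len(model$r), function(f) {
      v <- sum(est[[g]]$Lambda[, f] * L0[, f])
      if (v < 0) -1 else 1
    }, numeric(1))
    est[[g]]$Lambda <- sweep(est[[g]]$Lambda, 2L, s, `*`)
    est[[g]]$Phi <- est[[g]]$Phi * tcrossprod(s)
    est[[g]]$kappa <- est[[g]]$kappa * s
  }
  fa_model_pack(est, model)
}

#' Classify estimates as zero
#'
#' An estimate counts as zero when it rounds to zero at one decimal digit
#' (\eqn{|round(\hat\theta, 1)| = 0}), the report-time rule used for the
#' false-positive and model-selection summaries.
#'
#' @param x numeric vector of estimates.
#' @param digits rounding digits (default 1).
#' @return logical vector, `TRUE` where classified as zero.
#' @export
classify_zero <- function(x, digits = 1) {
  abs(round(x, digits)) < .Machine$double.eps^0.5
}

#' Monte-Carlo performance metrics
#'
#' Computes, over replicates, the estimated mean squared error
#' \eqn{MSE = \frac1L\sum_l (\hat\theta^{(l)}-\theta_0)^T
#' (\hat\theta^{(l)}-\theta_0)}, squared bias
#' \eqn{SB = (\bar{\hat\theta}-\theta_0)^T(\bar{\hat\theta}-\theta_0)}, true
#' and false positive rates of the penalized loadings under the one-decimal
#' rounding rule, and the proportion of replicates recovering the exact
#' zero/nonzero pattern (PCTM).
#'
#' @param theta_mat matrix of aligned estimates, one row per replicate.
#' @param pop a [sim_population()] preset.
#' @return A one-row tibble of metrics with Monte-Carlo standard errors and
#'   ranges.
#' @export
sim_metrics <- function(theta_mat, pop) {
  theta_mat <- as.matrix(theta_mat)
  L <- nrow(theta_mat)
  if (!L) stop("no replicates", call. = FALSE)
  dev <- sweep(theta_mat, 2L, pop$theta0)
  mse_l <- rowSums(dev^2)
  thbar <- colMeans(theta_mat)
  sb <- sum((thbar - pop$theta0)^2)
  nz <- pop$nonzero_ids; ze <- pop$zero_ids
  tpr_l <- apply(theta_mat, 1L, function(th)
    mean(!classify_zero(th[nz])))
  fpr_l <- apply(theta_mat, 1L, function(th)
    mean(!classify_zero(th[ze])))
  pctm_l <- apply(theta_mat, 1L, function(th)
    all(!classify_zero(th[nz])) && all(classify_zero(th[ze])))
  tibble::tibble(
    L = L,
    mse = mean(mse_l), mse_se = stats::sd(mse_l) / sqrt(L),
    mse_min = min(mse_l), mse_max = max(mse_l),
    sb = sb,
    tpr = mean(tpr_l), tpr_se = stats::sd(tpr_l) / sqrt(L),
    tpr_min = min(tpr_l), tpr_max = max(tpr_l),
    fpr = mean(fpr_l), fpr_se = stats::sd(fpr_l) / sqrt(L),
    fpr_min = min(fpr_l), fpr_max = max(fpr_l),
    pctm = mean(pctm_l),
    pctm_se = sqrt(mean(pctm_l) * (1 - mean(pctm_l)) / L))
}

# Deterministic per-replicate/attempt seed below 2^31.
replicate_seed <- function(master, l, attempt) {
  as.integer((as.numeric(master) + 7919 * l + 104729 * attempt) %% 2147483647L
             + 1)
}

#' Run one Monte-Carlo study condition
#'
#' Generates `L` replicate datasets from a population preset, fits the
#' requested estimator to each, aligns factor signs, and summarizes the
#' performance metrics. Replicates whose unpenalized maximum-likelihood fit
#' is inadmissible (nonpositive unique variance, non-positive-definite factor
#' covariance) are regenerated from a fresh seed rather than dropped, so the
#' summary is always over `L` admissible replicates.
#'
#' @param pop a [sim_population()] preset or preset name.
#' @param N total sample size per replicate.
#' @param L number of replicates.
#' @param seed master seed; per-replicate seeds are derived by a counter
#'   scheme so regeneration is reproducible.
#' @param estimator `"mle"`, `"auto"` (automatic tuning) or `"grid"`.
#' @param penalty a [penalty_config()] for the penalized estimators.
#' @param eta_grid grid of tuning values (`estimator = "grid"`).
#' @param information `"fisher"` or `"hessian"`.
#' @param retry_cap maximum regenerations per replicate slot.
#' @param workers number of parallel workers (forked; results do not depend
#'   on the worker count since every replicate has a fixed seed).
#' @return An object of class `fa_study`: list with `metrics` (tibble),
#'   `theta` (L x m matrix of aligned estimates), `replicates` (per-replicate
#'   tibble) and the seed ledger.
#' @export
sim_study <- function(pop, N, L, seed,
                      estimator = c("auto", "mle", "grid"),
                      penalty = penalty_config("alasso", a = 2, gamma = 4.5),
                      eta_grid = NULL, information = "fisher",
                      retry_cap = 25L, workers = 1L) {
  estimator <- match.arg(estimator)
  if (is.character(pop)) pop <- sim_population(pop)
  model <- pop$model
  one_rep <- function(l) {
    for (attempt in seq_len(retry_cap)) {
      sd_la <- replicate_seed(seed, l, attempt)
      dat <- sim_generate(pop, N, seed = sd_la)
      ds <- fa_data(dat, vars = pop$var_names,
                    group = if (pop$G > 1L) "group" else NULL)
      mle <- tryCatch(fa_fit_mle(ds, model, information = information),
                      error = function(e) NULL)
      if (is.null(mle) || !mle$convergence$converged || !mle$admissible) next
      fit <- switch(estimator,
        mle = mle,
        auto = tryCatch(fa_auto_tune(ds, model, penalty, mle = mle,
                                     information = information),
                        error = function(e) NULL),
        grid = tryCatch(fa_grid(ds, model, penalty, eta_grid, mle = mle,
                                information = information),
                        error = function(e) NULL))
      if (is.null(fit)) next
      return(list(theta = align_signs(fit$theta, pop), seed = sd_la,
                  attempts = attempt, edf = fit$edf, gbic = fit$gbic,
                  gbic_mle = mle$gbic))
    }
    stop("replicate ", l, ": no admissible fit within ", retry_cap,
         " attempts", call. = FALSE)
  }
  reps <- if (workers > 1L) {
    parallel::mclapply(seq_len(L), one_rep, mc.cores = workers)
  } else lapply(seq_len(L), one_rep)
  errs <- vapply(reps, inherits, logical(1), "try-error")
  if (any(vapply(reps, function(x) !is.list(x), logical(1))))
    stop("replicate failures in parallel execution", call. = FALSE)
  theta_mat <- do.call(rbind, lapply(reps, `[[`, "theta"))
  rep_tbl <- tibble::tibble(
    replicate = seq_len(L),
    seed = vapply(reps, `[[`, 0, "seed"),
    attempts = vapply(reps, `[[`, 0, "attempts"),
    edf = vapply(reps, `[[`, 0, "edf"),
    gbic = vapply(reps, `[[`, 0, "gbic"),
    gbic_mle = vapply(reps, `[[`, 0, "gbic_mle"))
  metrics <- sim_metrics(theta_mat, pop)
  metrics <- tibble::add_column(metrics,
                                preset = pop$name, N = sum(N),
                                estimator = estimator, .before = 1L)
  structure(list(metrics = metrics, theta = theta_mat, replicates = rep_tbl,
                 pop = pop, N = N, L = L, seed = seed,
                 estimator = estimator),
            class = "fa_study")
}

#' @export
print.fa_study <- function(x, ...) {
  cat(sprintf("fa_study: %s, N = %d, L = %d, estimator = %s\n",
              x$pop$name, sum(x$N), x$L, x$estimator))
  print(as.data.frame(x$metrics[c("mse", "sb", "tpr", "fpr", "pctm")]),
        row.names = FALSE)
  invisible(x)
}

#' Run several study conditions
#'
#' Maps [sim_study()] over a condition table and binds the metric rows.
#'
#' @param conditions a data frame with columns `preset`, `N` and optionally
#'   `estimator` (default `"auto"`).
#' @inheritParams sim_study
#' @return A tibble of metrics, one row per condition.
#' @export
sim_study_table <- function(conditions, L, seed,
                            penalty = penalty_config("alasso", a = 2,
                                                     gamma = 4.5),
                            eta_grid = NULL, information = "fisher",
                            workers = 1L) {
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    est <- if ("estimator" %in% names(cond)) cond$estimator else "auto"
    st <- sim_study(cond$preset, N = cond$N, L = L, seed = seed,
                    estimator = est, penalty = penalty, eta_grid = eta_grid,
                    information = information, workers = workers)
    st$metrics
  })
  dplyr::bind_rows(rows)
}
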