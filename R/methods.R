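#' @importFrom stats coef logLik
#' @export
print.fa_fit <- function(x, ...) {
  pen <- !is.null(x$penalty)
  cat("sparsefa fit:",
      if (pen) paste0("penalized (", x$penalty$sparsity, ")")
      else "maximum likelihood", "\n")
  cat(sprintf("  N = %d, free parameters = %d, edf = %.2f\n",
              as.integer(x$data$N), x$model$m, x$edf))
  cat(sprintf("  logLik = %.3f, GBIC = %.3f\n", x$loglik, x$gbic))
  if (pen && length(x$eta))
    cat("  eta =", paste(sprintf("%s=%.4g", names(x$eta), x$eta),
                         collapse = ", "), "\n")
  if (!x$convergence$converged)
    cat("  WARNING: optimizer did not converge (", x$convergence$reason,
        ")\n", sep = "")
  if (!x$admissible) cat("  WARNING: solution is inadmissible\n")
  invisible(x)
}

#' Tidy a fitted penalized factor model
#'
#' One row per free parameter with estimate, per-parameter effective degrees
#' of freedom, posterior standard error and confidence interval, and the
#' report-time zero classification of penalized loadings (estimate rounded to
#' one decimal equal to zero).
#'
#' @param x an `fa_fit`.
#' @param conf.level confidence level for the posterior intervals.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.fa_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = x$model$map$name,
    group = x$model$map$group,
    matrix = x$model$map$mat,
    estimate = x$theta,
    penalized = x$model$map$pen,
    edf = x$edf_per,
    std.error = x$se,
    conf.low = x$theta - z * x$se,
    conf.high = x$theta + z * x$se,
    zeroed = x$model$map$pen & classify_zero(x$theta))
}

#' Glance at a fitted penalized factor model
#'
#' @param x an `fa_fit`.
#' @param ... unused.
#' @return A one-row tibble with sample size, parameter counts, edf,
#'   log-likelihood, GBIC, tuning values and convergence.
#' @export
glance.fa_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$data$N,
    npar = x$model$m,
    edf = x$edf,
    logLik = x$loglik,
    gbic = x$gbic,
    eta = if (length(x$eta)) paste(sprintf("%s=%.4g", names(x$eta), x$eta),
                                   collapse = ", ") else "0",
    converged = x$convergence$converged,
    admissible = x$admissible)
}

#' @export
coef.fa_fit <- function(object, ...) {
  stats::setNames(object$theta, object$model$map$name)
}

#' @export
logLik.fa_fit <- function(object, ...) {
  structure(object$loglik, df = object$edf, nobs = object$data$N,
            class = "logLik")
}

#' @export
summary.fa_fit <- function(object, ...) {
  print(object)
  cat("\nParameter estimates:\n")
  print(tidy.fa_fit(object), n = Inf)
  invisible(object)
}

#' Plot the estimate profile of a fitted model
#'
#' Dot-and-interval plot of the estimates with posterior intervals, facetted
#' by parameter matrix; penalized loadings classified as zero are highlighted.
#'
#' @param object an `fa_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fa_fit <- function(object, ...) {
  td <- tidy.fa_fit(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$zeroed)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$matrix),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 name = "set to zero") +
    ggplot2::labs(x = "estimate (95% posterior interval)", y = NULL)
}

#' Plot a tuning-parameter search path
#'
#' Shows GBIC and effective degrees of freedom along the grid-search path of
#' a [fa_grid()] fit.
#'
#' @param fit an `fa_fit` produced by [fa_grid()].
#' @return A ggplot object.
#' @export
plot_path <- function(fit) {
  if (is.null(fit$path)) stop("fit has no search path; use fa_grid()",
                              call. = FALSE)
  pd <- fit$path[!is.na(fit$path$gbic), ]
  pd$eta_num <- vapply(strsplit(pd$eta, ","),
                       function(x) sum(as.numeric(x)), numeric(1))
  long <- rbind(
    data.frame(eta = pd$eta_num, value = pd$gbic, what = "GBIC"),
    data.frame(eta = pd$eta_num, value = pd$edf, what = "edf"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eta, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), scales = "free_y") +
    ggplot2::labs(x = "tuning parameter (sum over terms)", y = NULL)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Serialize a fit summary to JSON
#'
#' Writes the estimates table (value, edf, interval, penalized flag), tuning
#' parameters, total edf, log-likelihood, GBIC and the convergence block.
#'
#' @param fit an `fa_fit`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
fa_fit_json <- function(fit, path = NULL) {
  out <- list(
    estimates = tidy.fa_fit(fit),
    eta = as.list(if (length(fit$eta)) fit$eta else c(none = 0)),
    gamma = if (!is.null(fit$penalty)) fit$penalty$gamma else NA,
    a = if (!is.null(fit$penalty)) fit$penalty$a else NA,
    edf = fit$edf,
    loglik = fit$loglik,
    gbic = fit$gbic,
    N = fit$data$N,
    convergence = fit$convergence,
    admissible = fit$admissible)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
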