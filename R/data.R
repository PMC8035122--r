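#' Per-group sufficient statistics for factor analysis
#'
#' Reduces a raw data frame (rows = subjects, columns = observed variables,
#' optionally a group column) to the sufficient statistics of the normal
#' factor model: per-group sample size \eqn{N_g}, sample covariance matrix
#' \eqn{S_g} (maximum-likelihood divisor \eqn{N_g}) and mean vector
#' \eqn{\bar x_g}.
#'
#' @param data a data frame or matrix of numeric observations.
#' @param vars character vector of variable columns to use; default all
#'   numeric columns except `group`.
#' @param group optional name of a group column.
#' @return An object of class `fa_data`: a list with elements `groups` (each
#'   with `N`, `S`, `xbar`, `label`), `N` (total), `p` and `var_names`.
#' @export
fa_data <- function(data, vars = NULL, group = NULL) {
  data <- as.data.frame(data)
  if (!is.null(group)) {
    if (!group %in% names(data)) stop("group column '", group, "' not found",
                                      call. = FALSE)
    glab <- data[[group]]
    data <- data[setdiff(names(data), group)]
  } else {
    glab <- rep(1L, nrow(data))
  }
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variable(s) not in data: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[vars])
  if (!is.numeric(X)) stop("observed variables must be numeric", call. = FALSE)
  levels_g <- sort(unique(glab))
  groups <- lapply(levels_g, function(lv) {
    Xg <- X[glab == lv, , drop = FALSE]
    Ng <- nrow(Xg)
    if (Ng < 2L) stop("group '", lv, "' has fewer than 2 observations",
                      call. = FALSE)
    xbar <- colMeans(Xg)
    Xc <- sweep(Xg, 2L, xbar)
    S <- crossprod(Xc) / Ng
    list(N = Ng, S = S, xbar = xbar, label = lv)
  })
  structure(list(groups = groups, N = sum(vapply(groups, `[[`, 0, "N")),
                 p = ncol(X), var_names = vars),
            class = "fa_data")
}

#' Build an `fa_data` summary from sufficient statistics
#'
#' @param S a covariance matrix or list of per-group covariance matrices.
#' @param N sample size(s), one per group.
#' @param xbar optional mean vector(s); zero means are assumed when omitted.
#' @param var_names optional variable names (default from `S`).
#' @return An object of class `fa_data`.
#' @export
fa_data_from_stats <- function(S, N, xbar = NULL, var_names = NULL) {
  if (is.matrix(S)) S <- list(S)
  G <- length(S)
  N <- as.numeric(N)
  if (length(N) != G) stop("need one sample size per group", call. = FALSE)
  if (is.null(xbar)) xbar <- lapply(S, function(s) rep(0, ncol(s)))
  if (is.numeric(xbar) && !is.list(xbar)) xbar <- list(xbar)
  p <- ncol(S[[1]])
  for (g in seq_len(G)) {
    Sg <- as.matrix(S[[g]])
    if (nrow(Sg) != p || ncol(Sg) != p) stop("covariance matrices must share ",
                                             "dimensions", call. = FALSE)
    if (max(abs(Sg - t(Sg))) > 1e-8 * max(1, max(abs(Sg))))
      stop("covariance matrix of group ", g, " is not symmetric", call. = FALSE)
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("covariance matrix of group ", g, " is not positive semi-definite",
           call. = FALSE)
    S[[g]] <- (Sg + t(Sg)) / 2
  }
  if (is.null(var_names)) {
    var_names <- colnames(S[[1]])
    if (is.null(var_names)) var_names <- paste0("x", seq_len(p))
  }
  groups <- lapply(seq_len(G), function(g) {
    list(N = N[[g]], S = S[[g]], xbar = as.numeric(xbar[[g]]), label = g)
  })
  structure(list(groups = groups, N = sum(N), p = p, var_names = var_names),
            class = "fa_data")
}

#' Read sufficient statistics from delimited text files
#'
#' Each group is described by a covariance-matrix file (square numeric table,
#' whitespace or comma separated, optional header) plus the sample size;
#' means default to zero.
#'
#' @param cov_files character vector of file paths, one per group.
#' @param N numeric sample sizes, one per group.
#' @param mean_files optional character vector of files holding one mean
#'   vector each.
#' @return An object of class `fa_data`.
#' @export
fa_read_stats <- function(cov_files, N, mean_files = NULL) {
  S <- lapply(cov_files, function(f) {
    as.matrix(utils::read.table(f, header = FALSE, sep = "",
                                comment.char = "#"))
  })
  S <- lapply(S, function(x) { dimnames(x) <- NULL; x })
  xbar <- if (!is.null(mean_files)) {
    lapply(mean_files, function(f) scan(f, quiet = TRUE))
  } else NULL
  fa_data_from_stats(S, N, xbar)
}

#' @export
print.fa_data <- function(x, ...) {
  cat(sprintf("fa_data: %d variable(s), %d group(s), N = %d\n",
              x$p, length(x$groups), as.integer(x$N)))
  invisible(x)
}
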