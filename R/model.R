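#' Specify a factor analysis measurement model
#'
#' Parses a lavaan-style measurement syntax into a model specification that
#' records, for every entry of the loading matrix \eqn{\Lambda}, the unique
#' variances \eqn{\Psi}, the factor covariance matrix \eqn{\Phi}, the
#' intercepts \eqn{\tau} and the factor means \eqn{\kappa}, whether the entry
#' is fixed (and at what value), free, or free-and-penalized.
#'
#' Each line of `model` reads `factor =~ ind1 + ind2 + ...`. A numeric
#' premultiplier fixes a loading (`0.85*x1`); loadings of variables not listed
#' under a factor are fixed to zero. With a single group the factor variances
#' are fixed to one (unit-variance identification) and no mean structure is
#' used unless `meanstructure = TRUE`. With `ngroups > 1` the marker-variable
#' convention applies: the first indicator of each factor (or the one carrying
#' an explicit fixed value) is the marker; its loading is fixed (1 unless a
#' value is given), its loadings on the other factors and its intercept are
#' fixed to zero, and factor variances, covariances and means are free. The
#' same pattern is used in every group.
#'
#' @param model character; measurement syntax (possibly multi-line).
#' @param data_header character vector of observed-variable names used to
#'   validate the syntax, or `NULL` to accept the variables as written.
#' @param ngroups integer, number of groups.
#' @param penalize which free loadings are penalized for sparsity: `"loadings"`
#'   (all free loadings, the default) or `"none"`.
#' @param meanstructure logical; force a mean structure for a single group.
#' @return An object of class `fa_model`; see [fa_model_pack()] for the
#'   parameter ordering.
#' @examples
#' m <- fa_model("f1 =~ x1 + x2 + x3\nf2 =~ x3 + x4 + x5",
#'               data_header = paste0("x", 1:5))
#' m$m  # number of free parameters
#' @export
fa_model <- function(model, data_header = NULL, ngroups = 1L,
                     penalize = c("loadings", "none"),
                     meanstructure = ngroups > 1L) {
  penalize <- match.arg(penalize)
  G <- as.integer(ngroups)
  stopifnot(G >= 1L)
  lines <- unlist(strsplit(model, "[\n;]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty model syntax", call. = FALSE)

  factors <- character(0)
  load_tab <- list()   # per factor: tibble(var, fixed (NA = free), value)
  for (ln_i in seq_along(lines)) {
    ln <- lines[[ln_i]]
    if (!grepl("=~", ln, fixed = TRUE)) {
      stop(sprintf("line %d: expected 'factor =~ indicators': %s", ln_i, ln),
           call. = FALSE)
    }
    parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, "")
    if (length(parts) != 2L) {
      stop(sprintf("line %d: malformed line: %s", ln_i, ln), call. = FALSE)
    }
    fac <- trimws(parts[[1]])
    if (!nzchar(fac)) stop(sprintf("line %d: missing factor name", ln_i),
                           call. = FALSE)
    rhs <- trimws(strsplit(parts[[2]], "+", fixed = TRUE)[[1]])
    rhs <- rhs[nzchar(rhs)]
    if (!length(rhs)) {
      stop(sprintf("line %d: factor '%s' has no indicators", ln_i, fac),
           call. = FALSE)
    }
    vars <- character(length(rhs))
    vals <- rep(NA_real_, length(rhs))
    for (k in seq_along(rhs)) {
      tok <- rhs[[k]]
      if (grepl("*", tok, fixed = TRUE)) {
        bits <- trimws(strsplit(tok, "*", fixed = TRUE)[[1]])
        if (length(bits) != 2L || is.na(suppressWarnings(as.numeric(bits[[1]])))) {
          stop(sprintf("line %d: malformed term '%s'", ln_i, tok), call. = FALSE)
        }
        vals[[k]] <- as.numeric(bits[[1]])
        vars[[k]] <- bits[[2]]
      } else {
        vars[[k]] <- tok
      }
    }
    if (anyDuplicated(vars)) {
      stop(sprintf("line %d: duplicated indicator under factor '%s'", ln_i, fac),
           call. = FALSE)
    }
    if (fac %in% factors) {
      prev <- load_tab[[fac]]
      load_tab[[fac]] <- rbind(prev, data.frame(var = vars, value = vals))
    } else {
      factors <- c(factors, fac)
      load_tab[[fac]] <- data.frame(var = vars, value = vals)
    }
  }

  var_names <- unique(unlist(lapply(load_tab, `[[`, "var")))
  if (!is.null(data_header)) {
    unknown <- setdiff(var_names, data_header)
    if (length(unknown)) {
      stop("unknown observed variable(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    var_names <- intersect(data_header, var_names)
  }
  p <- length(var_names)
  r <- length(factors)
  if (r >= p) stop("model needs fewer factors than observed variables",
                   call. = FALSE)

  # entry status: 0 = fixed, 1 = free
  lambda_status <- matrix(0L, p, r, dimnames = list(var_names, factors))
  lambda_fixed  <- matrix(0, p, r, dimnames = list(var_names, factors))
  for (j in seq_len(r)) {
    tab <- load_tab[[factors[[j]]]]
    for (k in seq_len(nrow(tab))) {
      i <- match(tab$var[[k]], var_names)
      if (is.na(tab$value[[k]])) {
        lambda_status[i, j] <- 1L
      } else {
        lambda_fixed[i, j] <- tab$value[[k]]
      }
    }
  }

  identification <- if (G > 1L) "marker" else "unit-variance"
  markers <- rep(NA_integer_, r)
  tau_status <- rep(1L, p)
  tau_fixed <- rep(0, p)

  if (identification == "marker") {
    for (j in seq_len(r)) {
      tab <- load_tab[[factors[[j]]]]
      fixed_k <- which(!is.na(tab$value) & tab$value != 0)
      mk <- if (length(fixed_k)) fixed_k[[1]] else 1L
      i <- match(tab$var[[mk]], var_names)
      markers[[j]] <- i
      if (is.na(tab$value[[mk]])) {
        lambda_status[i, j] <- 0L
        lambda_fixed[i, j] <- 1
      }
      # marker loads only on its own factor; intercept anchored at zero
      other <- setdiff(seq_len(r), j)
      if (any(lambda_status[i, other] == 1L |
              lambda_fixed[i, other] != 0)) {
        stop(sprintf("marker variable '%s' may only load on factor '%s'",
                     var_names[[i]], factors[[j]]), call. = FALSE)
      }
      tau_status[[i]] <- 0L
    }
    if (anyDuplicated(stats::na.omit(markers))) {
      stop("the same variable is declared as marker for two factors",
           call. = FALSE)
    }
    phi_diag_free <- TRUE
    kappa_free <- TRUE
  } else {
    phi_diag_free <- FALSE   # unit factor variances
    kappa_free <- FALSE
    nz_fixed <- colSums(lambda_status == 0L)
    if (any(nz_fixed < r - 1L)) {
      warning("fewer than r-1 fixed loadings in some column; the model may ",
              "not be identified under factor rotation", call. = FALSE)
    }
  }

  lambda_pen <- lambda_status == 1L & penalize == "loadings"

  meanstructure <- isTRUE(meanstructure) || G > 1L
  obj <- structure(list(
    p = p, r = r, G = G,
    var_names = var_names, factor_names = factors,
    identification = identification,
    meanstructure = meanstructure,
    markers = markers,
    lambda_status = lambda_status,
    lambda_fixed = lambda_fixed,
    lambda_pen = lambda_pen,
    tau_status = tau_status,
    tau_fixed = tau_fixed,
    phi_diag_free = phi_diag_free,
    kappa_free = kappa_free
  ), class = "fa_model")
  obj$map <- fa_param_map(obj)
  # plain-vector view of the map, per group (hot loops avoid tibble access)
  obj$mapg <- lapply(seq_len(G), function(g) {
    mg <- obj$map[obj$map$group == g, ]
    list(id = as.integer(mg$id), mat = as.character(mg$mat),
         row = as.integer(mg$row), col = as.integer(mg$col),
         pen = mg$pen)
  })
  obj$m1 <- sum(obj$map$group == 1L)
  obj$m <- nrow(obj$map)
  obj$qstar <- sum(obj$map$group == 1L & obj$map$pen)
  obj$kstar <- if (meanstructure)
    sum(obj$map$group == 1L & obj$map$mat == "tau") else 0L
  obj
}

# Flat parameter map: group-major; within a group the penalized loadings come
# first (in vec(Lambda) order), then the remaining free loadings, then tau,
# diag(Psi), vech(Phi), kappa.
fa_param_map <- function(obj) {
  p <- obj$p; r <- obj$r
  rows <- list()
  add <- function(mat, row, col, pen, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, row = row, col = col, pen = pen, name = name,
      stringsAsFactors = FALSE)
  }
  # vec(Lambda): column-major, penalized first
  free_idx <- which(obj$lambda_status == 1L)   # column-major order
  pen_idx <- free_idx[obj$lambda_pen[free_idx]]
  oth_idx <- setdiff(free_idx, pen_idx)
  for (ii in c(pen_idx, oth_idx)) {
    i <- (ii - 1L) %% p + 1L
    j <- (ii - 1L) %/% p + 1L
    add("lambda", i, j, ii %in% pen_idx,
        paste0(obj$factor_names[[j]], "=~", obj$var_names[[i]]))
  }
  if (obj$meanstructure) {
    for (i in which(obj$tau_status == 1L)) {
      add("tau", i, 1L, FALSE, paste0(obj$var_names[[i]], "~1"))
    }
  }
  for (i in seq_len(p)) {
    add("psi", i, i, FALSE, paste0(obj$var_names[[i]], "~~", obj$var_names[[i]]))
  }
  for (j in seq_len(r)) {
    for (i in j:r) {
      if (i == j && !obj$phi_diag_free) next
      add("phi", i, j, FALSE,
          paste0(obj$factor_names[[i]], "~~", obj$factor_names[[j]]))
    }
  }
  if (obj$meanstructure && obj$kappa_free) {
    for (j in seq_len(r)) add("kappa", j, 1L, FALSE,
                              paste0(obj$factor_names[[j]], "~1"))
  }
  one <- do.call(rbind, rows)
  map <- do.call(rbind, lapply(seq_len(obj$G), function(g) {
    x <- one; x$group <- g; x
  }))
  map$id <- seq_len(nrow(map))
  map$name <- if (obj$G > 1L) paste0(map$name, ".g", map$group) else map$name
  tibble::as_tibble(map[, c("id", "group", "mat", "row", "col", "pen", "name")])
}

#' Unpack a flat parameter vector into per-group model matrices
#'
#' @param theta numeric vector of length `model$m`.
#' @param model an [fa_model()] specification.
#' @return A list with one element per group, each containing `Lambda` (p x r),
#'   `Psi` (length-p vector of unique variances), `Phi` (r x r), `tau` (length
#'   p) and `kappa` (length r).
#' @export
fa_model_unpack <- function(theta, model) {
  stopifnot(length(theta) == model$m)
  p <- model$p; r <- model$r
  out <- vector("list", model$G)
  for (g in seq_len(model$G)) {
    Lambda <- model$lambda_fixed
    Psi <- rep(0, p)
    Phi <- matrix(0, r, r)
    diag(Phi) <- if (model$phi_diag_free) 0 else 1
    tau <- model$tau_fixed
    kappa <- rep(0, r)
    mg <- model$mapg[[g]]
    th <- theta[mg$id]
    sel <- mg$mat == "lambda"
    Lambda[cbind(mg$row[sel], mg$col[sel])] <- th[sel]
    sel <- mg$mat == "psi"
    Psi[mg$row[sel]] <- th[sel]
    sel <- mg$mat == "phi"
    Phi[cbind(mg$row[sel], mg$col[sel])] <- th[sel]
    Phi[cbind(mg$col[sel], mg$row[sel])] <- th[sel]
    sel <- mg$mat == "tau"
    tau[mg$row[sel]] <- th[sel]
    sel <- mg$mat == "kappa"
    kappa[mg$row[sel]] <- th[sel]
    out[[g]] <- list(Lambda = Lambda, Psi = Psi, Phi = Phi,
                     tau = tau, kappa = kappa)
  }
  out
}

#' Pack per-group model matrices into a flat parameter vector
#'
#' The inverse of [fa_model_unpack()]: entries of the supplied matrices at the
#' free positions are collected in the documented ordering (group-major;
#' within each group penalized loadings, other free loadings, intercepts,
#' unique variances, factor covariances, factor means).
#'
#' @param groups list as returned by [fa_model_unpack()].
#' @param model an [fa_model()] specification.
#' @return numeric vector of length `model$m`.
#' @export
fa_model_pack <- function(groups, model) {
  stopifnot(length(groups) == model$G)
  theta <- numeric(model$m)
  for (g in seq_len(model$G)) {
    mg <- model$mapg[[g]]
    gg <- groups[[g]]
    Psi <- if (is.matrix(gg$Psi)) diag(gg$Psi) else gg$Psi
    for (k in seq_along(mg$id)) {
      i <- mg$row[[k]]; j <- mg$col[[k]]
      theta[mg$id[[k]]] <- switch(mg$mat[[k]],
                                  lambda = gg$Lambda[i, j],
                                  tau = gg$tau[[i]],
                                  psi = Psi[[i]],
                                  phi = gg$Phi[i, j],
                                  kappa = gg$kappa[[i]])
    }
  }
  theta
}

#' Serialize a model specification back to measurement syntax
#'
#' Produces canonical syntax that reparses to the same specification:
#' markers and other fixed nonzero loadings carry explicit premultipliers,
#' fixed-zero loadings are omitted.
#'
#' @param model an [fa_model()] specification.
#' @return A single character string of measurement syntax.
#' @export
fa_model_serialize <- function(model) {
  lines <- character(model$r)
  for (j in seq_len(model$r)) {
    terms <- character(0)
    if (model$identification == "marker") {
      i <- model$markers[[j]]
      terms <- c(terms, paste0(model$lambda_fixed[i, j], "*",
                               model$var_names[[i]]))
    }
    for (i in seq_len(model$p)) {
      if (model$identification == "marker" && i == model$markers[[j]]) next
      if (model$lambda_status[i, j] == 1L) {
        terms <- c(terms, model$var_names[[i]])
      } else if (model$lambda_fixed[i, j] != 0) {
        terms <- c(terms, paste0(model$lambda_fixed[i, j], "*",
                                 model$var_names[[i]]))
      }
    }
    lines[[j]] <- paste(model$factor_names[[j]], "=~",
                        paste(terms, collapse = " + "))
  }
  paste(lines, collapse = "\n")
}

#' @export
print.fa_model <- function(x, ...) {
  cat(sprintf("fa_model: %d variable(s), %d factor(s), %d group(s)\n",
              x$p, x$r, x$G))
  cat(sprintf("  identification: %s%s\n", x$identification,
              if (x$meanstructure) " (mean structure)" else ""))
  cat(sprintf("  free parameters: %d (%d penalized loadings per group)\n",
              x$m, x$qstar))
  invisible(x)
}

#' Starting values for a model
#'
#' Moderate loadings on the declared free positions, unique variances at half
#' of the observed variances, uncorrelated factors (unit variance where free),
#' intercepts at the sample means and zero factor means.
#'
#' @param model an [fa_model()] specification.
#' @param data an [fa_data()] summary.
#' @return numeric vector of length `model$m`.
#' @keywords internal
fa_start <- function(model, data) {
  groups <- vector("list", model$G)
  for (g in seq_len(model$G)) {
    Lambda <- model$lambda_fixed
    Lambda[model$lambda_status == 1L] <- 0.5
    Phi <- diag(model$r)
    Psi <- 0.5 * diag(data$groups[[g]]$S)
    tau <- if (model$meanstructure) {
      tt <- data$groups[[g]]$xbar
      tt[model$tau_status == 0L] <- 0
      tt
    } else rep(0, model$p)
    groups[[g]] <- list(Lambda = Lambda, Psi = Psi, Phi = Phi,
                        tau = tau, kappa = rep(0, model$r))
  }
  fa_model_pack(groups, model)
}
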