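# Direct scalar forms used as an independent oracle for the smooth
# approximations: the exact (non-differentiable) penalties.
exact_pen <- function(t, type, eta, a = NA, w = 1) {
  u <- abs(t)
  switch(type,
         lasso = eta * u,
         alasso = eta * w * u,
         scad = if (u <= eta) eta * u
                else if (u <= a * eta)
                  -(u^2 - 2 * a * eta * u + eta^2) / (2 * (a - 1))
                else (a + 1) * eta^2 / 2,
         mcp = if (u <= a * eta) eta * u - u^2 / (2 * a) else a * eta^2 / 2)
}

test_that("penalty configuration validates shape and tuning parameters", {
  expect_error(penalty_config("scad", a = 2), "a > 2")
  expect_error(penalty_config("mcp", a = 1), "a > 1")
  expect_error(penalty_config("alasso", a = -1), "a > 0")
  expect_error(penalty_config("lasso", eta = -0.1), "nonnegative")
  expect_error(penalty_config("lasso", c_bar = 0), "positive")
  expect_error(penalty_config("lasso", gamma = 0.5), "gamma")
  expect_error(penalty_config("scad", a = 3.7, eta = "auto"), "grid")
  expect_s3_class(penalty_config("scad", a = 3.7, eta = 0.1), "fa_penalty")
})

test_that("penalty value matches hand values and the approximation floor", {
  m <- toy_model(3)   # q* = 3 penalized loadings
  mk_theta <- function(lam) {
    fa_model_pack(list(list(Lambda = matrix(lam), Psi = rep(1, 3),
                            Phi = matrix(1), tau = rep(0, 3), kappa = 0)), m)
  }
  pen <- penalty_config("lasso", eta = 0.1)
  th <- mk_theta(c(0.3, 0, 0))
  # single active coordinate at 0.3 contributes eta * |0.3|, the two zeros
  # the sqrt(c_bar) floor each
  expect_equal(penalty_value(th, m, pen),
               0.1 * 0.3 + 2 * 0.1 * sqrt(1e-8), tolerance = 1e-6)
  th0 <- mk_theta(c(0, 0, 0))
  expect_equal(penalty_value(th0, m, pen), 0.1 * 3 * sqrt(1e-8),
               tolerance = 1e-12)
})

test_that("smooth approximation converges to the exact penalty as c_bar -> 0,
           with deviation sqrt(c_bar) at zero and < c_bar elsewhere", {
  m <- toy_model(2)
  mk <- function(lam) fa_model_pack(list(list(Lambda = matrix(lam),
                                              Psi = rep(1, 2),
                                              Phi = matrix(1), tau = rep(0, 2),
                                              kappa = 0)), m)
  for (type in c("lasso", "scad", "mcp")) {
    a <- switch(type, scad = 3.7, mcp = 3, NA)
    for (cb in c(1e-6, 1e-8, 1e-10)) {
      pen <- penalty_config(type, eta = 0.2, a = a, c_bar = cb)
      # at zero the deviation per coordinate is eta-scaled sqrt(c_bar)
      v0 <- penalty_value(mk(c(0, 0)), m, pen)
      expect_lt(v0, 2 * 0.2 * sqrt(cb) * (1 + 1e-6))
      # away from zero: closer than c_bar per coordinate
      v <- penalty_value(mk(c(0.5, -0.4)), m, pen)
      ve <- exact_pen(0.5, type, 0.2, a) + exact_pen(0.4, type, 0.2, a)
      expect_lt(abs(v - ve), 2 * cb + 1e-12)
    }
  }
})

test_that("shrink weights reproduce hand values for all penalty types", {
  expect_equal(shrink_weight(0.5, "lasso", eta = 0.1), 0.2, tolerance = 1e-6)
  expect_equal(shrink_weight(0.4, "alasso", eta = 0.2, a = 1, w = 1 / 0.8),
               0.625, tolerance = 1e-6)
  expect_equal(shrink_weight(0.9, "mcp", eta = 0.2, a = 3), 0,
               tolerance = 1e-12)
  expect_equal(shrink_weight(0.05, "scad", eta = 0.1, a = 3.7), 2.0,
               tolerance = 1e-3)
  expect_error(shrink_weight(0.5, "lasso", eta = -1), "nonnegative")
})

test_that("shrink weights equal the numeric derivative of the smooth penalty
           and vanish for large arguments (except lasso)", {
  cb <- 1e-8
  for (type in c("lasso", "alasso", "scad", "mcp")) {
    a <- switch(type, alasso = 2, scad = 3.7, mcp = 3, NA)
    w <- if (type == "alasso") 1.7 else 1
    for (tt in c(0.03, 0.1, 0.37, 0.9, 2.5)) {
      sm <- function(t) {
        u <- sqrt(t^2 + cb)
        sparsefa:::pen_fun(u, type, 0.15, a, w)
      }
      mq <- shrink_weight(tt, type, 0.15, a, w, cb)
      d_num <- (sm(tt + 1e-6) - sm(tt - 1e-6)) / 2e-6
      expect_equal(mq * tt, d_num, tolerance = 1e-5,
                   info = paste(type, tt))
      expect_gte(mq, 0)
    }
    w_inf <- if (type == "alasso") 1 / 1e4^a else w
    mq_inf <- shrink_weight(1e4, type, 0.15, a, w_inf, cb)
    if (type == "lasso") {
      expect_equal(mq_inf * 1e4, 0.15, tolerance = 1e-8)  # m |t| -> eta
    } else {
      expect_lt(mq_inf * 1e4, 1e-6)                        # de-biasing
    }
  }
})

test_that("scad penalty is continuous at its breakpoints", {
  eta <- 0.2; a <- 3.7; eps <- 1e-9
  for (b in c(eta, a * eta)) {
    lo <- exact_pen(b - eps, "scad", eta, a)
    hi <- exact_pen(b + eps, "scad", eta, a)
    expect_equal(lo, hi, tolerance = 1e-7)
  }
})

test_that("selector matrices compute pairwise cross-group differences", {
  m2 <- sim_population("sim2-null")$model
  sel <- build_selectors(m2)
  # R_q: single unit diagonal entry per penalized loading
  q1 <- m2$map$id[m2$map$pen][1]
  Rq <- sel$R[[as.character(q1)]]
  expect_equal(sum(Rq), 1)
  expect_equal(Rq[q1, q1], 1)
  # G = 2: |D_q theta|_1 is the absolute loading difference
  th <- numeric(m2$m)
  th[q1] <- 0.5; th[m2$m1 + q1] <- 0.3
  D <- sel$D_lambda[[1]]
  expect_equal(sum(abs(D %*% th)), 0.2)
  # invariant theta: all differences vanish
  th2 <- rep(random_theta(m2)[seq_len(m2$m1)], 2)
  for (D in sel$D_lambda) expect_equal(max(abs(D %*% th2)), 0)
  # G = 3: choose(3, 2) = 3 pairwise rows per parameter
  m3 <- fa_model("f1 =~ 1*x1 + x2 + x3\nf2 =~ 1*x4 + x5 + x6",
                 data_header = paste0("x", 1:6), ngroups = 3)
  sel3 <- build_selectors(m3)
  expect_equal(nrow(sel3$D_lambda[[1]]), 3)
})

test_that("penalty matrix is zero without tuning, diagonal for single-group
           lasso, and reproduces the fused quadratic form for two groups", {
  pop <- sim_population("sim1")
  m <- pop$model
  set.seed(3)
  th <- random_theta(m)
  pen0 <- penalty_config("lasso", eta = 0)
  expect_equal(build_penalty_matrix(th, m, pen0), matrix(0, m$m, m$m))

  pen <- penalty_config("lasso", eta = 0.3)
  E <- build_penalty_matrix(th, m, pen)
  expect_equal(E, diag(diag(E)))   # diagonal
  pid <- m$map$id[m$map$pen]
  expect_equal(diag(E)[pid], 0.3 / sqrt(th[pid]^2 + 1e-8))
  expect_equal(sum(abs(diag(E)[-pid])), 0)  # unpenalized rows exactly zero

  # two-group fusion: 0.5 theta' E2 theta equals the local quadratic value of
  # the difference penalty at the expansion point
  m2 <- sim_population("sim2-null")$model
  th2 <- random_theta(m2)
  pen2 <- penalty_config("lasso", fuse_loadings = "lasso",
                         fuse_intercepts = "none",
                         eta = c(sparsity = 0, fuse_loadings = 0.2,
                                 fuse_intercepts = 0))
  E2 <- build_penalty_matrix(th2, m2, pen2)
  lam_pos <- which(m2$map$group == 1L & m2$map$pen)
  d <- th2[lam_pos] - th2[m2$m1 + lam_pos]
  u <- sqrt(d^2 + 1e-8)
  expect_equal(0.5 * sum(th2 * (E2 %*% th2)),
               0.5 * sum((0.2 / u) * d^2), tolerance = 1e-10)
})

test_that("N E(theta) theta equals the gradient of the approximated penalty", {
  set.seed(9)
  cases <- list(
    list(sim_population("sim1")$model, penalty_config("scad", a = 3.7,
                                                      eta = 0.15)),
    list(sim_population("sim1")$model, penalty_config("mcp", a = 3,
                                                      eta = 0.2)),
    list(sim_population("sim2-null")$model,
         penalty_config("lasso", eta = c(sparsity = 0.1,
                                         fuse_loadings = 0.25,
                                         fuse_intercepts = 0.15)))
  )
  for (cs in cases) {
    m <- cs[[1]]; pen <- cs[[2]]
    th <- random_theta(m)
    E <- build_penalty_matrix(th, m, pen)
    g_pen <- as.numeric(E %*% th)
    g_num <- fd_grad(function(x) penalty_value(x, m, pen), th, h = 1e-7)
    expect_equal(g_pen, g_num, tolerance = 1e-5)
  }
})
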