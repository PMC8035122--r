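test_that("edf equals m at eta = 0, tends to m - r* as eta grows, and
           per-parameter edf stay in [0, 1]", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 500, seed = 14))
  mle <- fa_fit_mle(ds, pop$model)
  m <- pop$model$m

  expect_equal(mle$edf, m, tolerance = 1e-8)
  expect_equal(max(abs(mle$edf_per - 1)), 0, tolerance = 1e-8)
  expect_equal(max(abs(mle$influence - diag(m))), 0, tolerance = 1e-6)

  for (type in c("lasso", "alasso", "scad", "mcp")) {
    a <- switch(type, alasso = 2, scad = 3.7, mcp = 3, NA)
    pen <- penalty_config(type, a = a, eta = 1e8)
    w <- sparsefa:::alasso_weights(mle$theta, pop$model, pen)
    terms <- sparsefa:::pen_terms(pop$model, pen, w)
    ed <- sparsefa:::influence_edf_core(mle$theta, pop$model, ds, terms,
                                        c(sparsity = 1e8), 1e-8)
    rstar <- pop$model$qstar
    expect_equal(ed$edf_total, m - rstar, tolerance = 0.01,
                 info = type)
    expect_true(all(ed$edf_per >= 0 & ed$edf_per <= 1))
    # unpenalized parameters keep a full degree of freedom
    expect_equal(ed$edf_per[-pop$pen_ids], rep(1, m - rstar),
                 tolerance = 1e-6)
  }

  # multi-group limit: r* = G (q* + k*)
  pop2 <- sim_population("sim2-null")
  ds2 <- fa_data(sim_generate(pop2, 400, seed = 15), vars = pop2$var_names,
                 group = "group")
  mle2 <- fa_fit_mle(ds2, pop2$model)
  pen2 <- penalty_config("lasso", eta = 1e8)
  terms2 <- sparsefa:::pen_terms(pop2$model, pen2, NULL)
  ed2 <- sparsefa:::influence_edf_core(mle2$theta, pop2$model, ds2, terms2,
                                       c(sparsity = 1e8, fuse_loadings = 1e8,
                                         fuse_intercepts = 1e8), 1e-8)
  # limiting complexity reduction: all G q* penalized loadings are pinned at
  # zero, while each intercept difference penalty removes G - 1 of the G
  # intercept copies (the fused common value stays a free parameter)
  G <- pop2$model$G
  rstar2 <- G * pop2$model$qstar + (G - 1) * pop2$model$kstar
  expect_equal(ed2$edf_total, pop2$model$m - rstar2, tolerance = 0.01)
})

test_that("influence-matrix trace and F_p^{-1}F trace agree", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 300, seed = 16))
  mle <- fa_fit_mle(ds, pop$model)
  pen <- sim1_alasso()
  w <- sparsefa:::alasso_weights(mle$theta, pop$model, pen)
  terms <- sparsefa:::pen_terms(pop$model, pen, w)
  for (eta in c(0.001, 0.05, 1)) {
    ed <- sparsefa:::influence_edf_core(mle$theta, pop$model, ds, terms,
                                        c(sparsity = eta), 1e-8)
    expect_equal(sum(diag(ed$A)), sum(ed$Fp_inv * ed$Fisher),
                 tolerance = 1e-8)
  }
})

test_that("GBIC reduces to the ordinary BIC at eta = 0 and is a pure
           bookkeeping identity otherwise", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 250, seed = 17))
  mle <- fa_fit_mle(ds, pop$model)
  expect_equal(mle$gbic, -2 * mle$loglik + pop$model$m * log(ds$N))
  expect_equal(gbic(mle$loglik, mle$edf, ds$N),
               -2 * mle$loglik + log(ds$N) * mle$edf)
  # AIC-flavoured variant
  expect_equal(gbic(mle$loglik, mle$edf, ds$N, k = 2),
               -2 * mle$loglik + 2 * mle$edf)
  # restricted limit: BIC with m - r* parameters
  expect_equal(gbic(mle$loglik, pop$model$m - pop$model$qstar, ds$N),
               -2 * mle$loglik + (33 - 21) * log(ds$N))
})

test_that("tuning criterion: value at eta = 0, influence-factor identity and
           smoothness in log eta", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 350, seed = 18))
  mle <- fa_fit_mle(ds, pop$model)
  pen <- sim1_alasso()
  w <- sparsefa:::alasso_weights(mle$theta, pop$model, pen)
  m <- pop$model$m

  # eta = 0: A = I so the residual term vanishes and V = 2 gamma m / N - 1
  for (gam in c(1, 4.5)) {
    pg <- pen; pg$gamma <- gam
    v0 <- ubre(mle$theta, pop$model, ds, pg, c(sparsity = 0), weights = w)
    expect_equal(v0, 2 * gam * m / ds$N - 1, tolerance = 1e-6)
  }

  # V_gamma - V_1 = 2 (gamma - 1) tr(A) / N at any eta
  terms <- sparsefa:::pen_terms(pop$model, pen, w)
  for (eta in c(0.001, 0.02, 0.5)) {
    ed <- sparsefa:::influence_edf_core(mle$theta, pop$model, ds, terms,
                                        c(sparsity = eta), 1e-8)
    p1 <- pen; p1$gamma <- 1
    p45 <- pen; p45$gamma <- 4.5
    dv <- ubre(mle$theta, pop$model, ds, p45, c(sparsity = eta), w) -
      ubre(mle$theta, pop$model, ds, p1, c(sparsity = eta), w)
    expect_equal(dv, 2 * 3.5 * ed$edf_total / ds$N, tolerance = 1e-8)
  }

  # V is smooth in log eta: central differences are stable across step sizes
  st <- sparsefa:::ubre_state(mle$theta, pop$model, ds)
  Vr <- function(r) sparsefa:::ubre_value(exp(r), st, terms, 1e-8, 4.5,
                                          mle$theta)
  r0 <- log(0.01)
  d1 <- (Vr(r0 + 1e-3) - Vr(r0 - 1e-3)) / 2e-3
  d2 <- (Vr(r0 + 1e-4) - Vr(r0 - 1e-4)) / 2e-4
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("the automatic-procedure stopping rule fires exactly when the
           printed inequality holds", {
  ll <- c(-1000, -900, -899.99, -899.9899999, -899.98999995)
  for (i in 2:length(ll)) {
    expect_equal(auto_tune_stop(ll[i], ll[i - 1]),
                 abs(ll[i] - ll[i - 1]) / (0.1 + abs(ll[i])) < 1e-7)
  }
  expect_false(auto_tune_stop(-900, -1000))
  expect_true(auto_tune_stop(-900, -900 - 1e-6))
})

test_that("automatic tuning on a sparse-population replicate recovers the
           exact zero pattern, and a dense population keeps edf near m", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 1000, seed = 22))
  fit <- fa_auto_tune(ds, pop$model, sim1_alasso())
  al <- align_signs(fit$theta, pop)
  expect_true(all(classify_zero(al[pop$zero_ids])))
  expect_true(all(!classify_zero(al[pop$nonzero_ids])))
  expect_error(fa_auto_tune(ds, pop$model,
                            penalty_config("scad", a = 3.7, eta = 0.1)),
               "lasso")

  # dense model: every penalized loading truly nonzero
  vn <- paste0("x", 1:6)
  mdl <- fa_model("f1 =~ x1 + x2 + x3 + x5 + x6\nf2 =~ x2 + x4 + x5 + x6",
                  data_header = vn)
  Lambda <- matrix(0, 6, 2)
  Lambda[c(1, 2, 3, 5, 6), 1] <- c(0.8, 0.7, 0.6, 0.4, 0.5)
  Lambda[c(2, 4, 5, 6), 2] <- c(0.35, 0.8, 0.55, 0.4)
  Phi <- matrix(c(1, 0.3, 0.3, 1), 2)
  Psi <- pmax(1 - diag(Lambda %*% Phi %*% t(Lambda)), 0.2)
  set.seed(23)
  X <- MASS::mvrnorm(1000, rep(0, 6), Lambda %*% Phi %*% t(Lambda) + diag(Psi))
  colnames(X) <- vn
  dfit <- fa_auto_tune(fa_data(as.data.frame(X)), mdl,
                       penalty_config("alasso", a = 2, gamma = 1))
  expect_lt(max(dfit$eta), 0.05)
  expect_gt(dfit$edf, mdl$m - 1)
})

test_that("grid search brackets the unpenalized and fully-restricted fits and
           its path edf decrease with the tuning parameter", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 400, seed = 24))
  mle <- fa_fit_mle(ds, pop$model)
  pen <- penalty_config("lasso", eta = 1)

  g2 <- fa_grid(ds, pop$model, pen, eta_grid = c(0, 5), mle = mle)
  expect_equal(g2$gbic, min(g2$path$gbic))
  expect_equal(min(g2$path$gbic[g2$path$eta == "0"]), mle$gbic,
               tolerance = 1e-6)

  grid <- c(0.001, 0.005, 0.02, 0.05, 0.1, 0.3)
  gp <- fa_grid(ds, pop$model, pen, eta_grid = grid, mle = mle)
  edf_path <- gp$path$edf
  expect_true(all(diff(edf_path) <= 1e-6))
})

test_that("grid search and automatic tuning classify a seeded replicate
           identically", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 1000, seed = 25))
  mle <- fa_fit_mle(ds, pop$model)
  auto <- fa_auto_tune(ds, pop$model, sim1_alasso(), mle = mle)
  grid <- fa_grid(ds, pop$model, sim1_alasso(),
                  eta_grid = 10^seq(-4, 0, length.out = 40), mle = mle)
  za <- classify_zero(align_signs(auto$theta, pop)[pop$pen_ids])
  zg <- classify_zero(align_signs(grid$theta, pop)[pop$pen_ids])
  expect_equal(za, zg)
})

test_that("posterior covariance is the ML covariance at eta = 0, intervals
           shrink like 1/sqrt(N), and coverage is near nominal", {
  pop <- sim_population("sim1")
  ds <- fa_data(sim_generate(pop, 400, seed = 26))
  mle <- fa_fit_mle(ds, pop$model)
  post <- posterior_uncertainty(mle)
  Fi <- fa_information(mle$theta, pop$model, ds)
  expect_equal(post$Vtheta, solve(Fi), tolerance = 1e-6)
  # sandwich collapses to the same matrix at eta = 0
  post_s <- posterior_uncertainty(mle, type = "sandwich")
  expect_equal(post_s$Vtheta, post$Vtheta, tolerance = 1e-6)

  widths <- vapply(c(300, 1000), function(N) {
    dsn <- fa_data(sim_generate(pop, N, seed = 27))
    fit <- fa_auto_tune(dsn, pop$model, sim1_alasso())
    p <- posterior_uncertainty(fit)
    mean(p$intervals$conf.high - p$intervals$conf.low)
  }, numeric(1))
  expect_equal(widths[1] / widths[2], sqrt(1000 / 300), tolerance = 0.25)

  # stochastic spot check of coverage across replicates
  set.seed(28)
  L <- 25
  hits <- 0; tot <- 0
  for (l in 1:L) {
    dsl <- fa_data(sim_generate(pop, 500, seed = 28000 + l))
    fit <- fa_auto_tune(dsl, pop$model, sim1_alasso())
    al <- align_signs(fit$theta, pop)
    p <- posterior_uncertainty(fit)
    half <- 1.96 * sqrt(pmax(diag(p$Vtheta), 0))
    hits <- hits + sum(abs(al - pop$theta0) <= half)
    tot <- tot + pop$model$m
  }
  expect_gt(hits / tot, 0.85)
  expect_lt(hits / tot, 0.995)
})
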