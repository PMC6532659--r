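make_gaussian_data <- function(n = 40, m = 3, sigma_g = 1, sigma_e = 1,
                               slope = FALSE) {
  cl <- rep(sprintf("c%02d", seq_len(n)), each = m)
  N <- n * m
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(N), x2 = rnorm(N))
  tvec <- rep(seq_len(m), n)
  re <- rep(rnorm(n, 0, sqrt(sigma_g)), each = m)
  if (slope) re <- re + tvec * rep(rnorm(n, 0, sqrt(sigma_g)), each = m)
  y <- drop(X %*% c(1, 0.5, -0.3)) + re + rnorm(N, 0, sqrt(sigma_e))
  list(y = y, X = X, cluster = cl, time = tvec)
}

test_that("Gaussian fit collapses to OLS when the random effect is absent", {
  set.seed(11)
  d <- make_gaussian_data(n = 80, sigma_g = 0)
  fit <- glmm_null_fit(d$y, d$X, d$cluster)
  ols <- lm.fit(d$X, d$y)$coefficients
  expect_lt(fit$var_comp["sigma_g_sq"], 0.05)
  expect_equal(unname(fit$alpha), unname(ols), tolerance = 0.02)
})

test_that("Gaussian identity path is algebraically exact", {
  set.seed(12)
  d <- make_gaussian_data()
  fit <- glmm_null_fit(d$y, d$X, d$cluster)
  expect_identical(fit$y_star, d$y)
  expect_equal(fit$delta, rep(1, fit$N))
  expect_equal(fit$w_diag, rep(unname(fit$var_comp["sigma_e_sq"]), fit$N))
})

test_that("REML estimates match lme4 for intercept and slope models", {
  skip_if_not_installed("lme4")
  set.seed(13)
  d <- make_gaussian_data(n = 60)
  fit <- glmm_null_fit(d$y, d$X, d$cluster)
  df <- data.frame(y = d$y, x1 = d$X[, 2], x2 = d$X[, 3], cl = d$cluster,
                   tv = d$time)
  lf <- lme4::lmer(y ~ x1 + x2 + (1 | cl), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(unname(fit$alpha), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$var_comp[c("sigma_g_sq", "sigma_e_sq")]), vc,
               tolerance = 1e-4)
  expect_equal(fit$gamma,
               rep(lme4::ranef(lf)[[1]][, 1], each = 3), tolerance = 1e-5,
               ignore_attr = TRUE)

  d2 <- make_gaussian_data(n = 60, slope = TRUE)
  fit2 <- glmm_null_fit(d2$y, d2$X, d2$cluster, time = d2$time,
                        random = "slope")
  df2 <- data.frame(y = d2$y, x1 = d2$X[, 2], x2 = d2$X[, 3],
                    cl = d2$cluster, tv = d2$time)
  lf2 <- lme4::lmer(y ~ x1 + x2 + (1 | cl) + (0 + tv | cl), data = df2,
                    REML = TRUE)
  vc2 <- as.data.frame(lme4::VarCorr(lf2))$vcov
  expect_equal(unname(fit2$alpha), unname(lme4::fixef(lf2)), tolerance = 1e-4)
  expect_equal(unname(fit2$var_comp[1:3]), vc2, tolerance = 1e-3)
})

test_that("PQL fixed effects match the dense-matrix PQL oracle", {
  set.seed(14)
  for (family in c("binomial", "poisson")) {
    n <- 30
    m <- 3
    cl <- rep(seq_len(n), each = m)
    N <- n * m
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(N))
    eta <- drop(X %*% c(-0.2, 0.6)) + rep(rnorm(n, 0, 0.8), each = m)
    y <- if (family == "binomial") rbinom(N, 1, plogis(eta)) else rpois(N, exp(eta))
    if (family == "binomial" && length(unique(y)) < 2) next
    fit <- glmm_null_fit(y, X, cl, family = family)
    orc <- oracle_pql(y, X, cl, family)
    expect_equal(unname(fit$alpha), unname(orc$alpha), tolerance = 1e-4)
    expect_equal(unname(fit$var_comp["sigma_g_sq"]), unname(orc$g[1]),
                 tolerance = 1e-3)
  }
})

test_that("fitted ICC recovers the design values within Monte-Carlo error", {
  set.seed(15)
  reps <- 12
  for (sg in c(0.5, 1, 1.5)) {
    target <- sg / (sg + 1)
    iccs <- replicate(reps, {
      d <- make_gaussian_data(n = 150, sigma_g = sg)
      f <- glmm_null_fit(d$y, d$X, d$cluster)
      unname(f$var_comp["sigma_g_sq"] /
               (f$var_comp["sigma_g_sq"] + f$var_comp["sigma_e_sq"]))
    })
    expect_lt(abs(mean(iccs) - target), 3 * sd(iccs) / sqrt(reps) + 1e-6)
  }
})

test_that("marginal covariance blocks follow S G S' + W", {
  set.seed(16)
  d <- make_gaussian_data(n = 10, m = 2)
  fit <- glmm_null_fit(d$y, d$X, d$cluster)
  sg <- unname(fit$var_comp["sigma_g_sq"])
  se <- unname(fit$var_comp["sigma_e_sq"])
  mc <- marginal_covariance(fit)
  expect_equal(mc$V_blocks[[1]],
               matrix(sg, 2, 2) + diag(se, 2), tolerance = 1e-10)
  for (b in seq_along(mc$V_blocks)) {
    expect_equal(mc$V_blocks[[b]] %*% mc$Vinv_blocks[[b]], diag(2),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # slope design: S = [[1,1],[1,2]], G = I  =>  Sigma = [[2,3],[3,5]]
  S <- cbind(1, 1:2)
  expect_equal(S %*% diag(2) %*% t(S), matrix(c(2, 3, 3, 5), 2, 2))
  d2 <- make_gaussian_data(n = 12, m = 2, slope = TRUE)
  fit2 <- glmm_null_fit(d2$y, d2$X, d2$cluster, time = d2$time, random = "slope")
  g <- unname(fit2$var_comp[1:2])
  expect_equal(fit2$sigma_blocks[[1]],
               cbind(1, 1:2) %*% diag(g) %*% t(cbind(1, 1:2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # cross-cluster entries of the assembled Vinv are exactly zero
  Vinv <- as.matrix(marginal_covariance(fit2)$Vinv)
  expect_identical(Vinv[1, 3], 0)
  expect_identical(Vinv[2, 4], 0)
})

test_that("working residual agrees with a dense-matrix solve", {
  set.seed(17)
  d <- make_gaussian_data(n = 8, m = 3)
  fit <- glmm_null_fit(d$y, d$X, d$cluster)
  V <- as.matrix(marginal_covariance(fit)$V)
  r_dense <- solve(V, d$y - drop(d$X %*% fit$alpha))
  expect_equal(working_residual(fit), as.numeric(r_dense), tolerance = 1e-10)
  expect_equal(working_residual(fit, recompute = TRUE), as.numeric(r_dense),
               tolerance = 1e-10)
  # y* = X alpha exactly -> r = 0
  fit0 <- fit
  fit0$y_star <- drop(d$X %*% fit$alpha)
  expect_equal(working_residual(fit0, recompute = TRUE), rep(0, fit$N))
})

test_that("degenerate or malformed inputs raise informative errors", {
  set.seed(18)
  d <- make_gaussian_data(n = 6)
  expect_error(glmm_null_fit(rep(1, 18), d$X, d$cluster, family = "binomial"),
               "degenerate")
  Xbad <- cbind(d$X, dup = d$X[, 2])
  expect_error(glmm_null_fit(d$y, Xbad, d$cluster), "rank")
  expect_error(glmm_null_fit(d$y, d$X, rep(1, 18)), "at least 2 clusters")
  expect_error(glmm_null_fit(d$y, d$X, d$cluster, random = "slope"),
               "time points")
  shuffled <- sample(d$cluster)
  expect_error(glmm_null_fit(d$y, d$X, shuffled), "contiguous")
})

test_that("identity working-variance option changes only the score-stage W", {
  set.seed(19)
  n <- 25
  m <- 3
  cl <- rep(seq_len(n), each = m)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n * m))
  y <- rbinom(n * m, 1, plogis(0.3 * X[, 2] + rep(rnorm(n, 0, 1), each = m)))
  f1 <- glmm_null_fit(y, X, cl, family = "binomial", w_matrix = "working")
  f2 <- glmm_null_fit(y, X, cl, family = "binomial", w_matrix = "identity")
  expect_equal(f1$alpha, f2$alpha)
  expect_equal(f2$w_diag, rep(1, length(y)))
  expect_false(isTRUE(all.equal(f1$r, f2$r)))
  V2 <- as.matrix(marginal_covariance(f2)$V)
  expect_equal(f2$r, as.numeric(solve(V2, f2$y_star - drop(X %*% f2$alpha))),
               tolerance = 1e-8)
})
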