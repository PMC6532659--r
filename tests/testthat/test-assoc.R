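test_that("score statistic equals the brute-force double sum", {
  set.seed(51)
  for (i in 1:200) {
    N <- sample(2:8, 1)
    r <- rnorm(N)
    A <- matrix(rnorm(N * N), N, N)
    K <- crossprod(A)
    q <- score_statistic(r, K)
    brute <- 0
    for (a in 1:N) for (b in 1:N) brute <- brute + r[a] * K[a, b] * r[b]
    expect_equal(q, brute, tolerance = 1e-10)
    expect_gte(q, -1e-12)
  }
  expect_equal(score_statistic(rep(0, 4), diag(4)), 0)
  r <- rnorm(5)
  expect_equal(score_statistic(r, diag(5)), sum(r^2))
  expect_error(score_statistic(rnorm(3), diag(4)), "dimension")
})

test_that("permutation p-value estimator counts ties and never hits zero", {
  expect_equal(kernel_pvalue(10, rep(1, 999)), 1 / 1000)
  expect_equal(kernel_pvalue(5, rep(5, 99)), 1)
  q <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  expect_equal(kernel_pvalue(5, q), 6 / 10)
  expect_error(kernel_pvalue(1, numeric(0)), "at least one")
})

sim_fit <- function(seed = 1, n = 10, p = 40, family = "gaussian",
                    sigma_sq = 1, beta = 0, random = "intercept") {
  set.seed(seed)
  comm <- fixture_community(p = p)
  dat <- simulate_study(n = n, family = family, random = random,
                        sigma_sq = sigma_sq, beta = beta,
                        scenario = if (beta != 0) "P2" else NULL,
                        community = comm, n_assoc = min(20, p %/% 2))
  X <- cbind(`(Intercept)` = 1, x1 = dat$meta$x1, x2 = dat$meta$x2)
  fit <- glmm_null_fit(dat$meta$y, X, dat$meta$cluster,
                       time = if (random == "slope") dat$meta$time else NULL,
                       family = family, random = random)
  list(dat = dat, fit = fit)
}

test_that("test results are bit-identical under a fixed seed", {
  sf <- sim_fit(seed = 52)
  Ks <- lapply(ecological_distances(sf$dat$counts, sf$dat$tree), distance_kernel)
  r1 <- kat_test_kernels(sf$fit, Ks, B = 29, seed = 99)
  r2 <- kat_test_kernels(sf$fit, Ks, B = 29, seed = 99)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$omnibus_p, r2$omnibus_p)
})

test_that("zero kernel gives Q = 0 and p = 1", {
  sf <- sim_fit(seed = 53)
  K0 <- matrix(0, sf$fit$N, sf$fit$N)
  res <- kat_test_kernels(sf$fit, list(zero = K0), B = 49, seed = 1)
  expect_equal(res$results$statistic, 0)
  expect_equal(res$results$p.value, 1)
})

test_that("duplicated kernels add no multiplicity penalty to the omnibus", {
  sf <- sim_fit(seed = 54)
  K <- distance_kernel(dist_bray_curtis(sf$dat$counts))
  single <- kat_test_kernels(sf$fit, list(bc = K), B = 199, seed = 11)
  doubled <- kat_test_kernels(sf$fit, list(bc = K, bc2 = K), B = 199, seed = 11)
  expect_equal(doubled$results$p.value[1], doubled$results$p.value[2])
  expect_equal(doubled$omnibus_p, single$omnibus_p, tolerance = 2 / 200)
  # single-kernel omnibus p equals the kernel's p up to estimator granularity
  expect_equal(single$omnibus_p, single$results$p.value, tolerance = 2 / 200)
})

test_that("Q is invariant to consistent relabeling of clusters and OTUs", {
  sf <- sim_fit(seed = 55)
  dat <- sf$dat
  K <- distance_kernel(dist_bray_curtis(dat$counts))
  q1 <- score_statistic(sf$fit$r, K)
  # permute OTU columns (distance unchanged) and relabel clusters en bloc
  perm_otu <- sample(ncol(dat$counts))
  counts2 <- dat$counts[, perm_otu]
  K2 <- distance_kernel(dist_bray_curtis(counts2))
  expect_equal(score_statistic(sf$fit$r, K2), q1, tolerance = 1e-10)
  # reorder whole clusters: refit on the reordered rows
  ci <- glmmkat:::cluster_index(dat$meta$cluster)
  blocks <- split(seq_len(nrow(dat$counts)), ci$index)
  new_order <- unlist(blocks[sample(length(blocks))], use.names = FALSE)
  X <- cbind(`(Intercept)` = 1, x1 = dat$meta$x1, x2 = dat$meta$x2)
  fit2 <- glmm_null_fit(dat$meta$y[new_order], X[new_order, , drop = FALSE],
                        dat$meta$cluster[new_order])
  K3 <- distance_kernel(dist_bray_curtis(dat$counts[new_order, ]))
  expect_equal(score_statistic(fit2$r, K3), q1, tolerance = 1e-6)
})

test_that("per-kernel p-values are uniform under the Gaussian null", {
  set.seed(56)
  comm <- fixture_community(p = 40)
  pvals <- replicate(120, {
    dat <- simulate_study(n = 12, sigma_sq = 1, community = comm,
                          n_assoc = 20)
    K <- distance_kernel(dist_bray_curtis(dat$counts))
    X <- cbind(`(Intercept)` = 1, x1 = dat$meta$x1, x2 = dat$meta$x2)
    fit <- glmm_null_fit(dat$meta$y, X, dat$meta$cluster)
    kat_test_kernels(fit, list(bc = K), B = 99)$results$p.value
  })
  # permutation p-values are discrete, so the KS test warns about ties
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("the data-frame interface and the naive mode run end to end", {
  set.seed(57)
  comm <- fixture_community(p = 40)
  dat <- simulate_study(n = 10, community = comm, n_assoc = 20)
  res <- kat_test(dat$meta, dat$counts, dat$tree, trait = y,
                  covariates = c(x1, x2), cluster = cluster, B = 49, seed = 3)
  expect_s3_class(res, "glmmkat_test")
  expect_equal(nrow(res$results), 5)
  expect_true(all(res$results$p.value > 0 & res$results$p.value <= 1))
  expect_gte(res$omnibus_p, 1 / 50)
  expect_equal(res$omnibus_stat, min(res$results$p.value))
  # string-based column selection (CLI path)
  res2 <- kat_test(dat$meta, dat$counts, dat$tree, trait = "y",
                   covariates = dplyr::all_of(c("x1", "x2")),
                   cluster = "cluster", kernels = "bray_curtis", B = 49,
                   seed = 3)
  expect_equal(nrow(res2$results), 1)
  nv <- kat_test(dat$meta, dat$counts, trait = y, covariates = c(x1, x2),
                 cluster = cluster, kernels = "bray_curtis", B = 49,
                 seed = 3, method = "naive")
  expect_s3_class(nv, "glmmkat_test")
  expect_identical(nv$method, "naive")
})

test_that("naive mode is calibrated when the data truly are independent", {
  set.seed(58)
  comm <- fixture_community(p = 40)
  rej <- replicate(150, {
    dat <- simulate_study(n = 12, sigma_sq = 1e-8, community = comm,
                          n_assoc = 20)
    K <- distance_kernel(dist_bray_curtis(dat$counts))
    X <- cbind(`(Intercept)` = 1, x1 = dat$meta$x1, x2 = dat$meta$x2)
    kat_test_naive(dat$meta$y, X, K, "gaussian", B = 99)$results$p.value <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
})
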