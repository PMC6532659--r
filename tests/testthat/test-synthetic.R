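test_that("Dirichlet-multinomial rows hit the requested depth exactly", {
  set.seed(61)
  comm <- fixture_community(p = 120)
  cc <- simulate_dm_counts(comm$proportions, comm$dispersion, 25, 10000)
  expect_true(all(rowSums(cc) == 10000))
  expect_identical(dim(cc), c(25L, 120L))
  expect_error(simulate_dm_counts(comm$proportions, 1.2, 5), "dispersion")
  bad <- comm$proportions
  bad[1] <- bad[1] + 0.5
  expect_error(simulate_dm_counts(bad, 0.02, 5), "summing to 1")
})

test_that("dispersion estimator recovers truth and vanishes for multinomial", {
  set.seed(62)
  p <- 100
  props <- exp(rnorm(p))
  props <- props / sum(props)
  # multinomial data: dispersion ~ 0
  mn <- t(rmultinom(200, 10000, props))
  colnames(mn) <- paste0("o", 1:p)
  est0 <- fit_dm(mn)
  expect_lt(est0$dispersion, 0.02)
  expect_equal(sum(est0$proportions), 1, tolerance = 1e-10)
  # overdispersed data: within 20% relative error
  dm <- simulate_dm_counts(setNames(props, paste0("o", 1:p)), 0.1, 500, 10000)
  est <- fit_dm(dm)
  expect_lt(abs(est$dispersion - 0.1) / 0.1, 0.2)
  expect_error(fit_dm(mn[1, , drop = FALSE]), "two measurements")
})

test_that("near-zero dispersion approaches multinomial variance", {
  set.seed(63)
  p <- 30
  props <- rep(1 / p, p)
  cc <- simulate_dm_counts(setNames(props, paste0("o", 1:p)), 1e-4, 2000, 500)
  vr <- apply(cc, 2, var)
  vmult <- 500 * props * (1 - props)
  expect_true(all(vr / vmult > 0.8 & vr / vmult < 1.2))
})

test_that("within-cluster perturbation averages sequentially and rounds to even", {
  cc <- rbind(c(4, 0), c(0, 4), c(8, 0))
  rownames(cc) <- paste0("m", 1:3)
  colnames(cc) <- c("o1", "o2")
  out <- perturb_within_cluster(cc, rep("a", 3))
  expect_equal(unname(out[2, ]), c(2, 2))
  # third row averages with the ALREADY-updated second row: (2+8)/2, (2+0)/2
  expect_equal(unname(out[3, ]), c(5, 1))
  # singleton clusters unchanged
  single <- perturb_within_cluster(cc, c("a", "b", "c"))
  expect_identical(single, cc)
  # ties round to even: (1 + 0)/2 = 0.5 -> 0, (3 + 0)/2 = 1.5 -> 2
  cc2 <- rbind(c(1, 3), c(0, 0))
  rownames(cc2) <- c("m1", "m2")
  colnames(cc2) <- c("o1", "o2")
  out2 <- perturb_within_cluster(cc2, c("a", "a"))
  expect_equal(unname(out2[2, ]), c(0, 2))
})

test_that("perturbation induces positive adjacent-row correlation", {
  set.seed(64)
  comm <- fixture_community(p = 150)
  cl <- rep(sprintf("c%d", 1:20), each = 3)
  cc <- simulate_dm_counts(comm$proportions, 0.05, 60, 5000)
  pert <- perturb_within_cluster(cc, cl)
  adj_cor <- function(m) {
    mean(vapply(seq(1, 58, by = 3), function(i) {
      cor(m[i, ], m[i + 1, ])
    }, 0))
  }
  expect_gt(adj_cor(pert), adj_cor(cc))
})

test_that("associated-OTU scenarios select as designed", {
  set.seed(65)
  comm <- fixture_community(p = 150)
  cc <- simulate_dm_counts(comm$proportions, 0.02, 30, 10000)
  mra <- colMeans(cc / rowSums(cc))
  lower <- names(sort(mra))[1:75]
  a1 <- select_associated_otus(cc, "P1", comm)
  a2 <- select_associated_otus(cc, "P2", comm)
  a3 <- select_associated_otus(cc, "P3", comm)
  expect_length(a1, 50)
  expect_length(a2, 50)
  expect_true(all(a1 %in% lower))
  expect_length(intersect(a3, lower), 0)
  # P4: the PAM partition is disjoint and exhaustive; the set is one cluster
  part <- glmmkat:::pam_partition(comm)
  expect_identical(sort(unique(part)), 1:10)
  expect_length(part, 150)
  a4 <- select_associated_otus(cc, "P4", comm)
  expect_true(all(part[a4] == part[a4][1]))
  expect_setequal(a4, names(part)[part == part[a4][1]])
  small <- cc[, 1:80]
  expect_error(select_associated_otus(small, "P1", comm), "at least 100")
})

test_that("covariates have the designed confounding structure", {
  set.seed(66)
  comm <- fixture_community(p = 150)
  cl <- rep(sprintf("c%d", 1:150), each = 2)
  cc <- simulate_dm_counts(comm$proportions, 0.02, 300, 10000)
  A <- sample(colnames(cc), 50)
  cv <- simulate_covariates(cl, cc, A)
  # x1 constant within clusters, Bernoulli across
  expect_true(all(tapply(cv$x1, cl, function(v) length(unique(v))) == 1))
  expect_true(all(cv$x1 %in% c(0, 1)))
  # corr(x2, scale(sum_A z)) ~ 0.5/sqrt(1.25)
  s <- as.numeric(scale(rowSums(cc[, A])))
  expect_lt(abs(cor(cv$x2, s) - 0.5 / sqrt(1.25)), 0.12)
})

test_that("trait generator reproduces the designed intra-cluster correlations", {
  set.seed(67)
  comm <- fixture_community(p = 100)
  n <- 400
  cl <- rep(sprintf("c%d", 1:n), each = 2)
  tm <- rep(1:2, n)
  cc <- simulate_dm_counts(comm$proportions, 0.02, 2 * n, 5000)
  A <- sample(colnames(cc), 30)
  cv <- simulate_covariates(cl, cc, A)
  resid_icc <- function(y, keep = rep(TRUE, n)) {
    res <- resid(lm(y ~ cv$x1 + cv$x2))
    m <- matrix(res, ncol = 2, byrow = TRUE)
    cor(m[keep, 1], m[keep, 2])
  }
  y1 <- simulate_trait("gaussian", "intercept", 1, 0, cv, cc, A, cl)
  expect_lt(abs(resid_icc(y1) - 0.5), 0.1)      # sigma^2 = 1 -> ICC 1/2
  y0 <- simulate_trait("gaussian", "intercept", 1e-8, 0, cv, cc, A, cl)
  expect_lt(abs(resid_icc(y0)), 0.1)
  # Binomial and Poisson responses have the right support
  yb <- simulate_trait("binomial", "intercept", 1, 0, cv, cc, A, cl)
  expect_true(all(yb %in% c(0, 1)))
  yp <- simulate_trait("poisson", "intercept", 0.5, 0, cv, cc, A, cl)
  expect_true(all(yp >= 0 & yp == round(yp)))
})

test_that("slope-model equal-time correlation matches (1 + j^2) s/(s(1 + j^2) + 1)", {
  set.seed(68)
  n <- 2000
  cl <- rep(seq_len(n), each = 2)
  # equal times within pair: both measurements at t = j
  for (j in c(1, 2)) {
    s <- 0.5
    v1 <- rnorm(n, 0, sqrt(s))
    v2 <- rnorm(n, 0, sqrt(s))
    eta <- v1[rep(1:n, each = 2)] + j * v2[rep(1:n, each = 2)]
    y <- eta + rnorm(2 * n)
    m <- matrix(y, ncol = 2, byrow = TRUE)
    target <- s * (1 + j^2) / (s * (1 + j^2) + 1)  # = (1+j^2)/(j^2+3) at s = 1/2
    expect_lt(abs(cor(m[, 1], m[, 2]) - target), 0.05)
  }
})

test_that("fixture tree is binary, rooted and optionally ultrametric", {
  tr <- make_fixture_tree(40, seed = 5)
  expect_equal(nrow(tr$edge), 2 * 40 - 2)
  expect_true(ape::is.rooted(tr))
  depths <- ape::node.depth.edgelength(tr)[1:40]
  expect_lt(diff(range(depths)), 1e-10)
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph, t(coph))
  expect_equal(unname(diag(coph)), rep(0, 40))
  tr2 <- make_fixture_tree(15, ultrametric = FALSE, seed = 5)
  expect_equal(nrow(tr2$edge), 2 * 15 - 2)
  # deterministic under seed, and the caller's RNG stream is untouched
  set.seed(1)
  before <- rnorm(1)
  t_a <- make_fixture_tree(10, seed = 99)
  set.seed(1)
  expect_equal(rnorm(1), before)
  t_b <- make_fixture_tree(10, seed = 99)
  expect_identical(ape::write.tree(t_a), ape::write.tree(t_b))
})

test_that("simulate_study assembles the full design", {
  set.seed(69)
  comm <- fixture_community(p = 100)
  dat <- simulate_study(n = 20, family = "poisson", sigma_sq = 0.5,
                        beta = 1, scenario = "P2", community = comm)
  expect_equal(nrow(dat$counts), sum(cluster_size_pattern(20)))
  expect_identical(dat$meta$measurement_id, rownames(dat$counts))
  expect_equal(unname(table(dat$meta$cluster)), rep(c(2L, 4L, 3L), c(7, 7, 6)),
               ignore_attr = TRUE)
  expect_true(all(dat$meta$time == unlist(lapply(cluster_size_pattern(20), seq_len))))
  expect_length(dat$assoc, 50)
})
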