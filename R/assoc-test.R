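#' Variance-component score statistic
#'
#' The reduced-form quadratic score statistic `Q = r' K r`, where `r` is
#' the working residual of the null fit and `K` a (PSD-corrected) kernel.
#' The half scaling and trace term of the full score do not change the
#' comparative ranks of observed and permuted statistics, so they are
#' dropped.
#'
#' @param r Working residual vector ([working_residual()]).
#' @param K Kernel matrix of matching dimension.
#' @return Non-negative scalar (for PSD `K`).
#' @export
score_statistic <- function(r, K) {
  if (!is.numeric(r) || length(r) != nrow(K) || nrow(K) != ncol(K)) {
    abort("dimension mismatch between `r` and `K`")
  }
  drop(crossprod(r, K %*% r))
}

#' Permutation p-value
#'
#' `p = (1 + #\{Q_perm >= Q_obs\}) / (1 + B)`: ties count, the estimate is
#' never zero and never exceeds one.
#'
#' @param q_obs Observed statistic.
#' @param q_perm Vector of `B >= 1` permuted statistics.
#' @return p-value in `(0, 1]`.
#' @export
kernel_pvalue <- function(q_obs, q_perm) {
  if (length(q_perm) < 1) abort("at least one permutation is required")
  (1 + sum(q_perm >= q_obs)) / (1 + length(q_perm))
}

# shared core: observed and permuted statistics for every kernel on one set
# of permutations, per-kernel p-values, and the rank-based min-p omnibus
.kat_core <- function(r, kernels, perms) {
  B <- ncol(perms)
  Rmat <- matrix(r[perms], nrow = length(r), ncol = B)
  q_obs <- numeric(length(kernels))
  p_kernel <- numeric(length(kernels))
  null_p <- matrix(NA_real_, nrow = B, ncol = length(kernels))
  for (h in seq_along(kernels)) {
    K <- kernels[[h]]
    if (nrow(K) != length(r)) abort("kernel dimension does not match the fitted data")
    q_obs[h] <- drop(crossprod(r, K %*% r))
    q_perm <- colSums(Rmat * (K %*% Rmat))
    p_kernel[h] <- (1 + sum(q_perm >= q_obs[h])) / (1 + B)
    # within-permutation rank-based null p-values (ties counted as >=)
    null_p[, h] <- (B - rank(q_perm, ties.method = "min") + 1) / B
  }
  t_obs <- min(p_kernel)
  t_null <- do.call(pmin, as.data.frame(null_p))
  p_omnibus <- (1 + sum(t_null <= t_obs)) / (1 + B)
  list(q_obs = q_obs, p_kernel = p_kernel, t_obs = t_obs, p_omnibus = p_omnibus)
}

#' Kernel association test on a fitted null model
#'
#' Computes the score statistic for each supplied kernel, calibrates
#' per-kernel p-values by block permutation of the working residual over
#' exchangeable clusters, and combines the kernels through the min-p
#' omnibus statistic whose null distribution is taken from the same
#' permutations (rank-based, ties conservative). All kernels share one
#' permutation stream, so their correlation structure is preserved in the
#' omnibus null.
#'
#' @param fit A `glmmkat_null` object.
#' @param kernels Named list of kernel matrices (see [distance_kernel()]),
#'   or a single matrix.
#' @param B Number of permutations.
#' @param seed Optional integer seed making the permutation stream
#'   reproducible (the caller's RNG state is restored afterwards).
#' @return Object of class `glmmkat_test` with a per-kernel results tibble
#'   and the omnibus statistic/p-value; see [tidy.glmmkat_test()].
#' @export
kat_test_kernels <- function(fit, kernels, B = 999, seed = NULL) {
  stopifnot(inherits(fit, "glmmkat_null"))
  if (is.matrix(kernels)) kernels <- list(kernel = kernels)
  if (length(kernels) < 1) abort("at least one kernel is required")
  if (is.null(names(kernels))) names(kernels) <- sprintf("kernel%d", seq_along(kernels))
  dims <- vapply(kernels, nrow, 1L)
  if (any(dims != fit$N)) abort("all kernels must be N x N with N matching the fit")
  scheme <- permutation_scheme(fit$cluster$index, fit$time,
                               mode = if (fit$random == "slope") "slope" else "intercept",
                               B = B)
  run <- function() {
    perms <- draw_permutations(scheme, B)
    .kat_core(fit$r, kernels, perms)
  }
  core <- if (is.null(seed)) run() else with_isolated_seed(seed, run())
  structure(
    list(results = tibble::tibble(kernel = names(kernels),
                                  statistic = core$q_obs,
                                  p.value = core$p_kernel),
         omnibus_stat = core$t_obs, omnibus_p = core$p_omnibus,
         B = B, seed = seed, method = "glmm",
         family = fit$family, random = fit$random, N = fit$N,
         n_clusters = fit$cluster$n),
    class = "glmmkat_test"
  )
}

#' Adaptive kernel association test for correlated microbiome data
#'
#' One-stop interface: fits the null GLMM on the metadata, builds the
#' requested ecological distance kernels from the count table (and tree),
#' and runs the block-permutation score tests with the min-p omnibus
#' combination.
#'
#' @inheritParams fit_glmm_null
#' @param counts OTU count matrix, measurements x OTUs, rows aligned with
#'   `data`.
#' @param tree Rooted phylogenetic tree (needed for UniFrac kernels).
#' @param kernels Candidate distance measures (see
#'   [ecological_distances()]); the default is the five-measure candidate
#'   set.
#' @param theta Generalized-UniFrac abundance exponent.
#' @param B Number of block permutations.
#' @param seed Optional seed for the permutation stream.
#' @param method `"glmm"` for the mixed-model test; `"naive"` for the
#'   independent-sample comparator (GLM null, unrestricted permutations) —
#'   provided only to demonstrate the inflation caused by ignoring
#'   within-cluster correlation.
#' @param psd Apply PSD correction to the kernels.
#' @return A `glmmkat_test` object.
#' @examples
#' comm <- fixture_community(p = 60)
#' dat <- simulate_study(n = 12, sigma_sq = 1, community = comm)
#' kat_test(dat$meta, dat$counts, dat$tree, trait = y,
#'          covariates = c(x1, x2), cluster = cluster, B = 99, seed = 1)
#' @export
kat_test <- function(data, counts, tree = NULL, trait, covariates = NULL,
                     cluster, time = NULL,
                     family = c("gaussian", "binomial", "poisson"),
                     random = c("intercept", "slope"),
                     kernels = c("jaccard", "bray_curtis", "u_unifrac",
                                 "g_unifrac", "w_unifrac"),
                     theta = 0.5, B = 999, seed = NULL,
                     method = c("glmm", "naive"),
                     w_matrix = c("working", "identity"),
                     psd = TRUE, control = glmmkat_control()) {
  method <- match.arg(method)
  counts <- validate_counts(counts, require_positive_rows = TRUE)
  if (nrow(counts) != nrow(data)) abort("`counts` and `data` must have the same number of rows")
  D <- ecological_distances(counts, tree, measures = kernels, theta = theta)
  Ks <- lapply(D, distance_kernel, psd = psd)
  if (method == "naive") {
    y <- resolve_column(rlang::enquo(trait), data, "trait")
    cq <- rlang::enquo(covariates)
    X <- if (rlang::quo_is_null(cq)) {
      matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      stats::model.matrix(~., data = as.data.frame(dplyr::select(data, !!cq)))
    }
    return(kat_test_naive(y, X, Ks, family = match.arg(family), B = B, seed = seed))
  }
  fit <- fit_glmm_null(data, {{ trait }}, {{ covariates }}, {{ cluster }},
                       {{ time }}, family = family, random = random,
                       w_matrix = w_matrix, control = control)
  kat_test_kernels(fit, Ks, B = B, seed = seed)
}

#' Naive independent-sample kernel test
#'
#' The same score statistic with the random-effect covariance set to zero
#' (an ordinary GLM null) and unrestricted permutation of all N residuals.
#' Treating correlated measurements as independent inflates the type I
#' error, increasingly so with the within-cluster correlation; this mode
#' exists to demonstrate that, not for inference on clustered data.
#'
#' @param y Trait vector.
#' @param X Covariate matrix with leading intercept column.
#' @param kernels Named list of kernel matrices (or one matrix).
#' @param family Trait family.
#' @param B Number of permutations.
#' @param seed Optional seed.
#' @return A `glmmkat_test` object (`method = "naive"`).
#' @export
kat_test_naive <- function(y, X, kernels,
                           family = c("gaussian", "binomial", "poisson"),
                           B = 999, seed = NULL) {
  family <- match.arg(family)
  if (is.matrix(kernels)) kernels <- list(kernel = kernels)
  if (is.null(names(kernels))) names(kernels) <- sprintf("kernel%d", seq_along(kernels))
  X <- as.matrix(X)
  N <- length(y)
  fam <- switch(family, gaussian = stats::gaussian(), binomial = stats::binomial(),
                poisson = stats::poisson())
  gfit <- stats::glm.fit(X, y, family = fam)
  mu <- gfit$fitted.values
  if (family == "gaussian") {
    w <- rep(sum((y - mu)^2) / (N - ncol(X)), N)
    ystar <- y
  } else {
    vmu <- if (family == "binomial") pmax(mu * (1 - mu), 1e-10) else pmax(mu, 1e-10)
    eta <- fam$linkfun(pmin(pmax(mu, 1e-10), if (family == "binomial") 1 - 1e-10 else Inf))
    ystar <- eta + (y - mu) / vmu
    w <- 1 / vmu
  }
  eta0 <- as.numeric(X %*% gfit$coefficients)
  r <- (ystar - eta0) / w
  run <- function() {
    perms <- vapply(seq_len(B), function(b) sample.int(N), integer(N))
    .kat_core(r, kernels, perms)
  }
  core <- if (is.null(seed)) run() else with_isolated_seed(seed, run())
  structure(
    list(results = tibble::tibble(kernel = names(kernels),
                                  statistic = core$q_obs,
                                  p.value = core$p_kernel),
         omnibus_stat = core$t_obs, omnibus_p = core$p_omnibus,
         B = B, seed = seed, method = "naive", family = family,
         random = "none", N = N, n_clusters = NA_integer_),
    class = "glmmkat_test"
  )
}

#' @export
print.glmmkat_test <- function(x, ...) {
  cat(sprintf("Kernel association test (%s%s, %d permutations)\n",
              x$method,
              if (x$method == "glmm") sprintf(", %s family, random %s", x$family, x$random) else "",
              x$B))
  print(as.data.frame(x$results), row.names = FALSE, digits = 4)
  if (nrow(x$results) > 1) {
    cat(sprintf("omnibus (min-p): statistic %.4g, p-value %.4g\n",
                x$omnibus_stat, x$omnibus_p))
  }
  invisible(x)
}
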