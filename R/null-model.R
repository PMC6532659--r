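#' Control parameters for null-model fitting
#'
#' @param pql_tol Convergence tolerance on the maximum absolute change in
#'   fixed effects and variance components between penalized
#'   quasi-likelihood iterations.
#' @param pql_maxit Maximum number of PQL iterations.
#' @param var_floor Lower floor on variance components, keeping the marginal
#'   covariance non-singular.
#' @param reml_reltol Relative tolerance of the REML optimizer.
#' @param mu_eps Clamp for fitted means: Binomial means are kept in
#'   `[mu_eps, 1 - mu_eps]`, Poisson means at or above `mu_eps`.
#' @return List of control values.
#' @export
glmmkat_control <- function(pql_tol = 1e-6, pql_maxit = 100, var_floor = 1e-8,
                            reml_reltol = 1e-10, mu_eps = 1e-8) {
  list(pql_tol = pql_tol, pql_maxit = pql_maxit, var_floor = var_floor,
       reml_reltol = reml_reltol, mu_eps = mu_eps)
}

# REML criterion for y ~ N(X alpha, Sigma(g) + phi * diag(wb)) with
# Sigma block-diagonal from cluster random effects (intercept, or
# independent intercept + slope). All cluster-wise algebra is done through
# the Woodbury identity with rowsum() aggregation, so a criterion
# evaluation costs O(N) with no per-cluster loop.
#
# est_phi = TRUE profiles the residual scale out (Gaussian REML): the `lg`
# parameters are then log variance RATIOS g/phi and the criterion is the
# profiled one; est_phi = FALSE fixes phi = 1 (the PQL convention for
# Binomial/Poisson working responses).
.reml_crit <- function(lg, y, X, gi, n, wb, tvec, est_phi, var_floor,
                       want_alpha = FALSE) {
  d <- if (is.null(tvec)) 1L else 2L
  g1 <- var_floor + exp(lg[1])
  g2 <- if (d == 2L) var_floor + exp(lg[2]) else NULL
  a <- 1 / wb
  P <- cbind(X, y)
  q2 <- ncol(P)
  if (d == 1L) {
    rs <- rowsum(cbind(a, P * a), gi)
    sa <- rs[, 1]
    U1 <- rs[, -1, drop = FALSE]
    m11 <- 1 / g1 + sa
    C <- crossprod(P, P * a) - crossprod(U1, U1 / m11)
    logdetM <- sum(log(m11))
    logdetG <- n * log(g1)
  } else {
    at <- a * tvec
    rs <- rowsum(cbind(a, at, at * tvec, P * a, P * at), gi)
    m11 <- 1 / g1 + rs[, 1]
    m12 <- rs[, 2]
    m22 <- 1 / g2 + rs[, 3]
    U1 <- rs[, 3 + seq_len(q2), drop = FALSE]
    U2 <- rs[, 3 + q2 + seq_len(q2), drop = FALSE]
    det <- m11 * m22 - m12^2
    C2 <- crossprod(U1, U1 * (m22 / det)) - crossprod(U1, U2 * (m12 / det)) -
      crossprod(U2, U1 * (m12 / det)) + crossprod(U2, U2 * (m11 / det))
    C <- crossprod(P, P * a) - C2
    logdetM <- sum(log(det))
    logdetG <- n * (log(g1) + log(g2))
  }
  p1 <- ncol(X)
  Cxx <- C[seq_len(p1), seq_len(p1), drop = FALSE]
  Cxy <- C[seq_len(p1), q2]
  Cyy <- C[q2, q2]
  R <- tryCatch(chol(Cxx), error = function(e) NULL)
  if (is.null(R)) return(list(crit = 1e30))
  alpha <- backsolve(R, forwardsolve(t(R), Cxy))
  rss <- max(Cyy - sum(Cxy * alpha), 1e-300)
  logdetCxx <- 2 * sum(log(diag(R)))
  crit <- if (est_phi) {
    logdetG + logdetM + sum(log(wb)) + logdetCxx + (length(y) - p1) * log(rss)
  } else {
    logdetG + logdetM + sum(log(wb)) + logdetCxx + rss
  }
  if (want_alpha) list(crit = crit, alpha = alpha, rss = rss) else list(crit = crit)
}

.reml_fit <- function(y, X, gi, n, wb, tvec, est_phi, control, start = NULL) {
  d <- if (is.null(tvec)) 1L else 2L
  fn <- function(lg) .reml_crit(lg, y, X, gi, n, wb, tvec, est_phi,
                                control$var_floor)$crit
  if (d == 1L) {
    opt <- optim(start %||% 0, fn, method = "Brent", lower = -30, upper = 12,
                 control = list(reltol = control$reml_reltol))
  } else {
    opt <- optim(start %||% c(0, 0), fn, method = "Nelder-Mead",
                 control = list(reltol = control$reml_reltol, maxit = 500))
  }
  lg <- opt$par
  pieces <- .reml_crit(lg, y, X, gi, n, wb, tvec, est_phi, control$var_floor,
                       want_alpha = TRUE)
  g <- control$var_floor + exp(lg)
  if (est_phi) {
    phi <- pieces$rss / (length(y) - ncol(X))
    g <- g * phi
  } else {
    phi <- 1
  }
  list(alpha = setNames(as.numeric(pieces$alpha), colnames(X)),
       g = g, phi = phi, lg = lg, crit = pieces$crit)
}

# BLUPs and working residual at the fitted (absolute-scale) parameters:
# gamma = S M^-1 u per measurement and r = V^-1 (y - X alpha), computed as
# A^-1 (resid - gamma) via the Woodbury identity.
.lmm_finish <- function(g, phi, alpha, y, X, gi, wb, tvec) {
  a <- 1 / (phi * wb)
  resid <- as.numeric(y - X %*% alpha)
  if (is.null(tvec)) {
    rs <- rowsum(cbind(a, a * resid), gi)
    m11 <- 1 / g[1] + rs[, 1]
    b1 <- rs[, 2] / m11
    gamma <- b1[gi]
    b2 <- NULL
  } else {
    at <- a * tvec
    rs <- rowsum(cbind(a, at, at * tvec, a * resid, at * resid), gi)
    m11 <- 1 / g[1] + rs[, 1]
    m12 <- rs[, 2]
    m22 <- 1 / g[2] + rs[, 3]
    u1 <- rs[, 4]
    u2 <- rs[, 5]
    det <- m11 * m22 - m12^2
    b1 <- (m22 * u1 - m12 * u2) / det
    b2 <- (m11 * u2 - m12 * u1) / det
    gamma <- b1[gi] + tvec * b2[gi]
  }
  list(gamma = as.numeric(gamma), r = as.numeric(a * (resid - gamma)),
       b1 = b1, b2 = b2)
}

#' Fit the null generalized linear mixed model (matrix interface)
#'
#' Fits `g(mu) = X alpha + gamma` with cluster random intercepts (or
#' independent random intercepts and slopes) and no microbiome term, and
#' returns every working quantity the variance-component score statistic
#' needs. Gaussian traits get an exact REML linear-mixed-model fit;
#' Binomial and Poisson traits are fitted by penalized quasi-likelihood
#' (PQL): the working response `y* = eta + (y - mu) g'(mu)` is refitted by
#' weighted REML until the fixed effects and variance components stabilize,
#' with the dispersion fixed at 1.
#'
#' The working-error variance defaults to the Breslow-Clayton working
#' variance, `diag(phi)` for Gaussian, `diag(1/(mu(1-mu)))` for Binomial and
#' `diag(1/mu)` for Poisson; `w_matrix = "identity"` replaces it with the
#' identity matrix for Binomial/Poisson traits (an alternative convention
#' that permutation inference also supports).
#'
#' @param y Trait vector (Gaussian: any finite real; Binomial: 0/1;
#'   Poisson: non-negative integers).
#' @param X Covariate matrix including a leading column of ones.
#' @param cluster Cluster identifier per measurement; rows must be grouped
#'   by cluster.
#' @param time Time point per measurement (required for `random = "slope"`).
#' @param family One of `"gaussian"`, `"binomial"`, `"poisson"` (canonical
#'   links: identity, logit, log).
#' @param random `"intercept"` for a random intercept per cluster,
#'   `"slope"` for independent random intercept and slope.
#' @param w_matrix Working-error variance convention (see Details).
#' @param control See [glmmkat_control()].
#' @return Object of class `glmmkat_null`; see the fields in the examples
#'   and [working_residual()], [marginal_covariance()].
#' @export
glmm_null_fit <- function(y, X, cluster, time = NULL,
                          family = c("gaussian", "binomial", "poisson"),
                          random = c("intercept", "slope"),
                          w_matrix = c("working", "identity"),
                          control = glmmkat_control()) {
  family <- match.arg(family)
  random <- match.arg(random)
  w_matrix <- match.arg(w_matrix)
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  if (nrow(X) != N || length(cluster) != N) abort("inconsistent dimensions of y, X and cluster")
  if (is.null(colnames(X))) colnames(X) <- c("(Intercept)", sprintf("x%d", seq_len(ncol(X) - 1)))
  if (!all(X[, 1] == 1)) abort("the first column of `X` must be an intercept column of ones")
  if (qr(X)$rank < ncol(X)) abort("`X` is rank-deficient (collinear covariates)")
  if (anyNA(y) || any(!is.finite(y))) abort("`y` contains missing or non-finite values")
  if (family == "binomial") {
    if (!all(y %in% c(0, 1))) abort("Binomial traits must be coded 0/1")
    if (length(unique(y)) < 2) abort("degenerate Binomial trait: all values equal")
  }
  if (family == "poisson" && (any(y < 0) || any(y != round(y)))) {
    abort("Poisson traits must be non-negative integers")
  }
  ci <- cluster_index(cluster)
  gi <- ci$index
  n <- ci$n
  if (n < 2) abort("at least 2 clusters are required")
  tvec <- NULL
  if (random == "slope") {
    if (is.null(time)) abort("`random = \"slope\"` requires time points for all measurements")
    tvec <- as.numeric(time)
    if (anyNA(tvec)) abort("missing time points")
  }

  trace <- NULL
  if (family == "gaussian") {
    wb <- rep(1, N)
    fit <- .reml_fit(y, X, gi, n, wb, tvec, est_phi = TRUE, control)
    fin <- .lmm_finish(fit$g, fit$phi, fit$alpha, y, X, gi, wb, tvec)
    eta <- as.numeric(X %*% fit$alpha + fin$gamma)
    mu <- eta
    delta <- rep(1, N)
    ystar <- y
    iterations <- 1L
    converged <- TRUE
    wb_final <- wb
  } else {
    linkinv <- if (family == "binomial") plogis else exp
    vfun <- if (family == "binomial") function(m) m * (1 - m) else function(m) m
    clamp <- function(m) {
      if (family == "binomial") pmin(pmax(m, control$mu_eps), 1 - control$mu_eps)
      else pmax(m, control$mu_eps)
    }
    glm_fam <- if (family == "binomial") stats::binomial() else stats::poisson()
    glm0 <- stats::glm.fit(X, y, family = glm_fam)
    alpha <- glm0$coefficients
    eta <- as.numeric(X %*% alpha)
    g_prev <- NULL
    start <- NULL
    converged <- FALSE
    iterations <- 0L
    trace <- list()
    repeat {
      iterations <- iterations + 1L
      mu <- clamp(linkinv(eta))
      vmu <- vfun(mu)
      ystar <- eta + (y - mu) / vmu
      wb <- 1 / vmu
      fit <- .reml_fit(ystar, X, gi, n, wb, tvec, est_phi = FALSE, control, start = start)
      fin <- .lmm_finish(fit$g, 1, fit$alpha, ystar, X, gi, wb, tvec)
      step <- max(abs(fit$alpha - alpha),
                  if (is.null(g_prev)) Inf else abs(fit$g - g_prev))
      trace[[iterations]] <- c(iter = iterations, max_change = step,
                               setNames(fit$g, paste0("g", seq_along(fit$g))))
      alpha <- fit$alpha
      g_prev <- fit$g
      start <- fit$lg
      eta <- as.numeric(X %*% alpha + fin$gamma)
      if (step < control$pql_tol) { converged <- TRUE; break }
      if (iterations >= control$pql_maxit) break
    }
    trace <- do.call(rbind, trace)
    if (!converged) {
      abort(sprintf("PQL did not converge in %d iterations (last max change %.3g)",
                    iterations, trace[nrow(trace), "max_change"]),
            iteration_trace = trace)
    }
    # one consistent pass at the converged parameters
    mu <- clamp(linkinv(eta))
    vmu <- vfun(mu)
    ystar <- as.numeric(eta + (y - mu) / vmu)
    wb_final <- 1 / vmu
    fin <- .lmm_finish(fit$g, 1, fit$alpha, ystar, X, gi, wb_final, tvec)
    eta <- as.numeric(X %*% fit$alpha + fin$gamma)
    delta <- 1 / vmu
  }

  # score-stage working-error variance and the residual r = V^-1 (y* - X alpha)
  if (family == "gaussian") {
    w_diag <- rep(fit$phi, N)
    r <- fin$r
  } else if (w_matrix == "working") {
    w_diag <- wb_final
    r <- fin$r
  } else {
    w_diag <- rep(1, N)
    fin_id <- .lmm_finish(fit$g, 1, fit$alpha, ystar, X, gi, w_diag, tvec)
    r <- fin_id$r
  }

  d <- if (random == "slope") 2L else 1L
  split_ix <- split(seq_len(N), gi)
  G <- diag(fit$g, d)
  sigma_blocks <- lapply(split_ix, function(ix) {
    S <- if (d == 2L) cbind(1, tvec[ix]) else matrix(1, length(ix), 1)
    S %*% G %*% t(S)
  })
  vinv_blocks <- lapply(seq_along(split_ix), function(b) {
    ix <- split_ix[[b]]
    Vb <- sigma_blocks[[b]] + diag(w_diag[ix], length(ix))
    inv <- tryCatch(solve(Vb), error = function(e) NULL)
    if (is.null(inv)) abort(sprintf("singular marginal covariance block in cluster '%s'", ci$labels[b]))
    inv
  })
  names(vinv_blocks) <- names(sigma_blocks)

  var_comp <- if (family == "gaussian") {
    if (d == 1L) c(sigma_g_sq = unname(fit$g[1]), sigma_e_sq = fit$phi)
    else c(sigma_g1_sq = unname(fit$g[1]), sigma_g2_sq = unname(fit$g[2]), sigma_e_sq = fit$phi)
  } else {
    if (d == 1L) c(sigma_g_sq = unname(fit$g[1]), phi = 1)
    else c(sigma_g1_sq = unname(fit$g[1]), sigma_g2_sq = unname(fit$g[2]), phi = 1)
  }

  structure(
    list(alpha = fit$alpha, gamma = fin$gamma, mu = as.numeric(mu),
         eta = as.numeric(eta), y_star = as.numeric(ystar),
         delta = as.numeric(delta), w_diag = as.numeric(w_diag),
         var_comp = var_comp, r = as.numeric(r),
         sigma_blocks = sigma_blocks, vinv_blocks = vinv_blocks,
         cluster = ci, time = tvec, family = family, random = random,
         w_matrix = w_matrix, converged = converged, iterations = iterations,
         trace = trace, y = y, X = X, N = N),
    class = "glmmkat_null"
  )
}

#' Fit the null GLMM from a metadata data frame
#'
#' Data-frame-first wrapper around [glmm_null_fit()]: columns are selected
#' with tidy evaluation (bare names or strings).
#'
#' @param data Data frame / tibble with one row per measurement, grouped by
#'   cluster.
#' @param trait Trait column.
#' @param covariates Covariate columns (tidyselect; `NULL` for an
#'   intercept-only model). Factors are expanded through [model.matrix()].
#' @param cluster Cluster identifier column.
#' @param time Time-point column (required for `random = "slope"`).
#' @inheritParams glmm_null_fit
#' @return A `glmmkat_null` object.
#' @examples
#' dat <- simulate_study(n = 10, community = fixture_community(p = 40))
#' fit <- fit_glmm_null(dat$meta, trait = y, covariates = c(x1, x2),
#'                      cluster = cluster)
#' tidy(fit)
#' @export
fit_glmm_null <- function(data, trait, covariates = NULL, cluster, time = NULL,
                          family = c("gaussian", "binomial", "poisson"),
                          random = c("intercept", "slope"),
                          w_matrix = c("working", "identity"),
                          control = glmmkat_control()) {
  y <- resolve_column(rlang::enquo(trait), data, "trait")
  cl <- resolve_column(rlang::enquo(cluster), data, "cluster")
  tq <- rlang::enquo(time)
  tvec <- if (rlang::quo_is_null(tq)) NULL else {
    resolve_column(tq, data, "time", allow_null = TRUE)
  }
  cq <- rlang::enquo(covariates)
  if (rlang::quo_is_null(cq)) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cdf <- dplyr::select(data, !!cq)
    if (anyNA(cdf)) abort("missing values in covariate columns are not allowed")
    X <- stats::model.matrix(~., data = as.data.frame(cdf))
  }
  if (anyNA(y) || anyNA(cl) || (!is.null(tvec) && anyNA(tvec))) {
    abort("missing values in trait, cluster or time columns are not allowed")
  }
  glmm_null_fit(y, X, cl, tvec, family = family, random = random,
                w_matrix = w_matrix, control = control)
}

# evaluate a tidy-eval column reference; a length-1 character that names a
# column is treated as that column, so string-driven (CLI) calls also work
resolve_column <- function(quo, data, what, allow_null = FALSE) {
  v <- rlang::eval_tidy(quo, data)
  if (allow_null && is.null(v)) return(NULL)
  if (is.character(v) && length(v) == 1 && v %in% names(data)) v <- data[[v]]
  if (length(v) != nrow(data)) abort(sprintf("`%s` must select one column of `data`", what))
  v
}

#' Working residual of a null fit
#'
#' The repeated factor of the score statistic: `V^-1 (y* - X alpha)`,
#' computed cluster-block-wise (no dense N x N inverse).
#'
#' @param fit A `glmmkat_null` object.
#' @param recompute Recompute from the stored blocks instead of returning
#'   the cached vector.
#' @return Numeric vector of length N.
#' @export
working_residual <- function(fit, recompute = FALSE) {
  stopifnot(inherits(fit, "glmmkat_null"))
  if (!fit$converged) abort("null fit did not converge")
  if (!recompute) return(fit$r)
  resid <- fit$y_star - as.numeric(fit$X %*% fit$alpha)
  out <- numeric(fit$N)
  split_ix <- split(seq_len(fit$N), fit$cluster$index)
  for (b in seq_along(split_ix)) {
    ix <- split_ix[[b]]
    out[ix] <- fit$vinv_blocks[[b]] %*% resid[ix]
  }
  out
}

#' Marginal covariance of a null fit
#'
#' Block-diagonal `V = Sigma + W` with per-cluster blocks
#' `Sigma_i = S_i G S_i'` (S_i the cluster's random-effect design), and its
#' inverse.
#'
#' @param fit A `glmmkat_null` object.
#' @return List with sparse block-diagonal matrices `V`, `Vinv` and the
#'   per-cluster block lists `V_blocks`, `Vinv_blocks`, `Sigma_blocks`.
#' @export
marginal_covariance <- function(fit) {
  stopifnot(inherits(fit, "glmmkat_null"))
  split_ix <- split(seq_len(fit$N), fit$cluster$index)
  V_blocks <- lapply(seq_along(split_ix), function(b) {
    ix <- split_ix[[b]]
    fit$sigma_blocks[[b]] + diag(fit$w_diag[ix], length(ix))
  })
  names(V_blocks) <- names(fit$sigma_blocks)
  list(V = Matrix::bdiag(V_blocks), Vinv = Matrix::bdiag(fit$vinv_blocks),
       V_blocks = V_blocks, Vinv_blocks = fit$vinv_blocks,
       Sigma_blocks = fit$sigma_blocks)
}

#' @export
print.glmmkat_null <- function(x, ...) {
  cat(sprintf("Null GLMM (%s, random %s): %d measurements in %d clusters\n",
              x$family, x$random, x$N, x$cluster$n))
  cat("fixed effects:\n")
  print(round(x$alpha, 4))
  cat("variance components:\n")
  print(round(x$var_comp, 4))
  if (x$family != "gaussian") {
    cat(sprintf("PQL converged in %d iterations (W: %s)\n", x$iterations, x$w_matrix))
  }
  invisible(x)
}
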