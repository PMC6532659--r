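# Independent oracles used across the suite. These deliberately take the
# slow, literal route (dense matrices, recursive tree descent, explicit
# loops) so that agreement with the package's fast paths is informative.

# brute-force UniFrac by enumerating every edge's descendant tip set
oracle_unifrac <- function(counts, tree, type = c("uw", "w", "g"), theta = 0.5) {
  type <- match.arg(type)
  P <- counts / rowSums(counts)
  nedge <- nrow(tree$edge)
  N <- nrow(counts)
  tips_of <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    children <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(children, tips_of))
  }
  D <- matrix(0, N, N, dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(N - 1)) {
    for (b in (a + 1):N) {
      num <- den <- 0
      for (e in seq_len(nedge)) {
        tl <- intersect(tips_of(tree$edge[e, 2]), colnames(counts))
        bl <- tree$edge.length[e]
        pa <- sum(P[a, tl])
        pb <- sum(P[b, tl])
        S <- pa + pb
        if (S <= 0) next
        if (type == "uw") {
          den <- den + bl
          if ((pa > 0) != (pb > 0)) num <- num + bl
        } else if (type == "w") {
          num <- num + bl * abs(pa - pb)
          den <- den + bl * S
        } else {
          num <- num + bl * S^theta * abs(pa - pb) / S
          den <- den + bl * S^theta
        }
      }
      D[a, b] <- D[b, a] <- if (den > 0) num / den else 0
    }
  }
  D
}

# dense-matrix REML: builds the full N x N marginal covariance and uses
# generic determinant/solve calls (no Woodbury, no block structure)
oracle_reml <- function(y, X, cluster, tvec = NULL, wb = rep(1, length(y)),
                        est_phi = TRUE) {
  cl <- as.integer(factor(cluster, levels = unique(cluster)))
  n <- max(cl)
  N <- length(y)
  Z1 <- 1 * outer(cl, seq_len(n), "==")
  build_V <- function(g) {
    V <- g[1] * tcrossprod(Z1) + diag(wb)
    if (!is.null(tvec)) V <- V + g[2] * tcrossprod(Z1 * tvec)
    V
  }
  crit <- function(lg) {
    V <- build_V(exp(lg))
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    alpha <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% alpha
    rss <- drop(t(r) %*% Vi %*% r)
    ld <- as.numeric(determinant(V)$modulus + determinant(A)$modulus)
    if (est_phi) ld + (N - ncol(X)) * log(rss) else ld + rss
  }
  d <- if (is.null(tvec)) 1 else 2
  opt <- if (d == 1) {
    optim(0, crit, method = "Brent", lower = -25, upper = 10)
  } else {
    optim(c(0, 0), crit, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 1000))
  }
  g <- exp(opt$par)
  V <- build_V(g)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  alpha <- drop(solve(A, t(X) %*% Vi %*% y))
  r <- y - X %*% alpha
  rss <- drop(t(r) %*% Vi %*% r)
  phi <- if (est_phi) rss / (N - ncol(X)) else 1
  list(alpha = alpha, g = g * phi, phi = phi, r_work = drop(Vi %*% r) / phi)
}

# naive PQL built on the dense oracle (independent of the package's loop)
oracle_pql <- function(y, X, cluster, family, maxit = 60, tol = 1e-7) {
  linkinv <- if (family == "binomial") plogis else exp
  vfun <- if (family == "binomial") function(m) m * (1 - m) else function(m) m
  fam <- if (family == "binomial") binomial() else poisson()
  eta <- drop(X %*% glm.fit(X, y, family = fam)$coefficients)
  alpha_prev <- rep(Inf, ncol(X))
  for (it in seq_len(maxit)) {
    mu <- linkinv(eta)
    mu <- pmin(pmax(mu, 1e-8), if (family == "binomial") 1 - 1e-8 else Inf)
    v <- vfun(mu)
    z <- eta + (y - mu) / v
    fit <- oracle_reml(z, X, cluster, wb = 1 / v, est_phi = FALSE)
    # BLUP-updated linear predictor via the dense covariance
    cl <- as.integer(factor(cluster, levels = unique(cluster)))
    Z1 <- 1 * outer(cl, seq_len(max(cl)), "==")
    V <- fit$g[1] * tcrossprod(Z1) + diag(1 / v)
    gamma <- fit$g[1] * tcrossprod(Z1) %*% solve(V, z - X %*% fit$alpha)
    eta <- drop(X %*% fit$alpha + gamma)
    if (max(abs(fit$alpha - alpha_prev)) < tol) break
    alpha_prev <- fit$alpha
  }
  fit
}

# small random count table with positive row sums
random_counts <- function(N, p, lambda = 4) {
  m <- matrix(rpois(N * p, lambda), N, p,
              dimnames = list(paste0("s", seq_len(N)), paste0("t", seq_len(p))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}

# paired one-sided exact binomial comparison of two rejection indicator
# vectors: is method a more often significant than method b?
paired_binomial_p <- function(rej_a, rej_b) {
  wins <- sum(rej_a & !rej_b)
  losses <- sum(!rej_a & rej_b)
  if (wins + losses == 0) return(1)
  stats::binom.test(wins, wins + losses, p = 0.5, alternative = "greater")$p.value
}
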