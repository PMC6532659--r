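#' Method-of-moments Dirichlet-multinomial estimator
#'
#' Estimates the mean relative-abundance profile and the single
#' overdispersion parameter of a Dirichlet-multinomial community from a
#' count table. Proportions are the column means of the row-normalized
#' counts; the dispersion comes from the moment identity
#' `Var(p_hat_k) = pi_k (1 - pi_k) (d + (1 - d)/R)` at read depth `R`
#' (mean depth is used when depths are unequal), pooled over OTUs.
#'
#' @param counts Count matrix with at least two rows.
#' @return List with `proportions` (simplex vector, named by OTU) and
#'   `dispersion` (in `[0, 1)`).
#' @export
fit_dm <- function(counts) {
  counts <- validate_counts(counts, require_positive_rows = TRUE)
  if (nrow(counts) < 2) abort("at least two measurements are required to estimate dispersion")
  depth <- rowSums(counts)
  P <- counts / depth
  pi_hat <- colMeans(P)
  v <- apply(P, 2, stats::var)
  R <- mean(depth)
  pq <- pi_hat * (1 - pi_hat)
  d <- (sum(v) - sum(pq) / R) / (sum(pq) * (1 - 1 / R))
  list(proportions = pi_hat, dispersion = max(0, min(d, 1 - 1e-12)))
}

#' Simulate Dirichlet-multinomial OTU counts
#'
#' Each row is an independent draw: Dirichlet proportions with
#' concentration `(1 - d)/d * proportions`, then a multinomial of
#' `total_reads` reads, so every row total equals `total_reads` exactly.
#' Uses the current RNG stream.
#'
#' @param proportions Mean relative abundances (summing to 1).
#' @param dispersion Overdispersion `d` in `(0, 1)`.
#' @param n_rows Number of measurements to draw.
#' @param total_reads Reads per measurement.
#' @return Integer count matrix `n_rows` x `length(proportions)`.
#' @export
simulate_dm_counts <- function(proportions, dispersion, n_rows, total_reads = 10000) {
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    abort("`proportions` must be a non-negative vector summing to 1")
  }
  if (dispersion <= 0 || dispersion >= 1) abort("`dispersion` must lie in (0, 1)")
  if (total_reads < 1) abort("`total_reads` must be at least 1")
  p <- length(proportions)
  conc <- (1 - dispersion) / dispersion * proportions
  G <- matrix(rgamma(n_rows * p, shape = rep(conc, each = n_rows)), nrow = n_rows)
  G <- G / rowSums(G)
  out <- matrix(0L, n_rows, p)
  for (i in seq_len(n_rows)) {
    out[i, ] <- rmultinom(1, total_reads, G[i, ])
  }
  rownames(out) <- sprintf("M%d", seq_len(n_rows))
  colnames(out) <- names(proportions) %||% sprintf("OTU%d", seq_len(p))
  out
}

#' Within-cluster count perturbation
#'
#' Induces within-cluster relatedness of the microbial profiles by the
#' sequential in-place recurrence `Z_ij <- (Z_i(j-1) + Z_ij)/2` for
#' `j = 2, ..., m_i`, where the previous row is the already-updated one and
#' the first row of each cluster is unchanged. Half-integer averages are
#' rounded to the nearest integer (ties to even) to keep counts integral.
#'
#' @param counts Count matrix, rows ordered by (cluster, within-cluster
#'   position).
#' @param cluster Cluster identifier per row.
#' @return Perturbed count matrix of the same shape.
#' @export
perturb_within_cluster <- function(counts, cluster) {
  ci <- cluster_index(cluster)
  out <- counts
  for (ix in split(seq_len(nrow(counts)), ci$index)) {
    if (length(ix) < 2) next
    for (j in ix[-1]) {
      out[j, ] <- round((out[j - 1, ] + out[j, ]) / 2)
    }
  }
  out
}

# cluster sizes per the unbalanced study designs: n = 20 assigns sizes
# 2 (clusters 1-7), 4 (8-14), 3 (15-20); n = 50 assigns 2 (1-17), 3 (18-34),
# 4 (35-50); other n splits into thirds with sizes 2/3/4
#' Cluster-size patterns of the simulation designs
#'
#' @param n Number of clusters.
#' @return Integer vector of cluster sizes (length `n`).
#' @export
cluster_size_pattern <- function(n) {
  if (n == 20) return(c(rep(2L, 7), rep(4L, 7), rep(3L, 6)))
  if (n == 50) return(c(rep(2L, 17), rep(3L, 17), rep(4L, 16)))
  if (n < 3) abort("need at least 3 clusters for the 2/3/4 pattern")
  k <- n %/% 3
  c(rep(2L, k), rep(3L, n - 2 * k), rep(4L, k))
}

#' Frozen synthetic community profile
#'
#' A deterministic stand-in for a real estimated community: a log-normal
#' mean relative-abundance profile over `p` OTUs, a fixed
#' Dirichlet-multinomial dispersion, and a matching random-coalescent
#' phylogeny. The profile is generated from a fixed internal seed (the
#' caller's RNG state is untouched) and memoized, so every session sees the
#' identical community. Absolute power levels under this synthetic profile
#' differ from those under any real community, but test calibration and the
#' kernel-ordering behaviour are robust to the profile.
#'
#' @param p Number of OTUs.
#' @param dispersion Dirichlet-multinomial overdispersion.
#' @return List with `proportions`, `dispersion`, `tree`, `otu_ids`, and a
#'   private cache environment.
#' @export
fixture_community <- function(p = 856, dispersion = 0.02) {
  key <- sprintf("community_%d_%g", p, dispersion)
  cache_get_or(key, function() {
    otu_ids <- sprintf("OTU%04d", seq_len(p))
    with_isolated_seed(104729L + p, {
      props <- exp(rnorm(p, 0, 2))
      props <- props / sum(props)
      tree <- make_fixture_tree(p, labels = otu_ids, ultrametric = TRUE)
    })
    list(proportions = setNames(props, otu_ids), dispersion = dispersion,
         tree = tree, otu_ids = otu_ids, cache = new.env(parent = emptyenv()))
  })
}

#' Random coalescent fixture tree
#'
#' Rooted binary tree over `p` leaves built by sequential random
#' coalescence with exponential waiting times ([ape::rcoal]); the
#' non-ultrametric option draws independent exponential branch lengths
#' ([ape::rtree]).
#'
#' @param p Number of leaves (>= 2).
#' @param labels Leaf labels (defaults to `OTU0001`...).
#' @param ultrametric Equal root-to-leaf path lengths?
#' @param seed Optional isolated seed (otherwise the current RNG stream is
#'   used).
#' @return Rooted [ape::phylo] tree with `2p - 2` edges.
#' @export
make_fixture_tree <- function(p, labels = NULL, ultrametric = TRUE, seed = NULL) {
  if (p < 2) abort("`p` must be at least 2")
  labels <- labels %||% sprintf("OTU%04d", seq_len(p))
  gen <- function() {
    if (ultrametric) ape::rcoal(p, tip.label = labels)
    else ape::rtree(p, tip.label = labels, br = stats::rexp)
  }
  tree <- if (is.null(seed)) gen() else with_isolated_seed(seed, gen())
  validate_tree(tree)
}

# PAM partition of the community's OTUs into k phylogenetic clusters, from
# cophenetic (path-length) distances on the fixture tree; memoized on the
# community object
pam_partition <- function(community, k = 10) {
  env <- community$cache
  key <- sprintf("pam_%d", k)
  if (!exists(key, envir = env, inherits = FALSE)) {
    coph <- stats::as.dist(ape::cophenetic.phylo(community$tree))
    part <- cluster::pam(coph, k = k, cluster.only = TRUE)
    assign(key, part[community$otu_ids], envir = env)
  }
  get(key, envir = env, inherits = FALSE)
}

#' Select the associated OTU set for a power scenario
#'
#' Scenarios: `P1` — `n_assoc` OTUs sampled from the lower half of mean
#' relative abundance; `P2` — sampled from all OTUs; `P3` — from the upper
#' half; `P4` — all OTUs of one (uniformly chosen) cluster among `k = 10`
#' PAM clusters of the tree's cophenetic distances, mimicking a
#' phylogenetically coherent signal. Uses the current RNG stream.
#'
#' @param counts Count table used to rank OTUs by mean relative abundance.
#' @param scenario `"P1"`, `"P2"`, `"P3"` or `"P4"`.
#' @param community Community object (required for `P4`; see
#'   [fixture_community()]).
#' @param n_assoc Number of associated OTUs for P1-P3.
#' @return Character vector of OTU identifiers.
#' @export
select_associated_otus <- function(counts, scenario, community = NULL, n_assoc = 50) {
  scenario <- match.arg(scenario, c("P1", "P2", "P3", "P4"))
  otus <- colnames(counts)
  p <- length(otus)
  if (scenario %in% c("P1", "P3") && p < 2 * n_assoc) {
    abort(sprintf("scenarios P1/P3 need at least %d OTUs (half of the table must hold %d)",
                  2 * n_assoc, n_assoc))
  }
  if (scenario == "P4") {
    if (is.null(community)) abort("scenario P4 requires `community` (for the tree partition)")
    part <- pam_partition(community)[otus]
    chosen <- sample(sort(unique(part)), 1)
    return(otus[part == chosen])
  }
  mra <- colMeans(counts / rowSums(counts))
  ord <- order(mra)                      # increasing abundance
  half <- floor(p / 2)
  pool <- switch(scenario,
                 P1 = otus[ord[seq_len(half)]],
                 P2 = otus,
                 P3 = otus[ord[(p - half + 1):p]])
  sample(pool, n_assoc)
}

#' Simulate covariates with microbiome confounding
#'
#' `x1` is cluster-constant Bernoulli(0.5); `x2` is
#' `0.5 * scale(sum of associated-OTU counts) + N(0, 1)`, a confounder
#' associated with both the community and (through the trait model) the
#' trait. `scale` standardizes across all N measurements.
#'
#' @param cluster Cluster identifier per measurement.
#' @param counts Count table.
#' @param assoc Associated OTU identifiers.
#' @return Tibble with columns `x1`, `x2`.
#' @export
simulate_covariates <- function(cluster, counts, assoc) {
  ci <- cluster_index(cluster)
  x1 <- rbinom(ci$n, 1, 0.5)[ci$index]
  s <- rowSums(counts[, assoc, drop = FALSE])
  x2 <- 0.5 * scale_vec(s, "associated-OTU sum") + rnorm(length(s))
  tibble::tibble(x1 = x1, x2 = x2)
}

#' Simulate a trait under the null or alternative GLMM
#'
#' Linear predictor
#' `eta = 0.5 scale(x1 + x2) + beta scale(sum_A z) + s' v`, with
#' `v ~ N(0, sigma_sq)` random intercepts (or independent intercepts and
#' slopes with time `t = j`); Gaussian traits add `N(0, 1)` errors,
#' Binomial traits are Bernoulli(logit^-1(eta)), Poisson traits
#' Poisson(exp(eta)).
#'
#' @param family Trait family.
#' @param random Random-effect form.
#' @param sigma_sq Random-effect variance (shared by intercept and slope in
#'   the slope model).
#' @param beta Microbiome effect size (0 under the null).
#' @param covariates Tibble from [simulate_covariates()].
#' @param counts Count table.
#' @param assoc Associated OTU set.
#' @param cluster Cluster identifier per measurement.
#' @param time Time per measurement (slope model).
#' @return Numeric (or 0/1 integer) trait vector.
#' @export
simulate_trait <- function(family, random, sigma_sq, beta, covariates, counts,
                           assoc, cluster, time = NULL) {
  ci <- cluster_index(cluster)
  eta <- 0.5 * scale_vec(covariates$x1 + covariates$x2, "x1 + x2")
  if (beta != 0) {
    eta <- eta + beta * scale_vec(rowSums(counts[, assoc, drop = FALSE]), "associated-OTU sum")
  }
  if (random == "intercept") {
    v <- rnorm(ci$n, 0, sqrt(sigma_sq))
    eta <- eta + v[ci$index]
  } else {
    if (is.null(time)) abort("slope model requires time points")
    v1 <- rnorm(ci$n, 0, sqrt(sigma_sq))
    v2 <- rnorm(ci$n, 0, sqrt(sigma_sq))
    eta <- eta + v1[ci$index] + time * v2[ci$index]
  }
  switch(family,
         gaussian = eta + rnorm(length(eta)),
         binomial = rbinom(length(eta), 1, plogis(eta)),
         poisson = {
           if (any(eta > 30)) abort("Poisson linear predictor exceeds 30; mean would overflow")
           rpois(length(eta), exp(eta))
         },
         abort(sprintf("unknown family '%s'", family)))
}

#' Simulate one correlated microbiome study
#'
#' End-to-end generator: Dirichlet-multinomial counts at fixed depth,
#' within-cluster perturbation, a cluster-level and a confounded
#' measurement-level covariate, and a trait from the requested GLMM. The
#' associated OTU set is drawn even under `beta = 0`, because the
#' confounder `x2` is built from it in both cases. Uses the current RNG
#' stream; wrap in `set.seed()` for reproducibility.
#'
#' @param n Number of clusters (sizes from [cluster_size_pattern()]).
#' @param family Trait family.
#' @param random Random-effect form (`"intercept"` uses no time; `"slope"`
#'   sets `t_ij = j`).
#' @param sigma_sq Random-effect variance (1/2, 1, 3/2 give intra-cluster
#'   correlations 1/3, 1/2, 3/5 for Gaussian random intercepts).
#' @param beta Microbiome effect (0 for type-I-error studies, 1 for power).
#' @param scenario Associated-OTU scenario for `beta != 0` (`"P1"`..`"P4"`;
#'   `NULL` draws a plain random set for the confounder).
#' @param community Community profile ([fixture_community()] by default).
#' @param total_reads Reads per measurement.
#' @param n_assoc Size of the associated set (P1-P3).
#' @return List with `counts`, `meta` (tibble: measurement_id, cluster,
#'   time, y, x1, x2), `tree`, `assoc`, `family`, `random`.
#' @export
simulate_study <- function(n = 20,
                           family = c("gaussian", "binomial", "poisson"),
                           random = c("intercept", "slope"),
                           sigma_sq = 1, beta = 0, scenario = NULL,
                           community = fixture_community(),
                           total_reads = 10000, n_assoc = 50) {
  family <- match.arg(family)
  random <- match.arg(random)
  sizes <- cluster_size_pattern(n)
  N <- sum(sizes)
  cluster <- rep(sprintf("C%02d", seq_len(n)), sizes)
  time <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  counts <- simulate_dm_counts(community$proportions, community$dispersion,
                               N, total_reads)
  counts <- perturb_within_cluster(counts, cluster)
  # small test communities cap the associated set at half the OTUs
  n_assoc <- min(n_assoc, ncol(counts) %/% 2)
  assoc <- if (is.null(scenario)) {
    sample(colnames(counts), n_assoc)
  } else {
    select_associated_otus(counts, scenario, community, n_assoc)
  }
  covs <- simulate_covariates(cluster, counts, assoc)
  y <- simulate_trait(family, random, sigma_sq, beta, covs, counts, assoc,
                      cluster, time)
  meta <- tibble::tibble(measurement_id = rownames(counts),
                         cluster = cluster, time = time, y = y,
                         x1 = covs$x1, x2 = covs$x2)
  list(counts = counts, meta = meta, tree = community$tree, assoc = assoc,
       family = family, random = random)
}
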