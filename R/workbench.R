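#' Rarefy a count table to even depth
#'
#' Subsamples every measurement's reads without replacement to exactly
#' `depth` reads, the standard control for unequal library sizes. Uses the
#' current RNG stream.
#'
#' @param counts Count matrix.
#' @param depth Target depth; must not exceed any row total (defaults to
#'   the minimum row total).
#' @return Rarefied count matrix (all row sums equal `depth`).
#' @export
rarefy_counts <- function(counts, depth = min(rowSums(counts))) {
  counts <- validate_counts(counts, require_positive_rows = TRUE)
  tot <- rowSums(counts)
  low <- tot < depth
  if (any(low)) {
    abort(sprintf("row(s) with fewer than %d reads: %s", depth,
                  paste(rownames(counts)[low], collapse = ", ")))
  }
  # vegan warns about its own heuristic for spotting non-count input; the
  # inputs here are validated integer counts, so that advisory is noise
  out <- withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  dimnames(out) <- dimnames(counts)
  out
}

#' Drop OTUs of low average relative abundance
#'
#' Removes OTU columns whose mean (over measurements) relative abundance
#' falls below `threshold`; survivor order is preserved.
#'
#' @param counts Count matrix.
#' @param threshold Mean relative-abundance cutoff in `[0, 1)`.
#' @return Filtered count matrix.
#' @export
filter_low_abundance <- function(counts, threshold = 1e-5) {
  counts <- validate_counts(counts, require_positive_rows = TRUE)
  if (threshold < 0 || threshold >= 1) abort("`threshold` must lie in [0, 1)")
  mra <- colMeans(counts / rowSums(counts))
  keep <- mra >= threshold
  if (!any(keep)) abort("all OTUs fall below the abundance threshold")
  counts[, keep, drop = FALSE]
}

#' Drop measurements with low sequencing depth
#'
#' Removes rows with total reads below `min_reads` from both the count
#' table and the aligned metadata; clusters emptied entirely are dropped.
#'
#' @param counts Count matrix.
#' @param data Metadata (one row per measurement, aligned with `counts`).
#' @param cluster Cluster column of `data` (tidy-eval).
#' @param min_reads Depth threshold.
#' @return List with the filtered `counts` and `data`.
#' @export
filter_low_depth <- function(counts, data, cluster, min_reads = 10000) {
  if (nrow(counts) != nrow(data)) abort("`counts` and `data` must align row-wise")
  keep <- rowSums(counts) >= min_reads
  counts2 <- counts[keep, , drop = FALSE]
  data2 <- data[keep, , drop = FALSE]
  cl <- resolve_column(rlang::enquo(cluster), data2, "cluster")
  if (length(unique(cl)) < 2) abort("fewer than 2 clusters remain after depth filtering")
  list(counts = counts2, data = data2)
}

#' BMI categories
#'
#' Standard cutoffs at 18.5, 25 and 30 kg/m^2.
#'
#' @param bmi Numeric BMI values.
#' @return Factor with levels under/normal/over/obese.
#' @export
categorize_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("under", "normal", "over", "obese"), right = FALSE)
}

# one simulated replicate -> per-kernel and omnibus p-values; shared by the
# type-I-error and power runners. Kernels are rebuilt per replicate from
# the replicate's counts; the tree-edge structure is precomputed once.
.replicate_pvalues <- function(n, family, random, sigma_sq, beta, scenario,
                               community, kernels, theta, B, struct,
                               w_matrix = "working") {
  dat <- simulate_study(n = n, family = family, random = random,
                        sigma_sq = sigma_sq, beta = beta, scenario = scenario,
                        community = community)
  D <- ecological_distances(dat$counts, measures = kernels, theta = theta,
                            structure = struct)
  Ks <- lapply(D, distance_kernel, psd = TRUE)
  fit <- glmm_null_fit(dat$meta$y,
                       cbind(`(Intercept)` = 1, x1 = dat$meta$x1, x2 = dat$meta$x2),
                       dat$meta$cluster,
                       time = if (random == "slope") dat$meta$time else NULL,
                       family = family, random = random, w_matrix = w_matrix)
  res <- kat_test_kernels(fit, Ks, B = B)
  c(setNames(res$results$p.value, res$results$kernel),
    omnibus = res$omnibus_p)
}

.run_experiment <- function(cells, reps, B, alpha, seed, kernels, theta,
                            community, beta_default, progress,
                            detail = FALSE) {
  community <- community %||% fixture_community()
  need_uf <- any(c("u_unifrac", "g_unifrac", "w_unifrac") %in% kernels)
  struct <- if (need_uf) unifrac_structure(community$tree, community$otu_ids) else NULL
  # one seed bank shared by every cell, so paired (per-replicate)
  # comparisons across cells are meaningful
  rep_seeds <- with_isolated_seed(seed, sample.int(.Machine$integer.max - 1, reps))
  out <- vector("list", nrow(cells))
  detail_p <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    beta <- if ("beta" %in% names(cell)) cell$beta else beta_default
    scenario <- if ("scenario" %in% names(cell) && !is.na(cell$scenario)) cell$scenario else NULL
    pmat <- matrix(NA_real_, nrow = reps, ncol = length(kernels) + 1,
                   dimnames = list(NULL, c(kernels, "omnibus")))
    failed <- 0L
    for (r in seq_len(reps)) {
      set.seed(rep_seeds[r])
      pv <- tryCatch(
        .replicate_pvalues(cell$n, cell$family, cell$random, cell$sigma_sq,
                           beta, scenario, community, kernels, theta, B, struct),
        error = function(e) NULL)
      if (is.null(pv)) failed <- failed + 1L else pmat[r, names(pv)] <- pv
      if (progress && r %% 100 == 0) message(sprintf("cell %d/%d: replicate %d/%d", ci, nrow(cells), r, reps))
    }
    ok <- stats::complete.cases(pmat)
    rates <- colMeans(pmat[ok, , drop = FALSE] <= alpha)
    nr <- sum(ok)
    if (detail) detail_p[[ci]] <- pmat
    out[[ci]] <- dplyr::bind_cols(
      cell[rep(1, length(rates)), , drop = FALSE],
      tibble::tibble(test = names(rates),
                     rejection_rate = as.numeric(rates),
                     mc_se = as.numeric(sqrt(rates * (1 - rates) / nr)),
                     reps_used = nr, failed = failed, B = B, alpha = alpha))
  }
  res <- dplyr::bind_rows(out)
  if (detail) attr(res, "pvalues") <- detail_p
  res
}

#' Empirical type-I-error experiment
#'
#' For each design cell, simulates `reps` independent null studies
#' (`beta = 0`), runs the per-kernel and omnibus block-permutation tests,
#' and reports empirical rejection rates at level `alpha` with Monte-Carlo
#' standard errors. Deterministic under `seed`; the replicate seed bank is
#' shared across cells. Replicates whose null fit fails to converge are
#' dropped and counted in the `failed` column.
#'
#' @param cells Tibble of design cells with columns `family`, `random`,
#'   `n`, `sigma_sq`.
#' @param reps Replicates per cell.
#' @param B Permutations per test.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param kernels Candidate distance measures.
#' @param theta Generalized-UniFrac exponent.
#' @param community Community profile (defaults to [fixture_community()]).
#' @param progress Emit progress messages.
#' @param detail Also return the per-replicate p-value matrices (one per
#'   cell) in the `"pvalues"` attribute, for paired comparisons between
#'   cells or kernels.
#' @return Tidy tibble: one row per (cell, test) with `rejection_rate`,
#'   `mc_se`, `reps_used`.
#' @export
run_type1_experiment <- function(cells, reps = 2000, B = 499, alpha = 0.05,
                                 seed = 1,
                                 kernels = c("jaccard", "bray_curtis",
                                             "u_unifrac", "g_unifrac", "w_unifrac"),
                                 theta = 0.5, community = NULL,
                                 progress = FALSE, detail = FALSE) {
  cells$beta <- 0
  .run_experiment(cells, reps, B, alpha, seed, kernels, theta, community,
                  beta_default = 0, progress = progress, detail = detail)
}

#' Empirical power experiment
#'
#' As [run_type1_experiment()] but with `beta = 1` and a per-cell
#' associated-OTU `scenario` (`"P1"`..`"P4"`), so rejection rates estimate
#' power.
#'
#' @inheritParams run_type1_experiment
#' @param cells Tibble with columns `family`, `random`, `n`, `sigma_sq`,
#'   `scenario` (and optionally `beta`).
#' @export
run_power_experiment <- function(cells, reps = 1000, B = 499, alpha = 0.05,
                                 seed = 1,
                                 kernels = c("jaccard", "bray_curtis",
                                             "u_unifrac", "g_unifrac", "w_unifrac"),
                                 theta = 0.5, community = NULL,
                                 progress = FALSE, detail = FALSE) {
  if (!"scenario" %in% names(cells)) abort("power cells need a `scenario` column")
  if (!"beta" %in% names(cells)) cells$beta <- 1
  .run_experiment(cells, reps, B, alpha, seed, kernels, theta, community,
                  beta_default = 1, progress = progress, detail = detail)
}
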