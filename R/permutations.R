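#' Exchangeable cluster groups for block permutation
#'
#' Under the random-intercept model clusters are exchangeable when they have
#' the same number of measurements; under the random-slope model they must
#' also share the same time-point vector. Singleton groups are allowed —
#' those clusters are never relocated.
#'
#' @param cluster Cluster identifier per measurement (rows grouped by
#'   cluster).
#' @param time Time point per measurement (used in `mode = "slope"`).
#' @param mode `"intercept"` or `"slope"`.
#' @return A tibble with one row per cluster: `cluster`, `size`, `group`
#'   (integer group id).
#' @export
exchangeable_groups <- function(cluster, time = NULL, mode = c("intercept", "slope")) {
  mode <- match.arg(mode)
  ci <- cluster_index(cluster)
  split_ix <- split(seq_along(ci$index), ci$index)
  key <- if (mode == "intercept") {
    as.character(ci$sizes)
  } else {
    if (is.null(time)) abort("slope mode requires time points")
    vapply(split_ix, function(ix) {
      paste(length(ix), paste(time[ix], collapse = ","), sep = "|")
    }, "")
  }
  tibble::tibble(cluster = ci$labels, size = ci$sizes,
                 group = as.integer(factor(key, levels = unique(key))))
}

#' Block-permutation scheme over exchangeable clusters
#'
#' Encodes the permutation null used by the score tests: whole clusters are
#' relabelled uniformly at random within exchangeable groups, and — in
#' intercept mode only — measurement positions are additionally shuffled
#' within every cluster. Slope mode preserves within-cluster order and
#' therefore needs at least one non-singleton exchangeable group.
#'
#' @inheritParams exchangeable_groups
#' @param B Number of permutations drawn by consumers of the scheme.
#' @return Object of class `glmmkat_perm_scheme`.
#' @export
permutation_scheme <- function(cluster, time = NULL,
                               mode = c("intercept", "slope"), B = 999) {
  mode <- match.arg(mode)
  ci <- cluster_index(cluster)
  blocks <- split(seq_along(ci$index), ci$index)
  grp <- exchangeable_groups(cluster, time, mode)$group
  groups <- split(seq_len(ci$n), grp)
  if (mode == "slope" && all(lengths(groups) == 1)) {
    abort("no exchangeable clusters; permutation null is degenerate (slope mode requires clusters sharing size and time points)")
  }
  # concatenated positions per group, in cluster order (blocks in one group
  # share a size, so concatenations align position-wise)
  group_pos <- lapply(groups, function(g) unlist(blocks[g], use.names = FALSE))
  structure(
    list(blocks = blocks, groups = groups, group_pos = group_pos,
         block_id = rep(seq_len(ci$n), ci$sizes), mode = mode,
         N = length(ci$index), n = ci$n, B = B),
    class = "glmmkat_perm_scheme"
  )
}

#' Draw one block permutation
#'
#' Returns an index vector `p` such that `r[p]` is the permuted version of
#' a measurement-level vector `r`: each cluster's block of entries is
#' replaced by the block of a uniformly chosen same-group cluster, and in
#' intercept mode entries are additionally shuffled within clusters. Uses
#' the current RNG stream.
#'
#' @param scheme A [permutation_scheme()].
#' @return Integer permutation of `1:N`.
#' @export
generate_permutation <- function(scheme) {
  stopifnot(inherits(scheme, "glmmkat_perm_scheme"))
  drop(draw_permutations(scheme, 1L))
}

# N x B matrix of permutations (column-wise draws from the scheme); the
# draw loop lives in C++ but consumes R's RNG stream, so results are
# reproducible under set.seed()
draw_permutations <- function(scheme, B) {
  draw_permutations_cpp(unname(scheme$blocks), unname(scheme$groups),
                        scheme$mode == "intercept", scheme$N, as.integer(B))
}
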