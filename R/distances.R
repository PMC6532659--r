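#' Ecological distance matrices for microbiome data
#'
#' The five candidate community distances used by the kernel association
#' tests: binary Jaccard dissimilarity, Bray-Curtis dissimilarity, and the
#' unweighted, generalized and weighted UniFrac distances. Jaccard and
#' unweighted UniFrac use incidence (presence/absence with count > 0 as
#' presence) only; Bray-Curtis uses the counts as given (rarefy first if
#' library sizes are unequal); the UniFrac variants always normalize rows to
#' relative abundances internally, which makes them library-size invariant.
#'
#' @param counts Count matrix, measurements x OTUs; all row totals must be
#'   positive.
#' @param tree Rooted [ape::phylo] tree with branch lengths whose leaves
#'   cover `colnames(counts)` (UniFrac only).
#' @param theta Abundance exponent in `[0, 1]` for generalized UniFrac;
#'   `theta = 1` coincides with the (normalized) weighted variant and
#'   `theta = 0` down-weights abundance entirely.
#' @return A symmetric N x N distance matrix with zero diagonal and entries
#'   in `[0, 1]`, carrying a `"measure"` attribute.
#' @name distances
NULL

dist_attr <- function(D, ids, measure, theta = NULL) {
  dimnames(D) <- list(ids, ids)
  attr(D, "measure") <- measure
  if (!is.null(theta)) attr(D, "theta") <- theta
  D
}

# sparse pairwise merges in C++; vegan::vegdist computes the same
# quantities and serves as the independent cross-check in the test suite
.dist_jaccard_raw <- function(counts) {
  D <- count_distances_cpp(counts, TRUE, FALSE)$jaccard
  dist_attr(D, rownames(counts), "jaccard")
}

.dist_bray_raw <- function(counts) {
  D <- count_distances_cpp(counts, FALSE, TRUE)$bray
  dist_attr(D, rownames(counts), "bray_curtis")
}

#' @rdname distances
#' @export
dist_jaccard <- function(counts) {
  .dist_jaccard_raw(validate_counts(counts, require_positive_rows = TRUE))
}

#' @rdname distances
#' @export
dist_bray_curtis <- function(counts) {
  .dist_bray_raw(validate_counts(counts, require_positive_rows = TRUE))
}

# Per-edge structure of a rooted tree, aligned to a fixed OTU ordering:
# a sparse tip-by-edge incidence matrix (tip descends from edge), branch
# lengths, and the column permutation mapping counts columns onto tips.
# Cached by callers that recompute distances on many tables over one tree.
#' Precompute the tree-edge structure used by the UniFrac distances
#'
#' @param tree Rooted tree with branch lengths.
#' @param otu_ids OTU identifiers (the column order of the count tables the
#'   structure will be used with).
#' @return An opaque list passed to the UniFrac functions via `structure.`
#' @export
unifrac_structure <- function(tree, otu_ids) {
  tree <- validate_tree(tree)
  miss <- setdiff(otu_ids, tree$tip.label)
  if (length(miss) > 0) {
    abort(sprintf("OTU id(s) missing from tree leaves: %s%s",
                  paste(utils::head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5) else ""))
  }
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  E <- nrow(edge)
  # incoming-edge index per node
  edge_of <- integer(max(edge))
  edge_of[edge[, 2]] <- seq_len(E)
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # walk each tip up to the root, collecting the edges it descends from
  ii <- integer(0); jj <- integer(0)
  tip_pos <- match(otu_ids, tree$tip.label)
  for (k in seq_along(otu_ids)) {
    node <- tip_pos[k]
    path <- integer(0)
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent_of[node]
    }
    ii <- c(ii, rep.int(k, length(path)))
    jj <- c(jj, path)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(otu_ids), E))
  list(M = M, blen = tree$edge.length, otu_ids = otu_ids, n_edges = E)
}

# edges x measurements cumulative relative-abundance matrix
edge_abundance <- function(counts, struct) {
  P <- counts[, struct$otu_ids, drop = FALSE] / rowSums(counts)
  t(as.matrix(P %*% struct$M))
}

unifrac_all <- function(counts, tree, theta = 0.5, structure = NULL,
                        which = c("unweighted", "generalized", "weighted"),
                        validated = FALSE) {
  if (!validated) counts <- validate_counts(counts, require_positive_rows = TRUE)
  struct <- structure %||% unifrac_structure(tree, colnames(counts))
  if (!setequal(intersect(struct$otu_ids, colnames(counts)), colnames(counts))) {
    abort("UniFrac structure does not cover the OTU ids of `counts`")
  }
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    abort("`theta` must be a single number in [0, 1]")
  }
  Et <- edge_abundance(counts, struct)
  res <- unifrac_sparse_cpp(Et, struct$blen, theta,
                            "unweighted" %in% which,
                            "generalized" %in% which,
                            "weighted" %in% which)
  ids <- rownames(counts)
  out <- list()
  if ("unweighted" %in% which) out$unweighted <- dist_attr(res$unweighted, ids, "u_unifrac")
  if ("generalized" %in% which) out$generalized <- dist_attr(res$generalized, ids, "g_unifrac", theta)
  if ("weighted" %in% which) out$weighted <- dist_attr(res$weighted, ids, "w_unifrac")
  out
}

#' @rdname distances
#' @param structure Optional precomputed [unifrac_structure()] (a pure
#'   speed-up when many tables share one tree).
#' @export
dist_unifrac_unweighted <- function(counts, tree = NULL, structure = NULL) {
  unifrac_all(counts, tree, structure = structure, which = "unweighted")$unweighted
}

#' @rdname distances
#' @export
dist_unifrac_generalized <- function(counts, tree = NULL, theta = 0.5, structure = NULL) {
  unifrac_all(counts, tree, theta = theta, structure = structure,
              which = "generalized")$generalized
}

#' @rdname distances
#' @export
dist_unifrac_weighted <- function(counts, tree = NULL, structure = NULL) {
  unifrac_all(counts, tree, structure = structure, which = "weighted")$weighted
}

#' Compute a bundle of candidate ecological distances
#'
#' Convenience wrapper returning the default candidate set used by the
#' omnibus test.
#'
#' @inheritParams distances
#' @param measures Subset of
#'   `c("jaccard", "bray_curtis", "u_unifrac", "g_unifrac", "w_unifrac")`.
#' @param structure Optional precomputed [unifrac_structure()].
#' @return Named list of distance matrices.
#' @export
ecological_distances <- function(counts,
                                 tree = NULL,
                                 measures = c("jaccard", "bray_curtis",
                                              "u_unifrac", "g_unifrac", "w_unifrac"),
                                 theta = 0.5,
                                 structure = NULL) {
  measures <- match.arg(measures, several.ok = TRUE)
  counts <- validate_counts(counts, require_positive_rows = TRUE)
  out <- list()
  cd <- c("jaccard", "bray_curtis") %in% measures
  if (any(cd)) {
    res <- count_distances_cpp(counts, cd[1], cd[2])
    if (cd[1]) out$jaccard <- dist_attr(res$jaccard, rownames(counts), "jaccard")
    if (cd[2]) out$bray_curtis <- dist_attr(res$bray, rownames(counts), "bray_curtis")
  }
  uf <- intersect(measures, c("u_unifrac", "g_unifrac", "w_unifrac"))
  if (length(uf) > 0) {
    if (is.null(tree) && is.null(structure)) {
      abort("UniFrac measures require `tree` (or a precomputed `structure`)")
    }
    which <- c(u_unifrac = "unweighted", g_unifrac = "generalized",
               w_unifrac = "weighted")[uf]
    ufd <- unifrac_all(counts, tree, theta = theta, structure = structure,
                       which = unname(which), validated = TRUE)
    if ("u_unifrac" %in% uf) out$u_unifrac <- ufd$unweighted
    if ("g_unifrac" %in% uf) out$g_unifrac <- ufd$generalized
    if ("w_unifrac" %in% uf) out$w_unifrac <- ufd$weighted
  }
  out[measures]
}
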