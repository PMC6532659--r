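#' Convert a distance matrix to a centred similarity kernel
#'
#' Gower double-centering of the element-wise squared distances,
#' `K = -(1/2) (I - 11'/N) D^2 (I - 11'/N)`, so that every row and column of
#' `K` sums to zero. For Euclidean-embeddable distances the result equals
#' the centred Gram matrix of the embedded points; non-Euclidean ecological
#' distances can produce indefinite `K`, which is repaired by clamping
#' negative eigenvalues to zero (`psd = TRUE`, the default) so the matrix is
#' a valid similarity kernel.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param psd Apply the positive-semi-definite correction ([psd_correct()])?
#' @return Symmetric N x N kernel matrix with attributes `measure` (copied
#'   from `D`) and `psd_corrected`.
#' @export
distance_kernel <- function(D, psd = TRUE) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix")
  if (anyNA(D) || any(!is.finite(D))) abort("`D` contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) abort("`D` is not symmetric")
  if (max(abs(diag(D))) > 1e-8) abort("`D` does not have a zero diagonal")
  B <- D * D
  rm <- rowMeans(B)
  K <- -0.5 * (B - outer(rm, rm, "+") + mean(B))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(D)
  attr(K, "measure") <- attr(D, "measure")
  attr(K, "psd_corrected") <- FALSE
  if (psd) K <- psd_correct(K) else K
}

#' Clamp negative eigenvalues of a symmetric matrix to zero
#'
#' @param K Symmetric matrix.
#' @param tol Relative tolerance below which negative eigenvalues are
#'   treated as numerical noise and the input is returned unchanged.
#' @return PSD matrix (smallest eigenvalue >= -tol * max |eigenvalue|), with
#'   `psd_corrected = TRUE` when a repair was applied.
#' @export
psd_correct <- function(K, tol = 1e-10) {
  if (anyNA(K) || any(!is.finite(K))) abort("`K` contains non-finite entries")
  if (max(abs(K - t(K))) > 1e-8) abort("`K` is not symmetric")
  ee <- eigen(K, symmetric = TRUE)
  lmax <- max(abs(ee$values), 1e-300)
  if (min(ee$values) >= -tol * lmax) {
    attr(K, "psd_corrected") <- attr(K, "psd_corrected") %||% FALSE
    return(K)
  }
  lam <- pmax(ee$values, 0)
  K2 <- ee$vectors %*% (lam * t(ee$vectors))
  K2 <- (K2 + t(K2)) / 2
  dimnames(K2) <- dimnames(K)
  attr(K2, "measure") <- attr(K, "measure")
  attr(K2, "psd_corrected") <- TRUE
  K2
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical scaling: eigendecomposition of the Gower-centred kernel of `D`;
#' axes are ordered by decreasing eigenvalue and axes with non-positive
#' eigenvalues are dropped.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Number of axes requested (at most N - 1); fewer are returned if
#'   fewer positive eigenvalues exist.
#' @return Object of class `glmmkat_pcoa`: a list with `points` (tibble of
#'   measurement ids and axis scores), `eigenvalues` (all N, sorted
#'   decreasing) and `prop_explained` (relative to the positive eigenvalue
#'   total).
#' @export
pcoa_scores <- function(D, k = 2) {
  N <- nrow(D)
  if (k > N - 1) abort(sprintf("`k` must be at most N - 1 = %d", N - 1))
  if (k < 1) abort("`k` must be positive")
  K <- distance_kernel(D, psd = FALSE)
  ee <- eigen(K, symmetric = TRUE)
  pos <- which(ee$values > 1e-8 * max(abs(ee$values), 1e-300))
  kk <- min(k, length(pos))
  scores <- ee$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
    diag(sqrt(ee$values[pos[seq_len(kk)]]), kk)
  colnames(scores) <- sprintf("Axis%d", seq_len(kk))
  pts <- tibble::tibble(measurement_id = rownames(D) %||% as.character(seq_len(N)))
  pts <- dplyr::bind_cols(pts, tibble::as_tibble(scores))
  structure(
    list(points = pts,
         eigenvalues = ee$values,
         prop_explained = ee$values[pos] / sum(ee$values[pos]),
         measure = attr(D, "measure")),
    class = "glmmkat_pcoa"
  )
}

#' @export
print.glmmkat_pcoa <- function(x, ...) {
  cat(sprintf("PCoA (%s): %d measurements, %d positive axes\n",
              x$measure %||% "distance", nrow(x$points), length(x$prop_explained)))
  cat(sprintf("first axes explain %s of positive inertia\n",
              paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 3)), collapse = ", ")))
  invisible(x)
}
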