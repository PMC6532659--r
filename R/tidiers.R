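#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted null GLMM
#'
#' @param x A `glmmkat_null` object.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect and variance component
#'   (`term`, `estimate`, `type`).
#' @export
tidy.glmmkat_null <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$alpha), estimate = unname(x$alpha),
                   type = "fixed"),
    tibble::tibble(term = names(x$var_comp), estimate = unname(x$var_comp),
                   type = "varcomp")
  )
}

#' @rdname tidy.glmmkat_null
#' @return For `glance`: one-row tibble of fit metadata (family, design,
#'   sizes, convergence).
#' @export
glance.glmmkat_null <- function(x, ...) {
  tibble::tibble(family = x$family, random = x$random, n_obs = x$N,
                 n_clusters = x$cluster$n,
                 sigma_g_sq = unname(x$var_comp[1]),
                 dispersion = unname(x$var_comp[length(x$var_comp)]),
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a kernel association test
#'
#' @param x A `glmmkat_test` object.
#' @param ... Unused.
#' @return Tibble with one row per kernel plus (for multi-kernel runs) an
#'   `omnibus` row carrying the min-p statistic.
#' @export
tidy.glmmkat_test <- function(x, ...) {
  out <- x$results
  if (nrow(out) > 1) {
    out <- dplyr::bind_rows(out, tibble::tibble(kernel = "omnibus",
                                                statistic = x$omnibus_stat,
                                                p.value = x$omnibus_p))
  }
  out
}

#' @rdname tidy.glmmkat_test
#' @export
glance.glmmkat_test <- function(x, ...) {
  tibble::tibble(method = x$method, family = x$family, random = x$random,
                 n_obs = x$N, n_clusters = x$n_clusters, B = x$B,
                 n_kernels = nrow(x$results),
                 omnibus_p = if (nrow(x$results) > 1) x$omnibus_p else x$results$p.value[1])
}

#' Plot methods
#'
#' `autoplot()` for PCoA objects draws the first two principal coordinate
#' axes (optionally coloured by a grouping vector); for test objects it
#' shows the per-kernel p-values on a -log10 scale with the omnibus value
#' marked.
#'
#' @param object A `glmmkat_pcoa` or `glmmkat_test` object.
#' @param colour Optional grouping vector (length N) for the PCoA plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.glmmkat_pcoa <- function(object, colour = NULL, ...) {
  df <- object$points
  if (ncol(df) < 3) abort("PCoA has fewer than 2 axes; request k >= 2")
  if (!is.null(colour)) df$group <- colour
  pe <- 100 * object$prop_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", pe[1]),
                  y = sprintf("Axis 2 (%.1f%%)", pe[2]),
                  title = object$measure %||% "PCoA") +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @rdname autoplot.glmmkat_pcoa
#' @export
autoplot.glmmkat_test <- function(object, ...) {
  df <- tidy(object)
  df$kernel <- factor(df$kernel, levels = df$kernel)
  ggplot2::ggplot(df, ggplot2::aes(.data$kernel, -log10(.data$p.value))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = sprintf("Kernel association test (B = %d)", object$B)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' @export
ggplot2::autoplot
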