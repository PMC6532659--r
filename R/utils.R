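#' @importFrom rlang %||% abort warn
#' @importFrom stats rnorm rbinom rpois rgamma rmultinom runif optim optimize
#'   plogis model.matrix setNames sd var cor quantile
#' @importFrom Rcpp sourceCpp
#' @useDynLib glmmkat, .registration = TRUE
NULL

# standardize to mean 0, sd 1; errors on degenerate input because downstream
# simulation equations divide by the sd
scale_vec <- function(x, what = "x") {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) {
    abort(sprintf("cannot standardize `%s`: zero or non-finite variance", what))
  }
  (x - mean(x)) / s
}

# run `code` under a fixed seed without disturbing the caller's RNG stream;
# used for frozen fixtures only
with_isolated_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# package-local cache for memoized fixtures (community profile, PAM partition,
# UniFrac edge structures)
.glmmkat_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!exists(key, envir = .glmmkat_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .glmmkat_cache)
  }
  get(key, envir = .glmmkat_cache, inherits = FALSE)
}

# cluster labels -> integer index in order of first appearance, with the
# contiguity check every block-structured computation relies on
cluster_index <- function(cluster) {
  f <- factor(cluster, levels = unique(cluster))
  gi <- as.integer(f)
  if (any(diff(gi) < 0) || !all(tapply(seq_along(gi), gi, function(ix) all(diff(ix) == 1)))) {
    abort("measurements must be ordered so that each cluster occupies a contiguous block of rows")
  }
  list(index = gi, labels = levels(f), n = nlevels(f), sizes = as.integer(table(gi)))
}
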