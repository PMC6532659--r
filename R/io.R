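#' Validate an OTU count matrix
#'
#' Checks the container contract used throughout the package: a numeric
#' matrix of non-negative counts with measurements in rows and OTUs in
#' columns, unique row (measurement) and column (OTU) identifiers, and —
#' optionally — strictly positive row totals (required before any distance
#' computation).
#'
#' @param counts Numeric matrix, measurements x OTUs.
#' @param require_positive_rows Require every row total to be positive?
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_counts <- function(counts, require_positive_rows = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (measurements x OTUs)")
  }
  if (anyNA(counts) || any(!is.finite(counts))) abort("`counts` contains missing or non-finite values")
  if (any(counts < 0)) abort("`counts` contains negative values")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("M%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("OTU%d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) abort("duplicated measurement identifiers in `counts`")
  if (anyDuplicated(colnames(counts))) abort("duplicated OTU identifiers in `counts`")
  if (require_positive_rows) {
    z <- rowSums(counts) <= 0
    if (any(z)) {
      abort(sprintf(
        "measurement(s) with zero total count: %s",
        paste(rownames(counts)[z], collapse = ", ")
      ))
    }
  }
  counts
}

#' Read an OTU count table from delimited text
#'
#' Expects a header row of OTU identifiers and a first column of measurement
#' identifiers (use `otus_in_rows = TRUE` for the transposed dialect). The
#' delimiter is inferred from the file extension (`.csv` means comma,
#' anything else tab).
#'
#' @param path File path.
#' @param otus_in_rows Set to `TRUE` when rows are OTUs and columns are
#'   measurements.
#' @param sep Field delimiter; inferred from the extension when `NULL`.
#' @return Integer count matrix, measurements x OTUs.
#' @export
read_otu_counts <- function(path, otus_in_rows = FALSE, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (otus_in_rows) m <- t(m)
  validate_counts(m)
}

#' Write an OTU count table (or any labelled matrix) to delimited text
#'
#' @param counts Matrix with row and column names.
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @param id_column Header used for the identifier column.
#' @export
write_otu_counts <- function(counts, path, id_column = "measurement_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-measurement metadata from delimited text
#'
#' @param path File path (header row of named columns: trait, covariates,
#'   cluster identifier, optional time point).
#' @param sep Field delimiter; inferred from extension when `NULL`.
#' @return A tibble, one row per measurement.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      check.names = FALSE, comment.char = ""))
}

#' Read a rooted phylogenetic tree in Newick format
#'
#' The tree must be rooted and carry branch lengths; leaf labels must cover
#' the OTU identifiers used by any UniFrac computation.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_phylo_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths; UniFrac requires them")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort("tree branch lengths must be finite and non-negative")
  }
  if (!ape::is.rooted(tree)) {
    abort("tree is unrooted; root it first (e.g. ape::root() with an outgroup or midpoint rooting). UniFrac is defined here on a rooted tree.")
  }
  if (anyDuplicated(tree$tip.label)) abort("duplicated leaf labels in tree")
  tree
}

#' Round-trip a distance or kernel matrix through delimited text
#'
#' Measurement identifiers are written both as the header row and the first
#' column.
#'
#' @param m Square labelled matrix.
#' @param path Output path.
#' @export
write_square_matrix <- function(m, path) {
  write_otu_counts(m, path, id_column = "measurement_id")
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}
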