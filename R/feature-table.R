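#' Build a feature table
#'
#' A feature table holds nonnegative abundances of microbial features (OTUs or
#' KOs) for a set of samples. It is an ordinary tibble whose first column is
#' `sample_id` and whose remaining columns are numeric feature abundances, with
#' two attributes: `kind` ("otu" or "ko") and `normalization` ("counts" or
#' "relative"). All pipeline stages accept and return this shape, so tables
#' compose with dplyr verbs.
#'
#' @param x A data frame with a `sample_id` column and numeric feature columns,
#'   or a numeric matrix (samples in rows, features in columns, dimnames set).
#' @param kind Feature role, `"otu"` or `"ko"`.
#' @param normalization `"counts"` for raw abundances, `"relative"` for
#'   per-sample proportions (rows must then sum to 1).
#' @return A `feature_table` tibble.
#' @export
#' @examples
#' m <- matrix(c(4, 6, 0, 10), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' feature_table(m, kind = "otu")
feature_table <- function(x, kind = c("otu", "ko"),
                          normalization = c("counts", "relative")) {
  kind <- match.arg(kind)
  normalization <- match.arg(normalization)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop("matrix input needs sample row names and feature column names")
    }
    if (anyDuplicated(colnames(x))) stop("duplicate feature ids")
    if (anyDuplicated(rownames(x))) stop("duplicate sample ids")
    x <- tibble::as_tibble(as.data.frame(x), rownames = "sample_id")
  }
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    stop("feature table needs a 'sample_id' column")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  feats <- setdiff(names(x), "sample_id")
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(feats)) stop("duplicate feature ids")
  vals <- as.matrix(x[feats])
  if (!is.numeric(vals)) stop("feature columns must be numeric")
  if (anyNA(vals)) stop("missing abundances are not allowed")
  if (any(vals < 0)) stop("negative abundances are not allowed")
  if (normalization == "relative") {
    rs <- rowSums(vals)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("normalization = 'relative' requires each sample row to sum to 1")
    }
  }
  structure(x,
    class = c("feature_table", class(tibble::tibble())),
    kind = kind, normalization = normalization
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "# feature_table: %d samples x %d %s features (%s)\n",
    nrow(x), ncol(x) - 1L, attr(x, "kind"), attr(x, "normalization")
  ))
  NextMethod()
}

#' Feature ids, sample ids and the abundance matrix of a table
#'
#' @param table A [feature_table()].
#' @return `ft_features()` and `ft_samples()` return character vectors;
#'   `ft_matrix()` the numeric samples-by-features matrix.
#' @export
ft_matrix <- function(table) {
  m <- as.matrix(table[setdiff(names(table), "sample_id")])
  rownames(m) <- table$sample_id
  m
}

#' @rdname ft_matrix
#' @export
ft_features <- function(table) setdiff(names(table), "sample_id")

#' @rdname ft_matrix
#' @export
ft_samples <- function(table) table$sample_id

#' @rdname ft_matrix
#' @export
ft_kind <- function(table) attr(table, "kind") %||% "otu"

#' @rdname ft_matrix
#' @export
ft_normalization <- function(table) attr(table, "normalization") %||% "counts"

# rebuild a feature_table from a matrix, inheriting role tags; a "relative"
# tag is dropped when the subset no longer sums to 1
ft_rebuild <- function(m, template, normalization = NULL) {
  norm <- normalization %||% ft_normalization(template)
  if (norm == "relative" && nrow(m) > 0 &&
        any(abs(rowSums(m) - 1) > 1e-9)) {
    norm <- "counts"
  }
  feature_table(m, kind = ft_kind(template), normalization = norm)
}

#' Convert abundances to per-sample relative abundances
#'
#' Divides each sample row by its total so rows sum to 1. Idempotent.
#'
#' @param table A [feature_table()].
#' @return A relative-abundance `feature_table`.
#' @export
#' @examples
#' m <- matrix(c(2, 1, 2, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b")))
#' normalize_relative(feature_table(m))
normalize_relative <- function(table) {
  m <- ft_matrix(table)
  totals <- rowSums(m)
  bad <- rownames(m)[totals <= 0]
  if (length(bad) > 0) {
    stop("cannot normalize all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  ft_rebuild(m / totals, table, normalization = "relative")
}

#' Drop features by sample occurrence
#'
#' Keeps features that have nonzero abundance in at least `min_samples`
#' samples. The network and marker stages apply this with the default
#' `min_occurrence = 6`, i.e. features present in strictly more than five
#' samples.
#'
#' @param table A [feature_table()].
#' @param min_samples Minimum number of samples with nonzero abundance.
#' @return The filtered `feature_table`; feature order is preserved.
#' @export
filter_occurrence <- function(table, min_samples = 6) {
  stopifnot(min_samples >= 0)
  m <- ft_matrix(table)
  keep <- colSums(m > 0) >= min_samples
  ft_rebuild(m[, keep, drop = FALSE], table)
}
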