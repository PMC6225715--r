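new_ordination <- function(sample_ids, coordinates, eigenvalues,
                           proportion, method) {
  colnames(coordinates) <- paste0("axis", seq_len(ncol(coordinates)))
  rownames(coordinates) <- sample_ids
  structure(
    list(
      sample_ids = sample_ids, coordinates = coordinates,
      eigenvalues = eigenvalues, proportion_explained = proportion,
      method = method
    ),
    class = "ordination"
  )
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of -d^2/2 followed by an
#' eigendecomposition (via [ape::pcoa()]). Axes are ordered by decreasing
#' eigenvalue. Negative eigenvalues, which arise for semi-metric distances,
#' are kept in `eigenvalues` but excluded from the coordinates and from the
#' proportion-explained denominator.
#'
#' @param dist A `dist_matrix` (or symmetric matrix) of sample dissimilarities.
#' @return An `ordination` object with `coordinates`, `eigenvalues` and
#'   `proportion_explained`; see [tidy.ordination()].
#' @export
pcoa <- function(dist) {
  m <- as.matrix(dist)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  tol <- 1e-10 * max(1, max(abs(m)))
  if (all(abs(m) <= tol)) {
    coords <- matrix(0, nrow(m), 1)
    return(new_ordination(ids, coords, numeric(nrow(m)),
                          numeric(1), "pcoa"))
  }
  fit <- ape::pcoa(stats::as.dist(m))
  eig <- fit$values$Eigenvalues
  pos <- which(eig > tol)
  coords <- as.matrix(fit$vectors)[, seq_along(pos), drop = FALSE]
  prop <- eig[pos] / sum(eig[pos])
  new_ordination(ids, coords, eig, prop, "pcoa")
}

#' Principal component analysis of a feature table
#'
#' Centered (unscaled) PCA of the sample-by-feature matrix via [stats::prcomp].
#' Intended for KO relative-abundance tables; set `log10_transform = TRUE` to
#' work on log10(x + pseudocount).
#'
#' @param table A [feature_table()].
#' @param log10_transform Log-transform abundances first?
#' @param pseudocount Added before the log transform.
#' @return An `ordination` object; eigenvalues are the component variances.
#' @export
pca <- function(table, log10_transform = FALSE, pseudocount = 1e-6) {
  m <- ft_matrix(table)
  if (log10_transform) m <- log10(m + pseudocount)
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  total <- sum(eig)
  prop <- if (total > 0) eig / total else rep(0, length(eig))
  new_ordination(rownames(m), fit$x, eig, prop, "pca")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf(
    "# ordination (%s): %d samples, %d axes; first axes explain %s\n",
    x$method, length(x$sample_ids), ncol(x$coordinates),
    paste0(round(100 * utils::head(x$proportion_explained, 2), 1), "%",
           collapse = ", ")
  ))
  invisible(x)
}

#' Tidy an ordination
#'
#' `tidy()` returns one row per sample with axis coordinates; `glance()` one
#' row with the variance explained by the first two axes.
#'
#' @param x,object An `ordination` object.
#' @param ... Ignored.
#' @export
tidy.ordination <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids),
    tibble::as_tibble(x$coordinates)
  )
}

#' @rdname tidy.ordination
#' @export
glance.ordination <- function(x, ...) {
  p <- x$proportion_explained
  tibble::tibble(
    method = x$method,
    n_samples = length(x$sample_ids),
    n_axes = ncol(x$coordinates),
    prop_axis1 = if (length(p) >= 1) p[1] else NA_real_,
    prop_axis2 = if (length(p) >= 2) p[2] else NA_real_
  )
}

#' @rdname tidy.ordination
#' @param metadata Optional metadata tibble joined on `sample_id`.
#' @export
autoplot.ordination <- function(object, metadata = NULL, ...) {
  df <- tidy(object)
  if (ncol(df) < 3) df$axis2 <- 0
  lab <- function(i) {
    p <- object$proportion_explained
    if (length(p) >= i) sprintf("axis %d (%.1f%%)", i, 100 * p[i])
    else sprintf("axis %d", i)
  }
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, validate_metadata(metadata), by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                     colour = .data$group,
                                     shape = .data$host)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = lab(1), y = lab(2))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = lab(1), y = lab(2))
  }
}
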