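#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way pseudo-F test on a distance matrix. With squared distances d2,
#' `SS_total = sum over pairs d2 / N` and `SS_within = sum over groups of
#' (within-pair d2 sum) / n_g`; `F = (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value comes from label shuffling:
#' `p = (count(F_perm >= F_obs) + 1) / (n_permutations + 1)`. With
#' `exhaustive = TRUE` (two groups only) all distinct label splits are
#' enumerated instead and `p = count(F >= F_obs) / n_splits`, the identity
#' split included.
#'
#' @param dist A `dist_matrix` or symmetric matrix.
#' @param groups Group label per sample (character/factor), in matrix order,
#'   or a metadata tibble with `sample_id` and `group` columns.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param exhaustive Enumerate all label splits (two groups only).
#' @return A `permanova` object with fields `F`, `p`, `n_permutations`,
#'   `df_between`, `df_within`; see [tidy.permanova()].
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  m <- as.matrix(dist)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  if (is.data.frame(groups)) {
    md <- validate_metadata(groups)
    groups <- md$group[match(rownames(m), md$sample_id)]
    if (anyNA(groups)) stop("metadata does not cover all samples")
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("each group needs at least two samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d2 <- m^2
  f_obs <- pseudo_f(d2, groups)
  if (exhaustive) {
    if (length(sizes) != 2) stop("exhaustive enumeration supports two groups")
    labs <- names(sizes)
    n <- length(groups)
    picks <- combn(n, sizes[[1]])
    f_all <- apply(picks, 2, function(ix) {
      g <- rep(labs[2], n)
      g[ix] <- labs[1]
      pseudo_f(d2, g)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm <- ncol(picks)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      if (pseudo_f(d2, sample(groups)) >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  structure(
    list(
      F = f_obs, p = p, n_permutations = n_perm, seed = seed,
      df_between = length(sizes) - 1L,
      df_within = length(groups) - length(sizes),
      exhaustive = exhaustive
    ),
    class = "permanova"
  )
}

# pseudo-F from a squared-distance matrix and labels; returns 0 when both
# sums of squares vanish (all points coincide)
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    sub <- d2[ix, ix, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
  }
  a <- length(unique(groups))
  ss_between <- ss_total - ss_within
  if (ss_within <= 0) {
    return(if (ss_between <= 0) 0 else Inf)
  }
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: F = %.3f, p = %.4g (%s, df = %d, %d)\n",
    x$F, x$p,
    if (x$exhaustive) sprintf("%d exhaustive splits", x$n_permutations)
    else sprintf("%d permutations", x$n_permutations),
    x$df_between, x$df_within
  ))
  invisible(x)
}

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova` object.
#' @param ... Ignored.
#' @return `tidy()`/`glance()` return a one-row tibble with the pseudo-F,
#'   p-value, degrees of freedom and permutation count.
#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, p.value = x$p,
    df_between = x$df_between, df_within = x$df_within,
    n_permutations = x$n_permutations
  )
}

#' @rdname tidy.permanova
#' @export
glance.permanova <- function(x, ...) tidy(x)

#' Procrustes concordance of two ordinations with Monte-Carlo test
#'
#' Superimposes the first `n_axes` coordinates of two ordinations of the same
#' samples by translation, rotation/reflection and scaling, after scaling both
#' configurations to unit trace. The statistic is the minimized residual sum
#' of squares `M2 = 1 - (sum of singular values)^2`; small values mean
#' concordant ordinations. Significance comes from a Monte-Carlo test that
#' permutes the sample rows of the second configuration.
#'
#' @param ord_a,ord_b `ordination` objects (or coordinate matrices) over the
#'   same samples, in the same order.
#' @param n_axes Number of leading axes to compare (default 2).
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed Optional integer seed.
#' @return A list with `m2`, `p` and `n_permutations`.
#' @export
procrustes_mc <- function(ord_a, ord_b, n_axes = 2, n_permutations = 999,
                          seed = NULL) {
  xa <- procrustes_coords(ord_a, n_axes)
  xb <- procrustes_coords(ord_b, n_axes)
  if (nrow(xa) != nrow(xb)) stop("ordinations must share their samples")
  if (nrow(xa) < 3) stop("need at least three samples")
  m2_obs <- procrustes_m2(xa, xb)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    if (procrustes_m2(xa, xb[sample(nrow(xb)), , drop = FALSE]) <=
          m2_obs + 1e-12) {
      hits <- hits + 1L
    }
  }
  list(m2 = m2_obs, p = (hits + 1) / (n_permutations + 1),
       n_permutations = n_permutations)
}

procrustes_coords <- function(ord, n_axes) {
  x <- if (inherits(ord, "ordination")) ord$coordinates else as.matrix(ord)
  if (ncol(x) < n_axes) {
    x <- cbind(x, matrix(0, nrow(x), n_axes - ncol(x)))
  }
  x[, seq_len(n_axes), drop = FALSE]
}

# symmetric Procrustes residual: configurations centered and scaled to unit
# trace, then M2 = 1 - (sum of singular values of X'Y)^2
procrustes_m2 <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("degenerate configuration (all points equal)")
  xc <- xc / sx
  yc <- yc / sy
  d <- svd(crossprod(xc, yc))$d
  max(0, 1 - sum(d)^2)
}
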