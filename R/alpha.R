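#' Shannon diversity of one abundance vector
#'
#' H = -sum(p_i * log(p_i, base)) over the nonzero proportions p_i. Reported in
#' nats by default; pass `base = 2` for bits.
#'
#' @param abundances Nonnegative abundance vector with positive sum.
#' @param base Logarithm base (default `exp(1)`).
#' @return The Shannon index.
#' @export
shannon <- function(abundances, base = exp(1)) {
  p <- check_abundances(abundances)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Gini-Simpson diversity of one abundance vector
#'
#' 1 - sum(p_i^2): the probability that two random draws are different taxa.
#'
#' @inheritParams shannon
#' @return The Gini-Simpson index, in \[0, 1\].
#' @export
simpson <- function(abundances) {
  p <- check_abundances(abundances)
  1 - sum(p^2)
}

#' Bias-corrected Chao1 richness of one count vector
#'
#' S_obs + F1 * (F1 - 1) / (2 * (F2 + 1)) with F1 the number of singletons and
#' F2 the number of doubletons; requires integer counts.
#'
#' @param counts Nonnegative integer count vector.
#' @return The Chao1 richness estimate (>= observed richness).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1 requires integer counts")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

check_abundances <- function(abundances) {
  if (any(abundances < 0)) stop("negative abundances")
  total <- sum(abundances)
  if (total <= 0) stop("abundance vector sums to zero")
  abundances / total
}

#' Per-sample alpha diversity
#'
#' Computes, for every sample of a count table, the observed feature number,
#' Shannon index (nats by default), Gini-Simpson index and bias-corrected
#' Chao1 estimate. Counts are used as given (no rarefaction).
#'
#' @param table A [feature_table()] of counts.
#' @param base Logarithm base for the Shannon index.
#' @return A tibble with columns `sample_id`, `observed`, `shannon`,
#'   `simpson`, `chao1`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- ft_matrix(table)
  out <- tibble::tibble(
    sample_id = rownames(m),
    observed = as.integer(rowSums(m > 0)),
    shannon = unname(apply(m, 1, shannon, base = base)),
    simpson = unname(apply(m, 1, simpson)),
    chao1 = unname(apply(m, 1, chao1))
  )
  class(out) <- c("alpha_diversity", class(out))
  out
}

#' @export
#' @rdname alpha_diversity
#' @param object,x An `alpha_diversity` tibble.
#' @param metadata Optional metadata tibble joined on `sample_id` for grouping.
#' @param ... Ignored.
autoplot.alpha_diversity <- function(object, metadata = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"sample_id",
                              names_to = "index", values_to = "value")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, validate_metadata(metadata), by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value,
                                            fill = .data$group)) +
      ggplot2::geom_boxplot(outlier.size = 0.6)
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$value)) +
      ggplot2::geom_col() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  }
  p + ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "alpha diversity")
}
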