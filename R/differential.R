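#' Wilcoxon rank-sum p-value
#'
#' Wraps [stats::wilcox.test()] with the conventions used throughout the
#' pipeline: the exact null distribution when the pooled size is at most 12
#' and there are no ties, otherwise the normal approximation with mid-ranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric observation vectors for the two groups.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return The p-value.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less") # 1/choose(6,3) = 0.05
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) stop("both groups must be nonempty")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  exact <- !anyDuplicated(c(x, y)) && (length(x) + length(y) <= 12)
  suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE)
  )$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]: the adjusted value of the
#' i-th smallest p is `min over j >= i of p_(j) * m / j`, capped at 1, with
#' the original order restored.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) p.adjust(pvals, method = "BH")

#' Threshold profiles for marker discovery
#'
#' The study mixes selection rules by analysis: OTU markers at adjusted
#' p < 0.01, KO markers at unadjusted p < 0.05, network inputs at q < 0.01,
#' and a global q < 0.1 default. Profiles make the choice explicit.
#'
#' @param name One of `"paper-otu"`, `"paper-ko"`, `"paper-network"`,
#'   `"default"`.
#' @return A list with `alpha` and `use_adjusted`.
#' @export
marker_profile <- function(name = c("default", "paper-otu", "paper-ko",
                                    "paper-network")) {
  switch(match.arg(name),
    `default` = list(alpha = 0.1, use_adjusted = TRUE),
    `paper-otu` = list(alpha = 0.01, use_adjusted = TRUE),
    `paper-ko` = list(alpha = 0.05, use_adjusted = FALSE),
    `paper-network` = list(alpha = 0.01, use_adjusted = TRUE)
  )
}

#' Two-group differential feature discovery
#'
#' Occurrence-filters the table, relative-normalizes it (unless already
#' relative or `normalize = FALSE`), runs a per-feature two-sided Wilcoxon
#' rank-sum test between the two groups, BH-adjusts over all tested features
#' and annotates direction and effect. One-sided p-values in both directions
#' are kept alongside for the enrichment stage. All tested features are
#' returned; `significant` flags those passing the configured threshold, so
#' `dplyr::filter(res, significant)` gives the marker list.
#'
#' @param table A [feature_table()].
#' @param metadata Metadata tibble (`sample_id`, `group`, `host`).
#' @param group_a Reference group label (default `"H"`).
#' @param group_b Contrast group label (default `"M"`); directions are
#'   reported relative to this group (`up_in_M` / `down_in_M`).
#' @param min_occurrence Occurrence filter threshold (default 6 samples,
#'   computed over the selected samples).
#' @param alpha Significance threshold.
#' @param use_adjusted Apply `alpha` to BH q-values (`TRUE`) or raw p-values.
#' @param normalize Relative-normalize before testing (default `TRUE`).
#' @param pseudocount Pseudocount for the log2 abundance ratio.
#' @return A tibble with one row per tested feature: `feature_id`, `p`, `q`,
#'   `p_up`, `p_down`, `direction`, `effect` (difference of group mean
#'   relative abundances, group_b minus group_a), `log2_ratio`, `prevalence`,
#'   `significant`.
#' @export
find_markers <- function(table, metadata, group_a = "H", group_b = "M",
                         min_occurrence = 6, alpha = 0.1,
                         use_adjusted = TRUE, normalize = TRUE,
                         pseudocount = 1e-6) {
  md <- match_metadata(table, metadata)
  keep <- md$group %in% c(group_a, group_b)
  if (sum(md$group == group_a) < 2 || sum(md$group == group_b) < 2) {
    stop("each group needs at least two samples")
  }
  sub <- ft_rebuild(ft_matrix(table)[keep, , drop = FALSE], table)
  grp <- md$group[keep]
  sub <- filter_occurrence(sub, min_occurrence)
  m <- ft_matrix(sub)
  if (normalize && ft_normalization(sub) != "relative") {
    m <- m / rowSums(m)
  }
  in_a <- grp == group_a
  in_b <- grp == group_b
  res <- purrr::map_dfr(colnames(m), function(f) {
    xa <- m[in_a, f]
    xb <- m[in_b, f]
    tibble::tibble(
      feature_id = f,
      p = wilcoxon_rank_sum(xb, xa, "two_sided"),
      p_up = wilcoxon_rank_sum(xb, xa, "greater"),
      p_down = wilcoxon_rank_sum(xb, xa, "less"),
      effect = mean(xb) - mean(xa),
      log2_ratio = log2((mean(xb) + pseudocount) / (mean(xa) + pseudocount)),
      prevalence = sum(m[, f] > 0)
    )
  })
  if (nrow(res) == 0) {
    res$q <- numeric(0)
    res$direction <- character(0)
    res$significant <- logical(0)
    return(res)
  }
  res$q <- bh_adjust(res$p)
  # zero effects break the tie with the one-sided p-values
  up <- res$effect > 0 | (res$effect == 0 & res$p_up <= res$p_down)
  res$direction <- ifelse(up, paste0("up_in_", group_b),
                          paste0("down_in_", group_b))
  res$significant <- if (use_adjusted) res$q < alpha else res$p < alpha
  res[c("feature_id", "p", "q", "p_up", "p_down", "direction", "effect",
        "log2_ratio", "prevalence", "significant")]
}
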