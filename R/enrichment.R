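#' Inverse-normal z-transform of a p-value
#'
#' `z = qnorm(1 - p)`: small p-values map to large positive z. Values outside
#' (0, 1) are clamped to \[1e-15, 1 - 1e-15\] with a warning.
#'
#' @param p P-value(s) in (0, 1).
#' @return z score(s).
#' @export
ko_z <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    warning("p-values outside (0,1) clamped")
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  }
  qnorm(1 - p)
}

#' Aggregate member z scores into a pathway reporter score
#'
#' `Z = sum(z) / sqrt(k)` for the k tested KOs of a pathway.
#'
#' @param z_list Numeric vector of KO z scores.
#' @return The raw pathway reporter score.
#' @export
pathway_z <- function(z_list) {
  k <- length(z_list)
  if (k == 0) stop("no z scores to aggregate")
  sum(z_list) / sqrt(k)
}

#' Background-correct a raw pathway score
#'
#' Draws `n_draws` random size-k KO sets from the pool of all tested KO
#' z scores, computes their [pathway_z()] values, and standardizes the raw
#' score against that null: `z_adj = (z_raw - mean) / sd`.
#'
#' @param z_raw Raw pathway score.
#' @param k Number of tested KOs in the pathway.
#' @param z_pool z scores of all tested KOs (length >= k).
#' @param n_draws Number of random sets (default 1000).
#' @param seed Optional integer seed.
#' @return The background-corrected score.
#' @export
background_correct <- function(z_raw, k, z_pool, n_draws = 1000, seed = NULL) {
  if (length(z_pool) < k) stop("background pool smaller than pathway")
  if (!is.null(seed)) set.seed(seed)
  null_z <- replicate(n_draws, sum(sample(z_pool, k))) / sqrt(k)
  s <- sd(null_z)
  if (!is.finite(s) || s == 0) {
    stop("degenerate background pool (zero variance)")
  }
  (z_raw - mean(null_z)) / s
}

#' Pathway direction from up/down KO counts
#'
#' A pathway counts as upregulated only when the number of upregulated KOs is
#' at least 10% more than the number of downregulated ones (`n_up >=
#' 1.1 * n_down`), and vice versa; otherwise it is `"mixed"`. Exact real
#' comparison, no rounding.
#'
#' @param n_up,n_down Counts of significantly up- and downregulated KOs.
#' @return `"up"`, `"down"` or `"mixed"`.
#' @export
classify_direction <- function(n_up, n_down) {
  up_ok <- n_up >= 1.1 * n_down
  down_ok <- n_down >= 1.1 * n_up
  if (up_ok && !down_ok) "up" else if (down_ok && !up_ok) "down" else "mixed"
}

#' Reporter-score pathway enrichment
#'
#' Aggregates per-KO differential statistics (from [find_markers()] on a KO
#' table) to pathways. For each pathway with at least one tested member KO,
#' the two-sided KO p-values are z-transformed ([ko_z()]), summed into a raw
#' reporter score ([pathway_z()]) and background-corrected against random KO
#' sets of the same size drawn from all tested KOs. A pathway is called
#' significant when `z_adj > z_threshold` (default 1.6, the one-decimal
#' rounding of the standard-normal 90%-confidence quantile). Direction comes
#' from the one-sided KO tests at `wilcoxon_alpha` and the 10% majority rule
#' of [classify_direction()].
#'
#' @param marker_kos Tibble from [find_markers()] on a KO table (all tested
#'   KOs, not only significant ones).
#' @param pathway_map Tibble with `ko`, `pathway` (and optional
#'   `pathway_name`) columns.
#' @param z_threshold Detection threshold on the corrected score.
#' @param wilcoxon_alpha One-sided significance level for direction counts.
#' @param n_draws Background sets per pathway.
#' @param seed Optional integer seed for the background draws.
#' @return A tibble with one row per pathway holding `pathway`,
#'   `pathway_name`, `k`, `z_raw`, `z_adj`, `n_up`, `n_down`, `direction`,
#'   `fraction_label` (`"n_changed/k"`) and `significant`.
#' @export
enrich <- function(marker_kos, pathway_map, z_threshold = 1.6,
                   wilcoxon_alpha = 0.05, n_draws = 1000, seed = NULL) {
  if (!all(c("feature_id", "p", "p_up", "p_down") %in% names(marker_kos))) {
    stop("marker_kos must come from find_markers() on a KO table")
  }
  if (!"pathway_name" %in% names(pathway_map)) {
    pathway_map$pathway_name <- pathway_map$pathway
  }
  kos <- marker_kos
  kos$z <- ko_z(pmin(pmax(kos$p, 1e-15), 1 - 1e-15))
  kos$up_sig <- kos$p_up < wilcoxon_alpha
  kos$down_sig <- kos$p_down < wilcoxon_alpha
  joined <- dplyr::inner_join(pathway_map, kos, by = c(ko = "feature_id"))
  if (nrow(joined) == 0) return(empty_pathway_scores())
  if (!is.null(seed)) set.seed(seed)
  pool <- kos$z
  out <- joined |>
    dplyr::group_by(.data$pathway, .data$pathway_name) |>
    dplyr::summarise(
      k = dplyr::n(),
      z_raw = pathway_z(.data$z),
      n_up = sum(.data$up_sig),
      n_down = sum(.data$down_sig),
      .groups = "drop"
    )
  out$z_adj <- purrr::pmap_dbl(out[c("z_raw", "k")], function(z_raw, k) {
    background_correct(z_raw, k, pool, n_draws = n_draws)
  })
  out$direction <- purrr::map2_chr(out$n_up, out$n_down, classify_direction)
  out$fraction_label <- paste0(out$n_up + out$n_down, "/", out$k)
  out$significant <- out$z_adj > z_threshold
  dplyr::arrange(
    out[c("pathway", "pathway_name", "k", "z_raw", "z_adj", "n_up", "n_down",
          "direction", "fraction_label", "significant")],
    dplyr::desc(.data$z_adj)
  )
}

empty_pathway_scores <- function() {
  tibble::tibble(
    pathway = character(), pathway_name = character(), k = integer(),
    z_raw = numeric(), z_adj = numeric(), n_up = integer(),
    n_down = integer(), direction = character(),
    fraction_label = character(), significant = logical()
  )
}
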