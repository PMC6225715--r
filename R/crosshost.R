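#' Mean between-group distance
#'
#' Arithmetic mean of d(i, j) over all pairs with i in `group_a` and j in
#' `group_b`. The within-group pairs are deliberately excluded: the statistic
#' is the scalar "averaged distance between groups" used by the
#' amplification-effect comparison.
#'
#' @param dist A `dist_matrix` or symmetric matrix with sample dimnames.
#' @param metadata Metadata tibble (`sample_id`, `group`, `host`).
#' @param group_a,group_b Two distinct group labels.
#' @return The mean between-group distance.
#' @export
mean_between_group_distance <- function(dist, metadata, group_a, group_b) {
  if (identical(group_a, group_b)) {
    stop("group_a and group_b must differ (between-group distance only)")
  }
  m <- as.matrix(dist)
  md <- validate_metadata(metadata)
  ids_a <- intersect(rownames(m), md$sample_id[md$group == group_a])
  ids_b <- intersect(rownames(m), md$sample_id[md$group == group_b])
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    stop("empty group in distance matrix")
  }
  mean(m[ids_a, ids_b, drop = FALSE])
}

#' Donor-to-recipient amplification factor
#'
#' Ratio of the recipient hosts' mean between-group (healthy vs diseased)
#' distance to the donor hosts' one. A value above 1 means the transplant
#' amplified the disease-health divergence of the microbiota.
#'
#' @param donor_mean,recipient_mean Mean between-group distances (> 0 for the
#'   donor).
#' @return `recipient_mean / donor_mean`.
#' @export
#' @examples
#' amplification_factor(0.104, 0.312) # 3-fold
amplification_factor <- function(donor_mean, recipient_mean) {
  if (donor_mean <= 0) stop("donor mean distance must be positive")
  recipient_mean / donor_mean
}

#' Format a fold value the way headline results print it
#'
#' Round-half-up to integer (22.88 -> 23).
#'
#' @param fold Numeric fold value.
#' @return Integer-rounded fold.
#' @export
fold_label <- function(fold) floor(fold + 0.5)

#' Shared features between donor and recipient communities
#'
#' For each group present in both hosts, measures how much of the recipient
#' community is attributable to taxa that occur in the matching donor group:
#' both as the fraction of recipient mean relative abundance on shared taxa
#' (abundance mode) and as the fraction of recipient feature count (count
#' mode). At `rank = "otu"` sharing means exact feature-id match; at genus or
#' family level features are first mapped through the taxonomy (unclassified
#' tokens are per-OTU and never match across hosts).
#'
#' @param donor_table,recipient_table [feature_table()]s of the two hosts.
#' @param donor_metadata,recipient_metadata Matching metadata tibbles.
#' @param taxonomy Taxonomy tibble (required for genus/family ranks). For
#'   rank aggregation both hosts' feature ids must appear in it.
#' @param rank `"otu"`, `"genus"` or `"family"`.
#' @param groups Group pairings to report (default the groups present in
#'   both hosts).
#' @return A tibble with columns `rank`, `group`, `shared_fraction_abundance`,
#'   `shared_fraction_count`, `n_shared`, `n_recipient`.
#' @export
shared_features <- function(donor_table, recipient_table,
                            donor_metadata, recipient_metadata,
                            taxonomy = NULL, rank = c("otu", "genus", "family"),
                            groups = NULL) {
  rank <- match.arg(rank)
  dm <- match_metadata(donor_table, donor_metadata)
  rm_ <- match_metadata(recipient_table, recipient_metadata)
  if (is.null(groups)) groups <- intersect(unique(dm$group), unique(rm_$group))
  taxon_of <- rank_mapper(taxonomy, rank)
  d_rel <- ft_matrix(normalize_relative(donor_table))
  r_rel <- ft_matrix(normalize_relative(recipient_table))
  purrr::map_dfr(groups, function(g) {
    d_mean <- colMeans(d_rel[dm$group == g, , drop = FALSE])
    r_mean <- colMeans(r_rel[rm_$group == g, , drop = FALSE])
    donor_taxa <- unique(taxon_of(names(d_mean)[d_mean > 0]))
    r_present <- r_mean[r_mean > 0]
    r_taxa <- taxon_of(names(r_present))
    shared <- r_taxa %in% donor_taxa
    tibble::tibble(
      rank = rank, group = g,
      shared_fraction_abundance = sum(r_present[shared]) / sum(r_present),
      shared_fraction_count =
        length(unique(r_taxa[shared])) / length(unique(r_taxa)),
      n_shared = length(unique(r_taxa[shared])),
      n_recipient = length(unique(r_taxa))
    )
  })
}

rank_mapper <- function(taxonomy, rank) {
  if (rank == "otu") return(identity)
  if (is.null(taxonomy)) stop("taxonomy required for rank = '", rank, "'")
  taxonomy <- fill_unclassified(taxonomy)
  function(ids) {
    ix <- match(ids, taxonomy$otu_id)
    if (anyNA(ix)) {
      stop("features missing from taxonomy: ",
           paste(ids[is.na(ix)], collapse = ", "))
    }
    taxonomy[[rank]][ix]
  }
}

#' Direction-concordant markers across hosts
#'
#' Features (or rank-level taxa) that are significant in both the donor and
#' the recipient comparison with the same direction of change. KOs are
#' matched by id; OTUs can be matched at genus or family level through the
#' taxonomy, in which case a taxon only counts when all its significant
#' markers within a host agree in direction.
#'
#' @param donor_markers,recipient_markers [find_markers()] results.
#' @param taxonomy Taxonomy tibble (for OTU rank matching).
#' @param rank `"otu"`, `"genus"`, `"family"` (use `"otu"` for KO ids too).
#' @return A tibble with `taxon`, `donor_direction`, `recipient_direction`.
#' @export
concordant_markers <- function(donor_markers, recipient_markers,
                               taxonomy = NULL,
                               rank = c("otu", "genus", "family")) {
  rank <- match.arg(rank)
  taxon_of <- rank_mapper(taxonomy, rank)
  side <- function(markers) {
    sig <- dplyr::filter(markers, .data$significant)
    if (nrow(sig) == 0) {
      return(tibble::tibble(taxon = character(), direction = character()))
    }
    # normalize direction labels to up/down regardless of the contrast name
    sig$dirn <- ifelse(grepl("^up_in_", sig$direction), "up", "down")
    sig$taxon <- taxon_of(sig$feature_id)
    sig |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(direction = if (dplyr::n_distinct(.data$dirn) == 1)
        .data$dirn[1] else NA_character_, .groups = "drop") |>
      dplyr::filter(!is.na(.data$direction))
  }
  d <- side(donor_markers)
  r <- side(recipient_markers)
  dplyr::inner_join(d, r, by = "taxon", suffix = c("_donor", "_recipient")) |>
    dplyr::filter(.data$direction_donor == .data$direction_recipient) |>
    dplyr::transmute(
      taxon = .data$taxon,
      donor_direction = .data$direction_donor,
      recipient_direction = .data$direction_recipient
    )
}
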