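#' Validate a bundle of pipeline inputs
#'
#' Cross-checks ids between tables, tree, metadata, pathway map and taxonomy.
#' Problems are returned as a tibble with a `severity` column: `"fatal"`
#' issues (samples without metadata, OTUs missing from the tree or taxonomy)
#' prevent a run, `"warning"` issues (KOs without a pathway) do not.
#'
#' @param otu_table,ko_table [feature_table()]s (either may be `NULL`).
#' @param tree Rooted [ape::phylo] tree or `NULL`.
#' @param metadata Metadata tibble.
#' @param pathway_map Pathway map tibble or `NULL`.
#' @param taxonomy Taxonomy tibble or `NULL`.
#' @return A tibble with columns `severity`, `stage`, `message`; zero rows
#'   when everything is consistent.
#' @export
validate_inputs <- function(otu_table = NULL, ko_table = NULL, tree = NULL,
                            metadata = NULL, pathway_map = NULL,
                            taxonomy = NULL) {
  issues <- list()
  add <- function(severity, stage, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, stage = stage, message = message
    )
  }
  check_meta <- function(table, label) {
    missing <- setdiff(ft_samples(table), metadata$sample_id)
    if (length(missing) > 0) {
      add("fatal", "metadata", paste0(label, " samples without metadata: ",
                                      paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(metadata)) {
    ok <- tryCatch({validate_metadata(metadata); TRUE},
                   error = function(e) {add("fatal", "metadata",
                                            conditionMessage(e)); FALSE})
    if (ok) {
      if (!is.null(otu_table)) check_meta(otu_table, "OTU table")
      if (!is.null(ko_table)) check_meta(ko_table, "KO table")
    }
  }
  if (!is.null(otu_table) && !is.null(tree)) {
    missing <- setdiff(ft_features(otu_table), tree$tip.label)
    if (length(missing) > 0) {
      add("fatal", "beta",
          paste0("OTUs absent from tree: ", paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(otu_table) && !is.null(taxonomy)) {
    missing <- setdiff(ft_features(otu_table), taxonomy$otu_id)
    if (length(missing) > 0) {
      add("fatal", "crosshost", paste0("OTUs absent from taxonomy: ",
                                       paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(ko_table) && !is.null(pathway_map)) {
    orphan <- setdiff(ft_features(ko_table), pathway_map$ko)
    if (length(orphan) > 0) {
      add("warning", "enrichment",
          paste0(length(orphan), " KO(s) without a pathway assignment"))
    }
  }
  if (length(issues) == 0) {
    return(tibble::tibble(severity = character(), stage = character(),
                          message = character()))
  }
  dplyr::bind_rows(issues)
}

#' Run the full cross-host analysis
#'
#' Orchestrates every stage on a study bundle: alpha diversity, beta
#' diversity (phylogeny-weighted for OTUs, cosine for KOs), PCoA/PCA
#' ordination, PERMANOVA, marker discovery for OTUs and KOs in both hosts,
#' reporter-score pathway enrichment, the OTU-KO co-occurrence network, and
#' the donor-versus-recipient overlap and amplification report. All stage
#' outputs are persisted under `out_dir` as TSV/JSON and the headline numbers
#' are returned (and written) as a run report. One global seed derives every
#' stage seed, so a rerun with the same inputs and seed is byte-identical.
#'
#' @param bundle A `study_bundle` from [generate_paired_study()], or a list
#'   with the same elements assembled from files.
#' @param out_dir Output directory.
#' @param seed Global integer seed (default the bundle's config seed, or 1).
#' @param n_permutations Permutations for PERMANOVA (default 999).
#' @param otu_profile,ko_profile,network_profile [marker_profile()] names
#'   used for the marker, enrichment and network stages.
#' @param min_occurrence Occurrence filter (default 6).
#' @return A `run_report` list (also saved as `report.json` and
#'   `report.txt`), with per-stage headline numbers.
#' @export
run_full <- function(bundle, out_dir, seed = NULL, n_permutations = 999,
                     otu_profile = "paper-otu", ko_profile = "paper-ko",
                     network_profile = "paper-network",
                     min_occurrence = 6) {
  seed <- seed %||% bundle$config$seed %||% 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  issues <- validate_inputs(bundle$donor_otu, bundle$donor_ko, bundle$tree,
                            bundle$donor_metadata, bundle$pathway_map,
                            bundle$taxonomy)
  if (any(issues$severity == "fatal")) {
    stop("stage 'validate' failed: ",
         paste(issues$message[issues$severity == "fatal"], collapse = "; "))
  }
  if (is.null(bundle$tree)) {
    stop("stage 'beta' failed: phylogenetic distance requested but no tree")
  }
  meta_all <- dplyr::bind_rows(bundle$donor_metadata,
                               bundle$recipient_metadata)

  report <- list(parameters = list(
    seed = seed, n_permutations = n_permutations,
    otu_profile = otu_profile, ko_profile = ko_profile,
    network_profile = network_profile, min_occurrence = min_occurrence
  ), version = as.character(utils::packageVersion("fmtpipe")))

  # alpha
  alpha <- stage("alpha", dplyr::bind_rows(
    alpha_diversity(bundle$donor_otu), alpha_diversity(bundle$recipient_otu)
  ))
  readr::write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))

  # beta + ordination + permanova, per host
  hosts <- list(
    donor = list(otu = bundle$donor_otu, ko = bundle$donor_ko,
                 meta = bundle$donor_metadata),
    recipient = list(otu = bundle$recipient_otu, ko = bundle$recipient_ko,
                     meta = bundle$recipient_metadata)
  )
  report$permanova <- list()
  dists <- list()
  for (h in names(hosts)) {
    hx <- hosts[[h]]
    d_otu <- stage("beta", pairwise_distances(hx$otu, "phylo",
                                              tree = bundle$tree))
    d_ko <- stage("beta", pairwise_distances(hx$ko, "cosine"))
    dists[[h]] <- list(otu = d_otu, ko = d_ko)
    write_distance_matrix(d_otu, file.path(out_dir,
                                           paste0(h, "_otu_dist.tsv")))
    write_distance_matrix(d_ko, file.path(out_dir, paste0(h, "_ko_dist.tsv")))
    ord_otu <- stage("ordination", pcoa(d_otu))
    ord_ko <- stage("ordination", pca(hx$ko))
    readr::write_tsv(tidy(ord_otu),
                     file.path(out_dir, paste0(h, "_otu_pcoa.tsv")))
    readr::write_tsv(tidy(ord_ko),
                     file.path(out_dir, paste0(h, "_ko_pca.tsv")))
    hm <- hx$meta$group %in% c("H", "M")
    sub_ids <- hx$meta$sample_id[hm]
    pv_otu <- stage("permanova", permanova(
      as.matrix(d_otu)[sub_ids, sub_ids], hx$meta[hm, ],
      n_permutations = n_permutations, seed = derive_seed(seed, 11)
    ))
    pv_ko <- stage("permanova", permanova(
      as.matrix(d_ko)[sub_ids, sub_ids], hx$meta[hm, ],
      n_permutations = n_permutations, seed = derive_seed(seed, 12)
    ))
    report$permanova[[h]] <- list(
      otu = list(F = pv_otu$F, p = pv_otu$p),
      ko = list(F = pv_ko$F, p = pv_ko$p)
    )
    # taxon-function concordance of the two ordinations
    shared_ord <- intersect(ord_otu$sample_ids, ord_ko$sample_ids)
    pr <- stage("procrustes", procrustes_mc(
      ord_otu$coordinates[shared_ord, , drop = FALSE],
      ord_ko$coordinates[shared_ord, , drop = FALSE],
      n_permutations = n_permutations, seed = derive_seed(seed, 13)
    ))
    report$procrustes[[h]] <- list(m2 = pr$m2, p = pr$p)
  }

  # markers
  otu_prof <- marker_profile(otu_profile)
  ko_prof <- marker_profile(ko_profile)
  markers <- list()
  for (h in names(hosts)) {
    hx <- hosts[[h]]
    mk_otu <- stage("markers", find_markers(
      hx$otu, hx$meta, "H", "M", min_occurrence = min_occurrence,
      alpha = otu_prof$alpha, use_adjusted = otu_prof$use_adjusted
    ))
    mk_ko <- stage("markers", find_markers(
      hx$ko, hx$meta, "H", "M", min_occurrence = min_occurrence,
      alpha = ko_prof$alpha, use_adjusted = ko_prof$use_adjusted
    ))
    markers[[h]] <- list(otu = mk_otu, ko = mk_ko)
    readr::write_tsv(mk_otu, file.path(out_dir, paste0(h, "_otu_markers.tsv")))
    readr::write_tsv(mk_ko, file.path(out_dir, paste0(h, "_ko_markers.tsv")))
    report$markers[[h]] <- list(
      otu = sum(mk_otu$significant), ko = sum(mk_ko$significant)
    )
  }

  # enrichment
  report$enrichment <- list()
  enr <- list()
  for (h in names(hosts)) {
    e <- stage("enrichment", enrich(
      markers[[h]]$ko, bundle$pathway_map, seed = derive_seed(seed, 21)
    ))
    enr[[h]] <- e
    readr::write_tsv(e, file.path(out_dir, paste0(h, "_pathways.tsv")))
    report$enrichment[[h]] <- list(
      significant = sum(e$significant),
      up = sum(e$significant & e$direction == "up"),
      down = sum(e$significant & e$direction == "down")
    )
  }

  # network on donor differential features (network profile thresholds)
  net_prof <- marker_profile(network_profile)
  report$network <- stage("network", {
    mk_o <- dplyr::filter(find_markers(
      hosts$donor$otu, hosts$donor$meta, "H", "M",
      min_occurrence = min_occurrence,
      alpha = net_prof$alpha, use_adjusted = net_prof$use_adjusted
    ), .data$significant)
    mk_k <- dplyr::filter(find_markers(
      hosts$donor$ko, hosts$donor$meta, "H", "M",
      min_occurrence = min_occurrence,
      alpha = net_prof$alpha, use_adjusted = net_prof$use_adjusted
    ), .data$significant)
    if (nrow(mk_o) >= 1 && nrow(mk_k) >= 1) {
      sel <- function(tab, ids) ft_rebuild(
        ft_matrix(tab)[, ids, drop = FALSE], tab)
      net <- build_network(
        sel(hosts$donor$otu, mk_o$feature_id),
        sel(hosts$donor$ko, mk_k$feature_id),
        taxonomy = bundle$taxonomy, pathway_map = bundle$pathway_map
      )
      export_network(net, file.path(out_dir, "network_edges.tsv"),
                     "edge_tsv")
      list(nodes = nrow(net$nodes), edges = nrow(net$edges))
    } else {
      list(nodes = 0L, edges = 0L)
    }
  })

  # cross-host report
  report$crosshost <- stage("crosshost", {
    folds <- lapply(c("otu", "ko"), function(kind) {
      d_mean <- mean_between_group_distance(dists$donor[[kind]],
                                            bundle$donor_metadata, "H", "M")
      r_mean <- mean_between_group_distance(dists$recipient[[kind]],
                                            bundle$recipient_metadata,
                                            "H", "M")
      list(donor_mean_between = d_mean, recipient_mean_between = r_mean,
           fold = amplification_factor(d_mean, r_mean))
    })
    names(folds) <- c("otu", "ko")
    sharing <- dplyr::bind_rows(lapply(c("otu", "genus", "family"), function(r)
      shared_features(bundle$donor_otu, bundle$recipient_otu,
                      bundle$donor_metadata, bundle$recipient_metadata,
                      taxonomy = bundle$taxonomy, rank = r,
                      groups = c("H", "M"))))
    readr::write_tsv(sharing, file.path(out_dir, "shared_features.tsv"))
    conc <- concordant_markers(markers$donor$otu, markers$recipient$otu,
                               taxonomy = bundle$taxonomy, rank = "genus")
    readr::write_tsv(conc, file.path(out_dir, "concordant_genera.tsv"))
    list(
      amplification = folds,
      family_sharing = as.list(setNames(
        sharing$shared_fraction_abundance[sharing$rank == "family"],
        paste0("group_", sharing$group[sharing$rank == "family"])
      )),
      concordant_genera = nrow(conc)
    )
  })

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  writeLines(format_run_report(report), file.path(out_dir, "report.txt"))
  structure(report, class = "run_report")
}

format_run_report <- function(report) {
  c(
    sprintf("fmtpipe run report (version %s, seed %d)",
            report$version, report$parameters$seed),
    sprintf("PERMANOVA H vs M (donor):     OTU F = %.3f (p = %.4g), KO F = %.3f (p = %.4g)",
            report$permanova$donor$otu$F, report$permanova$donor$otu$p,
            report$permanova$donor$ko$F, report$permanova$donor$ko$p),
    sprintf("PERMANOVA H vs M (recipient): OTU F = %.3f (p = %.4g), KO F = %.3f (p = %.4g)",
            report$permanova$recipient$otu$F, report$permanova$recipient$otu$p,
            report$permanova$recipient$ko$F, report$permanova$recipient$ko$p),
    sprintf("markers: donor %d OTU / %d KO; recipient %d OTU / %d KO",
            report$markers$donor$otu, report$markers$donor$ko,
            report$markers$recipient$otu, report$markers$recipient$ko),
    sprintf("enriched pathways: donor %d, recipient %d",
            report$enrichment$donor$significant,
            report$enrichment$recipient$significant),
    sprintf("network: %d nodes, %d edges",
            report$network$nodes, report$network$edges),
    sprintf("amplification fold: OTU %.3f (%.4f -> %.4f), KO %.3f (%.4f -> %.4f)",
            report$crosshost$amplification$otu$fold,
            report$crosshost$amplification$otu$donor_mean_between,
            report$crosshost$amplification$otu$recipient_mean_between,
            report$crosshost$amplification$ko$fold,
            report$crosshost$amplification$ko$donor_mean_between,
            report$crosshost$amplification$ko$recipient_mean_between)
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}
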