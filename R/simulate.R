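#' Configuration for the paired-study generator
#'
#' Defaults emulate the design of a cow-to-mouse FMT study: two hosts (donor
#' cows, recipient germ-free mice), groups H (healthy) and M (mastitis) of 12
#' samples each plus an optional probiotic-intervention group P in the
#' recipient, counts drawn from a Dirichlet-multinomial at roughly 10,000
#' reads per sample, a planted set of differential OTUs of both signs, KO
#' profiles induced from the OTUs through a gene-content matrix, and a
#' donor-to-recipient amplification of the planted between-group divergence.
#'
#' `base_concentration` is the per-feature Dirichlet concentration: counts for
#' a sample of group g are multinomial draws from a Dirichlet with parameter
#' `base_concentration * n_otus * p_g`, where `p_g` is the group's expected
#' composition.
#'
#' @param n_otus,n_kos,n_pathways Numbers of OTUs, KOs and pathways.
#' @param samples_per_group Samples per group and host (default 12).
#' @param base_concentration Per-feature Dirichlet concentration (default 50).
#' @param depth Sequencing depth per sample (default 10000 reads).
#' @param n_diff_otus Number of planted differential OTUs (default 30),
#'   half enriched in M, half depleted.
#' @param n_diff_pathways Number of planted enriched pathways (default 4,
#'   half up, half down in M).
#' @param log2_effect Planted donor log2 effect size (default 1.5).
#' @param amplification Multiplier on the planted log2 effect in the
#'   recipient host (default 3).
#' @param ko_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on KO abundances (default 0.2).
#' @param engraftment_dropout Probability that a non-planted donor OTU fails
#'   to engraft in a recipient group (default 0.1).
#' @param recipient_flip_fraction Fraction of planted OTUs whose direction is
#'   flipped in the recipient host (default 0; raise it to study cross-host
#'   marker concordance).
#' @param include_p Generate recipient group P (default `TRUE`).
#' @param functional_recovery For group P, fraction by which the planted
#'   KO-level effects are pulled back toward group H while the OTU structure
#'   stays at group M (default 0.6).
#' @param seed Integer seed; the bundle is bit-reproducible given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_otus = 150, n_kos = 300, n_pathways = 20,
                       samples_per_group = 12, base_concentration = 50,
                       depth = 10000, n_diff_otus = 30, n_diff_pathways = 4,
                       log2_effect = 1.5, amplification = 3,
                       ko_noise_cv = 0.2, engraftment_dropout = 0.1,
                       recipient_flip_fraction = 0, include_p = TRUE,
                       functional_recovery = 0.6, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_diff_otus > cfg$n_otus) stop("n_diff_otus exceeds n_otus")
  if (cfg$samples_per_group < 3) stop("need at least 3 samples per group")
  if (cfg$base_concentration <= 0) stop("base_concentration must be positive")
  if (cfg$log2_effect < 0 || cfg$amplification <= 0 || cfg$ko_noise_cv < 0) {
    stop("effect sizes must be nonnegative and amplification positive")
  }
  structure(cfg, class = "sim_config")
}

#' Random rooted bifurcating tree with exponential branch lengths
#'
#' @param n_leaves Number of leaves (>= 2); labeled `OTU_1 .. OTU_n`.
#' @param seed Integer seed.
#' @return A rooted [ape::phylo] tree.
#' @export
generate_tree <- function(n_leaves, seed = 1) {
  if (n_leaves < 2) stop("need at least two leaves")
  set.seed(seed)
  tree <- ape::rtree(n_leaves, br = function(n) rexp(n, rate = 10))
  tree$tip.label <- paste0("OTU_", seq_len(n_leaves))
  tree
}

rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) == 0) stop("degenerate Dirichlet draw")
  g / sum(g)
}

# Dirichlet-multinomial count table: one row per sample
sample_counts <- function(p_group, n_samples, concentration, depth, prefix) {
  counts <- t(vapply(seq_len(n_samples), function(i) {
    probs <- rdirichlet1(concentration * p_group)
    rmultinom(1, depth, probs)[, 1]
  }, numeric(length(p_group))))
  dimnames(counts) <- list(paste0(prefix, seq_len(n_samples)),
                           names(p_group))
  counts
}

#' Generate a paired donor/recipient study bundle
#'
#' Produces, from one [sim_config()], the complete cross-host study: donor
#' and recipient OTU count tables with metadata, KO relative-abundance tables
#' induced through a shared gene-content matrix, a random phylogeny, a
#' KO-to-pathway map, a taxonomy, and the planted ground truth. Group M
#' differs from H by `log2_effect` (log2 scale) on the planted OTUs in the
#' donor and by `log2_effect * amplification` in the recipient; planted
#' pathways aggregate KO-level differences of a consistent sign because their
#' member KOs load on planted OTUs of one sign.
#'
#' @param config A [sim_config()].
#' @return A `study_bundle` list with elements `donor_otu`, `donor_ko`,
#'   `donor_metadata`, `recipient_otu`, `recipient_ko`, `recipient_metadata`,
#'   `tree`, `pathway_map`, `taxonomy`, `gene_content`, `truth`, `config`.
#' @export
generate_paired_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  otus <- paste0("OTU_", seq_len(cfg$n_otus))
  kos <- sprintf("K%05d", seq_len(cfg$n_kos))
  tree <- generate_tree(cfg$n_otus, seed = derive_seed(cfg$seed, 1))

  set.seed(derive_seed(cfg$seed, 2))
  taxonomy <- simulate_taxonomy(otus)

  # baseline community: lognormal rank-abundance profile
  base <- rlnorm(cfg$n_otus, meanlog = 0, sdlog = 1)
  p0 <- setNames(base / sum(base), otus)

  # plant differential OTUs among the non-rare majority so markers reflect
  # taxa a survey could actually see
  eligible <- which(p0 >= stats::quantile(p0, 0.25))
  diff_idx <- sample(eligible, cfg$n_diff_otus)
  signs <- rep(c(1, -1), length.out = cfg$n_diff_otus)
  n_flip <- round(cfg$recipient_flip_fraction * cfg$n_diff_otus)
  flipped <- seq_len(cfg$n_diff_otus) %in%
    sample(seq_len(cfg$n_diff_otus), n_flip)

  shift <- function(p, idx, log2fc) {
    p[idx] <- p[idx] * 2^log2fc
    p / sum(p)
  }
  p_donor_h <- p0
  p_donor_m <- shift(p0, diff_idx, signs * cfg$log2_effect)

  # engraftment: recipients start from the pooled donor inoculum; some
  # non-planted OTUs fail to transfer, independently per recipient group
  engraft <- function(p) {
    drop <- runif(length(p)) < cfg$engraftment_dropout
    drop[diff_idx] <- FALSE
    p[drop] <- 0
    p / sum(p)
  }
  q_h <- engraft(p_donor_h)
  rec_signs <- ifelse(flipped, -signs, signs)
  p_rec_m <- shift(engraft(p_donor_h), diff_idx,
                   rec_signs * cfg$log2_effect * cfg$amplification)

  set.seed(derive_seed(cfg$seed, 3))
  conc <- cfg$base_concentration * cfg$n_otus
  n <- cfg$samples_per_group
  donor_counts <- rbind(
    sample_counts(p_donor_h, n, conc, cfg$depth, "cow_H_"),
    sample_counts(p_donor_m, n, conc, cfg$depth, "cow_M_")
  )
  rec_counts <- rbind(
    sample_counts(q_h, n, conc, cfg$depth, "mouse_H_"),
    sample_counts(p_rec_m, n, conc, cfg$depth, "mouse_M_")
  )
  if (cfg$include_p) {
    # group P is structurally group M: same expected OTU composition
    rec_counts <- rbind(
      rec_counts,
      sample_counts(p_rec_m, n, conc, cfg$depth, "mouse_P_")
    )
  }

  donor_meta <- tibble::tibble(
    sample_id = rownames(donor_counts),
    group = rep(c("H", "M"), each = n), host = "cow"
  )
  rec_groups <- c(rep(c("H", "M"), each = n),
                  if (cfg$include_p) rep("P", n))
  rec_meta <- tibble::tibble(
    sample_id = rownames(rec_counts), group = rec_groups, host = "mouse"
  )

  set.seed(derive_seed(cfg$seed, 4))
  gc <- simulate_gene_content(otus, kos, cfg$n_pathways, cfg$n_diff_pathways,
                              diff_idx, signs)
  gene_content <- gc$gene_content
  pathway_map <- gc$pathway_map

  # group P: planted-pathway KOs pulled toward the healthy level while the
  # OTU structure stays at group M
  p_factor <- rep(1, cfg$n_kos)
  if (cfg$include_p) {
    planted_paths <- gc$planted_pathways
    primary <- gc$primary_pathway
    for (j in seq_len(nrow(planted_paths))) {
      hit <- primary == planted_paths$pathway[j]
      fc <- cfg$log2_effect * cfg$amplification * cfg$functional_recovery
      p_factor[hit] <- 2^(-planted_paths$sign[j] * fc)
    }
  }

  donor_otu <- feature_table(donor_counts, kind = "otu")
  recipient_otu <- feature_table(rec_counts, kind = "otu")
  donor_ko <- otu_to_ko_table(donor_otu, gene_content, cfg$ko_noise_cv,
                              seed = derive_seed(cfg$seed, 5))
  rec_ko_mult <- matrix(1, nrow(rec_counts), cfg$n_kos)
  if (cfg$include_p) {
    rec_ko_mult[rec_meta$group == "P", ] <-
      matrix(p_factor, n, cfg$n_kos, byrow = TRUE)
  }
  recipient_ko <- otu_to_ko_table(recipient_otu, gene_content,
                                  cfg$ko_noise_cv,
                                  seed = derive_seed(cfg$seed, 6),
                                  multiplier = rec_ko_mult)

  truth <- list(
    otus = tibble::tibble(
      otu_id = otus[diff_idx], sign = signs,
      recipient_sign = rec_signs
    ),
    pathways = gc$planted_pathways,
    amplification = cfg$amplification
  )
  structure(
    list(
      donor_otu = donor_otu, donor_ko = donor_ko, donor_metadata = donor_meta,
      recipient_otu = recipient_otu, recipient_ko = recipient_ko,
      recipient_metadata = rec_meta,
      tree = tree, pathway_map = pathway_map, taxonomy = taxonomy,
      gene_content = gene_content, truth = truth, config = cfg
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "# study_bundle: %d OTUs, %d KOs, %d donor + %d recipient samples, %d planted OTUs, amplification %g\n",
    x$config$n_otus, x$config$n_kos, nrow(x$donor_otu),
    nrow(x$recipient_otu), nrow(x$truth$otus), x$truth$amplification
  ))
  invisible(x)
}

# taxonomy: genera nested in families nested in two phyla; ~10% of OTUs
# lack a genus and get per-OTU unclassified tokens
simulate_taxonomy <- function(otus) {
  n <- length(otus)
  n_fam <- max(4, n %/% 15)
  n_gen <- max(8, n %/% 6)
  fam_of_gen <- sample(n_fam, n_gen, replace = TRUE)
  phyla <- c("Firmicutes", "Bacteroidetes")
  phy_of_fam <- sample(phyla, n_fam, replace = TRUE)
  gen <- sample(n_gen, n, replace = TRUE)
  tx <- tibble::tibble(
    otu_id = otus,
    phylum = phy_of_fam[fam_of_gen[gen]],
    family = paste0("family_", fam_of_gen[gen]),
    genus = paste0("genus_", gen)
  )
  tx$genus[runif(n) < 0.1] <- NA_character_
  fill_unclassified(tx)
}

# gene-content matrix + pathway map with planted enriched pathways: member
# KOs of an up (down) pathway load on the M-enriched (M-depleted) planted
# OTUs, so KO-level differences aggregate with a consistent sign
simulate_gene_content <- function(otus, kos, n_pathways, n_diff_pathways,
                                  diff_idx, signs) {
  n_otus <- length(otus)
  n_kos <- length(kos)
  pathways <- sprintf("path%03d", seq_len(n_pathways))
  primary <- sample(rep_len(seq_len(n_pathways), n_kos))
  planted_ix <- seq_len(n_diff_pathways)
  planted_signs <- rep(c(1, -1), length.out = n_diff_pathways)
  up_otus <- diff_idx[signs > 0]
  down_otus <- diff_idx[signs < 0]
  g <- matrix(0, n_otus, n_kos, dimnames = list(otus, kos))
  for (j in seq_len(n_kos)) {
    path <- primary[j]
    if (path %in% planted_ix) {
      carriers <- if (planted_signs[path] > 0) up_otus else down_otus
      carriers <- sample(carriers, max(2, length(carriers) %/% 2))
      g[carriers, j] <- rgamma(length(carriers), shape = 2, rate = 0.5)
      # faint background so the KO is not private to planted OTUs
      bg <- sample(setdiff(seq_len(n_otus), diff_idx), 3)
      g[bg, j] <- rgamma(3, shape = 0.5, rate = 2)
    } else {
      carriers <- sample(setdiff(seq_len(n_otus), diff_idx),
                         max(3, n_otus %/% 5))
      g[carriers, j] <- rgamma(length(carriers), shape = 1, rate = 1)
    }
  }
  pm <- tibble::tibble(ko = kos, pathway = pathways[primary])
  # many-to-many: a quarter of the KOs belong to a second, non-planted pathway
  extra_ix <- sample(n_kos, n_kos %/% 4)
  secondary <- pathways[-planted_ix][
    sample(n_pathways - n_diff_pathways, length(extra_ix), replace = TRUE)]
  pm <- dplyr::bind_rows(pm, tibble::tibble(ko = kos[extra_ix],
                                            pathway = secondary))
  pm <- dplyr::distinct(pm)
  pm$pathway_name <- paste0("pathway ", sub("^path0*", "", pm$pathway))
  list(
    gene_content = g,
    pathway_map = dplyr::arrange(pm, .data$pathway, .data$ko),
    planted_pathways = tibble::tibble(pathway = pathways[planted_ix],
                                      sign = planted_signs),
    primary_pathway = pathways[primary]
  )
}

#' Derive a KO table from an OTU table through a gene-content matrix
#'
#' Relative-normalizes the OTU table, multiplies by the nonnegative
#' OTU-by-KO gene-content matrix, applies multiplicative lognormal noise with
#' the given coefficient of variation, and relative-normalizes the result.
#'
#' @param otu_table A [feature_table()] of OTUs.
#' @param gene_content Nonnegative matrix, OTUs (rows) by KOs (columns).
#' @param noise_cv Coefficient of variation of the lognormal noise (0 = none).
#' @param seed Optional integer seed.
#' @param multiplier Optional samples-by-KOs matrix of deterministic
#'   abundance multipliers applied before the noise.
#' @return A relative [feature_table()] of kind `"ko"`.
#' @export
otu_to_ko_table <- function(otu_table, gene_content, noise_cv = 0,
                            seed = NULL, multiplier = NULL) {
  if (any(gene_content < 0)) stop("gene content must be nonnegative")
  m <- ft_matrix(otu_table)
  if (!identical(colnames(m), rownames(gene_content))) {
    stop("gene content rows must match the OTU features")
  }
  rel <- m / rowSums(m)
  ko <- rel %*% gene_content
  if (!is.null(multiplier)) ko <- ko * multiplier
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(rlnorm(length(ko), -sdlog^2 / 2, sdlog), nrow(ko))
    ko <- ko * noise
  }
  feature_table(ko / rowSums(ko), kind = "ko", normalization = "relative")
}

#' Write a study bundle to a directory of plain-text files
#'
#' Tables as feature-by-sample TSV, metadata as TSV, the tree as newick, the
#' pathway map and taxonomy as TSV, and the planted truth as JSON.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_feature_table(bundle$donor_otu, fp("donor_otu.tsv"))
  write_feature_table(bundle$donor_ko, fp("donor_ko.tsv"))
  write_feature_table(bundle$recipient_otu, fp("recipient_otu.tsv"))
  write_feature_table(bundle$recipient_ko, fp("recipient_ko.tsv"))
  readr::write_tsv(bundle$donor_metadata, fp("donor_metadata.tsv"))
  readr::write_tsv(bundle$recipient_metadata, fp("recipient_metadata.tsv"))
  ape::write.tree(bundle$tree, fp("tree.nwk"))
  readr::write_tsv(bundle$pathway_map, fp("pathway_map.tsv"))
  readr::write_tsv(bundle$taxonomy, fp("taxonomy.tsv"))
  jsonlite::write_json(
    list(otus = bundle$truth$otus, pathways = bundle$truth$pathways,
         amplification = bundle$truth$amplification),
    fp("truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
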