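#' Read and write feature tables
#'
#' Feature tables on disk follow the usual supplementary-table orientation:
#' features in rows, samples in columns, tab separated with a header row whose
#' first field names the feature-id column. The BIOM reader accepts the JSON
#' dialect via the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"` (JSON dialect).
#' @param kind Feature role recorded on the table, `"otu"` or `"ko"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"),
                               kind = c("otu", "ko")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (format == "tsv") {
    raw <- readr::read_tsv(path, name_repair = "minimal",
                           show_col_types = FALSE)
    # first column holds feature ids whatever its header says
    ids <- as.character(raw[[1]])
    vals <- raw[-1]
    if (!all(vapply(vals, is.numeric, logical(1)))) {
      stop("non-numeric abundance columns in ", path)
    }
    m <- t(as.matrix(vals))
    colnames(m) <- ids
  } else {
    b <- biomformat::read_biom(path)
    dense <- as(biomformat::biom_data(b), "matrix") # features x samples
    m <- t(dense)
  }
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids in ", path)
  if (any(m < 0)) stop("negative values in ", path)
  feature_table(m, kind = kind)
}

#' @rdname read_feature_table
#' @param table A [feature_table()] to write.
#' @export
write_feature_table <- function(table, path) {
  m <- t(ft_matrix(table)) # features x samples on disk
  out <- tibble::as_tibble(as.data.frame(m), rownames = "feature_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a rooted phylogenetic tree
#'
#' Thin wrapper over [ape::read.tree()] that checks the tree is rooted and has
#' nonnegative branch lengths.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree in ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  invisible(tree)
}

#' Check that a tree's leaves cover a set of OTU ids
#'
#' @param tree An [ape::phylo] tree.
#' @param otu_ids Character vector of OTU ids that must appear as leaves.
#' @return Invisibly `TRUE`; errors listing the missing ids otherwise.
#' @export
check_tree_covers <- function(tree, otu_ids) {
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing) > 0) {
    stop(
      "tree leaves do not cover all OTU ids; missing: ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' Read sample metadata
#'
#' Expects a three-column TSV: `sample_id`, `group` (H, M or P) and `host`
#' (cow or mouse).
#'
#' @param path TSV file path.
#' @return A tibble with columns `sample_id`, `group`, `host`.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = "ccc", show_col_types = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  md <- tibble::as_tibble(md)
  need <- c("sample_id", "group", "host")
  if (!all(need %in% names(md))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(md$group %in% c("H", "M", "P"))) stop("group must be H, M or P")
  if (!all(md$host %in% c("cow", "mouse"))) stop("host must be cow or mouse")
  md[need]
}

# every table sample must have exactly one metadata record
match_metadata <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  missing <- setdiff(ft_samples(table), metadata$sample_id)
  if (length(missing) > 0) {
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  metadata[match(ft_samples(table), metadata$sample_id), ]
}

#' Read a KO-to-pathway membership map
#'
#' Two-column TSV (`ko`, `pathway`), one row per membership; a KO belonging to
#' several pathways appears on several rows. An optional third column
#' `pathway_name` supplies display names.
#'
#' @param path TSV file path.
#' @return A tibble with columns `ko`, `pathway` and (always) `pathway_name`.
#' @export
read_pathway_map <- function(path) {
  pm <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  if (ncol(pm) < 2) stop("pathway map needs at least two columns")
  names(pm)[1:2] <- c("ko", "pathway")
  if (!"pathway_name" %in% names(pm)) pm$pathway_name <- pm$pathway
  dplyr::distinct(pm[c("ko", "pathway", "pathway_name")])
}

#' Read a taxonomy map
#'
#' TSV with columns `otu_id`, `phylum`, `family`, `genus`. Missing ranks are
#' replaced with per-OTU `unclassified_<otu_id>` tokens so that unclassified
#' taxa never match each other when computing rank-level sharing.
#'
#' @param path TSV file path.
#' @return A tibble with columns `otu_id`, `phylum`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  need <- c("otu_id", "phylum", "family", "genus")
  if (!all(need %in% names(tx))) {
    stop("taxonomy needs columns: ", paste(need, collapse = ", "))
  }
  fill_unclassified(tx[need])
}

fill_unclassified <- function(tx) {
  for (rank in c("phylum", "family", "genus")) {
    blank <- is.na(tx[[rank]]) | tx[[rank]] == ""
    tx[[rank]][blank] <- paste0("unclassified_", tx$otu_id[blank])
  }
  tx
}

#' Write and read a square distance matrix as TSV
#'
#' @param dist A [pairwise_distances()] result or square matrix.
#' @param path TSV path; written with a header row and an id column.
#' @export
write_distance_matrix <- function(dist, path) {
  m <- as.matrix(dist)
  out <- tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", .default = "d"))
  m <- as.matrix(raw[-1])
  rownames(m) <- raw$sample_id
  new_dist_matrix(m, method = "file")
}
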