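#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks both vectors, computes the Pearson correlation of the ranks and a
#' two-sided p-value from the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @return A list with `rho` and `p`; `rho` is `NA` (with a warning) when
#'   either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors must have equal length")
  if (n < 4) stop("need at least four paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Taxon-function co-occurrence network
#'
#' Correlates differential OTUs against differential KOs (Spearman, across
#' shared samples) and keeps edges with `|rho| > rho_threshold` and BH
#' q-value (over all tested pairs) below `q_threshold`. By default only
#' OTU-KO pairs are tested; `pairs = "all"` adds OTU-OTU and KO-KO edges.
#'
#' @param otu_table,ko_table [feature_table()]s restricted to the differential
#'   features, sharing sample ids.
#' @param rho_threshold Magnitude threshold on rho (default 0.8).
#' @param q_threshold BH q-value threshold (default 0.01).
#' @param pairs `"otu-ko"` (default) or `"all"`.
#' @param taxonomy Optional taxonomy tibble to annotate OTU nodes with genus.
#' @param pathway_map Optional pathway map to annotate KO nodes.
#' @return A `co_network`: list with `nodes` (id, kind, annotation,
#'   component), `edges` (node_a, node_b, rho, p, q, sign) and `n_tested`.
#' @export
build_network <- function(otu_table, ko_table, rho_threshold = 0.8,
                          q_threshold = 0.01, pairs = c("otu-ko", "all"),
                          taxonomy = NULL, pathway_map = NULL) {
  pairs <- match.arg(pairs)
  shared <- intersect(ft_samples(otu_table), ft_samples(ko_table))
  if (length(shared) < 4) stop("need at least four shared samples")
  mo <- ft_matrix(otu_table)[shared, , drop = FALSE]
  mk <- ft_matrix(ko_table)[shared, , drop = FALSE]
  keep_var <- function(m, kind) {
    const <- apply(m, 2, sd) == 0
    if (any(const)) {
      warning("skipping constant ", kind, " feature(s): ",
              paste(colnames(m)[const], collapse = ", "))
    }
    m[, !const, drop = FALSE]
  }
  mo <- keep_var(mo, "otu")
  mk <- keep_var(mk, "ko")
  ro <- apply(mo, 2, rank)
  rk <- apply(mk, 2, rank)
  n <- length(shared)
  edge_frame <- function(ra, rb, kind_a, kind_b, same) {
    rho <- cor(ra, rb)
    idx <- if (same) which(upper.tri(rho), arr.ind = TRUE) else
      as.matrix(expand.grid(seq_len(ncol(ra)), seq_len(ncol(rb))))
    tibble::tibble(
      node_a = colnames(ra)[idx[, 1]], kind_a = kind_a,
      node_b = colnames(rb)[idx[, 2]], kind_b = kind_b,
      rho = rho[idx]
    )
  }
  cand <- edge_frame(ro, rk, "otu", "ko", same = FALSE)
  if (pairs == "all") {
    cand <- dplyr::bind_rows(
      cand,
      if (ncol(ro) > 1) edge_frame(ro, ro, "otu", "otu", same = TRUE),
      if (ncol(rk) > 1) edge_frame(rk, rk, "ko", "ko", same = TRUE)
    )
  }
  cand$p <- vapply(cand$rho, spearman_p, numeric(1), n = n)
  cand$q <- bh_adjust(cand$p)
  edges <- dplyr::filter(cand, abs(.data$rho) > rho_threshold,
                         .data$q < q_threshold)
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = colnames(mo), kind = "otu"),
    tibble::tibble(id = colnames(mk), kind = "ko")
  )
  nodes$annotation <- NA_character_
  if (!is.null(taxonomy)) {
    ix <- match(nodes$id, taxonomy$otu_id)
    nodes$annotation[nodes$kind == "otu"] <-
      taxonomy$genus[ix][nodes$kind == "otu"]
  }
  if (!is.null(pathway_map)) {
    agg <- pathway_map |>
      dplyr::group_by(.data$ko) |>
      dplyr::summarise(paths = paste(sort(unique(.data$pathway)),
                                     collapse = ";"))
    ix <- match(nodes$id, agg$ko)
    nodes$annotation[nodes$kind == "ko"] <- agg$paths[ix][nodes$kind == "ko"]
  }
  g <- igraph::graph_from_data_frame(
    edges[c("node_a", "node_b")], directed = FALSE,
    vertices = nodes["id"]
  )
  nodes$component <- igraph::components(g)$membership[nodes$id]
  structure(
    list(nodes = nodes,
         edges = edges[c("node_a", "kind_a", "node_b", "kind_b",
                         "rho", "p", "q", "sign")],
         n_tested = nrow(cand)),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "# co_network: %d nodes, %d edges (of %d tested pairs), %d components\n",
    nrow(x$nodes), nrow(x$edges), x$n_tested,
    length(unique(x$nodes$component))
  ))
  invisible(x)
}

#' Export / import a co-occurrence network
#'
#' `edge_tsv` writes the edge table (plus a companion `<path>.nodes.tsv` with
#' node attributes); `graphml` writes GraphML via igraph. Both round-trip
#' through [import_network()].
#'
#' @param network A `co_network`.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
export_network <- function(network, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    readr::write_tsv(network$edges, path)
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"))
  } else {
    cols <- c("node_a", "node_b",
              setdiff(names(network$edges), c("node_a", "node_b")))
    g <- igraph::graph_from_data_frame(
      network$edges[cols], directed = FALSE,
      vertices = network$nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               node_a = "c", kind_a = "c", node_b = "c",
                               kind_b = "c", sign = "c", .default = "d"))
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(component = "d",
                                                     .default = "c"))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices"))
    nodes$id <- NULL # graphml XML node ids; the vertex name is the feature id
    nodes <- dplyr::rename(nodes, id = "name")
    edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
    edges <- dplyr::rename(edges, node_a = "from", node_b = "to")
  }
  structure(list(nodes = nodes, edges = edges, n_tested = NA_integer_),
            class = "co_network")
}

#' @rdname build_network
#' @param object A `co_network`.
#' @param ... Ignored.
#' @export
autoplot.co_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE,
                                     vertices = object$nodes["id"])
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  lay <- dplyr::left_join(lay, object$nodes, by = "id")
  seg <- object$edges |>
    dplyr::left_join(lay[c("id", "x", "y")], by = c(node_a = "id")) |>
    dplyr::left_join(lay[c("id", "x", "y")], by = c(node_b = "id"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(.data$x, .data$y, colour = .data$kind), size = 3
    ) +
    ggplot2::theme_void()
}
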