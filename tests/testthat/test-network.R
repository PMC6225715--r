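test_that("spearman correlation matches hand rank computations", {
  expect_equal(spearman_cor(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_cor(1:6, 6:1)$rho, -1)
  # Sum d^2 = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  res <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$rho, 0.8, tolerance = 1e-12)
  expect_warning(cc <- spearman_cor(rep(2, 5), 1:5), "constant")
  expect_true(is.na(cc$rho))
  expect_error(spearman_cor(1:3, 1:3), "four")
})

test_that("a feature correlated with its own copy forms a rho = 1 edge", {
  set.seed(41)
  x <- runif(12)
  otu <- feature_table(matrix(x, 12, 1,
                              dimnames = list(paste0("s", 1:12), "OTU_1")))
  ko <- feature_table(matrix(x, 12, 1,
                             dimnames = list(paste0("s", 1:12), "K00001")),
                      kind = "ko")
  net <- build_network(otu, ko)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$rho, 1)
  expect_equal(net$edges$sign, "positive")
})

test_that("independent features produce no edges and roles are symmetric", {
  set.seed(42)
  counts <- vapply(1:6, function(i) {
    otu <- feature_table(matrix(runif(24 * 5), 24, 5,
      dimnames = list(paste0("s", 1:24), paste0("OTU_", 1:5))))
    ko <- feature_table(matrix(runif(24 * 8), 24, 8,
      dimnames = list(paste0("s", 1:24), sprintf("K%05d", 1:8))), kind = "ko")
    nrow(build_network(otu, ko)$edges)
  }, numeric(1))
  expect_equal(median(counts), 0)

  b <- tiny_bundle(seed = 4)
  sel <- function(tab, n) fmtpipe:::ft_rebuild(
    ft_matrix(tab)[, seq_len(n), drop = FALSE], tab)
  otu <- sel(b$donor_otu, 6)
  ko <- sel(b$donor_ko, 10)
  fwd <- build_network(otu, ko, rho_threshold = 0.6, q_threshold = 0.05)
  swapped <- build_network(ko, otu, rho_threshold = 0.6, q_threshold = 0.05)
  key <- function(e) sort(paste(pmin(e$node_a, e$node_b),
                                pmax(e$node_a, e$node_b)))
  expect_identical(key(fwd$edges), key(swapped$edges))
})

test_that("stored edge statistics can be recomputed from the raw data", {
  b <- tiny_bundle(seed = 6)
  mk_o <- dplyr::filter(find_markers(b$donor_otu, b$donor_metadata), .data$significant)
  mk_k <- dplyr::filter(find_markers(b$donor_ko, b$donor_metadata,
                                     alpha = 0.05, use_adjusted = FALSE),
                        .data$significant)
  skip_if(nrow(mk_o) == 0 || nrow(mk_k) == 0)
  sel <- function(tab, ids) fmtpipe:::ft_rebuild(
    ft_matrix(tab)[, ids, drop = FALSE], tab)
  net <- build_network(sel(b$donor_otu, mk_o$feature_id),
                       sel(b$donor_ko, mk_k$feature_id),
                       rho_threshold = 0.8, q_threshold = 0.05)
  expect_true(all(abs(net$edges$rho) > 0.8))
  mo <- ft_matrix(b$donor_otu)
  mk <- ft_matrix(b$donor_ko)
  for (i in seq_len(min(nrow(net$edges), 10))) {
    e <- net$edges[i, ]
    again <- spearman_cor(mo[, e$node_a], mk[, e$node_b])
    expect_equal(e$rho, again$rho, tolerance = 1e-12)
    expect_equal(e$p, again$p, tolerance = 1e-12)
  }
})

test_that("the planted driver OTU is the hub of its component", {
  b <- tiny_bundle(seed = 7)
  mk_o <- dplyr::filter(find_markers(b$donor_otu, b$donor_metadata),
                        .data$significant)
  mk_k <- dplyr::filter(find_markers(b$donor_ko, b$donor_metadata,
                                     alpha = 0.05, use_adjusted = FALSE),
                        .data$significant)
  sel <- function(tab, ids) fmtpipe:::ft_rebuild(
    ft_matrix(tab)[, ids, drop = FALSE], tab)
  net <- build_network(sel(b$donor_otu, mk_o$feature_id),
                       sel(b$donor_ko, mk_k$feature_id),
                       rho_threshold = 0.7, q_threshold = 0.05)
  expect_gt(nrow(net$edges), 0)
  deg <- table(c(net$edges$node_a, net$edges$node_b))
  top <- names(deg)[which.max(deg)]
  expect_true(top %in% b$truth$otus$otu_id)
})

test_that("network export round-trips through edge TSV and GraphML", {
  b <- tiny_bundle(seed = 8)
  sel <- function(tab, n) fmtpipe:::ft_rebuild(
    ft_matrix(tab)[, seq_len(n), drop = FALSE], tab)
  net <- build_network(sel(b$donor_otu, 8), sel(b$donor_ko, 15),
                       rho_threshold = 0.5, q_threshold = 0.2,
                       taxonomy = b$taxonomy, pathway_map = b$pathway_map)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  back <- import_network(tsv, "edge_tsv")
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges),
               tolerance = 1e-12)
  expect_equal(back$nodes$id, net$nodes$id)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- import_network(gml, "graphml")
  expect_setequal(g$nodes$id, net$nodes$id)
  expect_equal(nrow(g$edges), nrow(net$edges))
  expect_equal(sort(g$edges$rho), sort(net$edges$rho), tolerance = 1e-6)

  # empty networks still export valid files
  empty <- net
  empty$edges <- net$edges[0, ]
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, tsv2, "edge_tsv")
  expect_equal(nrow(import_network(tsv2, "edge_tsv")$edges), 0)
})

test_that("a two-node, one-edge network writes the exact expected TSV", {
  net <- structure(list(
    nodes = tibble::tibble(id = c("OTU_1", "K00001"), kind = c("otu", "ko"),
                           annotation = NA_character_, component = c(1, 1)),
    edges = tibble::tibble(node_a = "OTU_1", kind_a = "otu",
                           node_b = "K00001", kind_b = "ko",
                           rho = 0.9, p = 0.001, q = 0.001,
                           sign = "positive"),
    n_tested = 1L
  ), class = "co_network")
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path, "edge_tsv")
  expect_identical(readLines(path), c(
    "node_a\tkind_a\tnode_b\tkind_b\trho\tp\tq\tsign",
    "OTU_1\totu\tK00001\tko\t0.9\t0.001\t0.001\tpositive"
  ))
})
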