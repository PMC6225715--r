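test_that("phylogeny-weighted similarity handles the boundary cases", {
  tr <- star_tree(3, c("A", "B", "C"))
  a <- c(A = 0.6, B = 0.4, C = 0)
  expect_equal(phylo_similarity(a, a, tr), 1, tolerance = 1e-12)
  # disjoint supports on a star: only the root could match, and its linear
  # weight is zero
  b <- c(A = 0, B = 0, C = 1)
  expect_equal(phylo_similarity(c(A = 1, B = 0, C = 0), b, tr), 0)
  # on a star tree the similarity is the min-total overlap
  b2 <- c(A = 0.2, B = 0.2, C = 0.6)
  expect_equal(phylo_similarity(a, b2, tr), 0.4, tolerance = 1e-12)
  expect_equal(phylo_distance(a, b2, tr), 0.6, tolerance = 1e-12)

  expect_error(phylo_similarity(c(A = 0.5, B = 0.2, C = 0), b, tr),
               "normalized")
  expect_error(phylo_similarity(c(A = 0.5, D = 0.5), b, tr), "D")
})

test_that("caterpillar tree reproduces a hand-traced recursion", {
  # ((A:1,B:2):1,C:3); heights: AB node 2, root 3 -> weights 1/3 and 0
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3):0;")
  a <- c(A = 0.5, B = 0.3, C = 0.2)
  b <- c(A = 0.1, B = 0.4, C = 0.5)
  # leaves match 0.1 + 0.3 + 0.2 = 0.6; AB node matches min(0.4, 0.1) = 0.1
  # at weight 1/3; root matches the remaining 0.3 at weight 0
  expect_equal(phylo_similarity(a, b, tr), 0.6 + 0.1 / 3, tolerance = 1e-12)
  expect_equal(phylo_distance(a, b, tr), 1 - (0.6 + 0.1 / 3),
               tolerance = 1e-12)
})

test_that("star-tree distance equals Bray-Curtis (vegan oracle)", {
  skip_if_not_installed("vegan")
  set.seed(21)
  tr <- star_tree(8)
  for (i in 1:20) {
    a <- setNames(random_composition(8), tr$tip.label)
    b <- setNames(random_composition(8), tr$tip.label)
    bc <- as.numeric(vegan::vegdist(rbind(a, b), "bray"))
    expect_equal(phylo_distance(a, b, tr), bc, tolerance = 1e-10)
  }
})

test_that("matched mass plus root residual accounts for all mass", {
  set.seed(5)
  tr <- generate_tree(12, seed = 3)
  plan <- fmtpipe:::phylo_plan(tr, "exponential", lambda = 0.7)
  a <- setNames(random_composition(12), tr$tip.label)
  b <- setNames(random_composition(12), tr$tip.label)
  res <- fmtpipe:::phylo_match(
    fmtpipe:::align_profile(a, plan), fmtpipe:::align_profile(b, plan), plan
  )
  expect_equal(sum(res$matched) + res$residual_a, 1, tolerance = 1e-12)
  expect_equal(sum(res$matched) + res$residual_b, 1, tolerance = 1e-12)
})

test_that("shrinking branches raises internal weights and lowers distance", {
  set.seed(6)
  base <- generate_tree(10, seed = 9)
  a <- setNames(random_composition(10), base$tip.label)
  b <- setNames(random_composition(10), base$tip.label)
  scales <- c(4, 2, 1, 0.5, 0.25, 0.05)
  dists <- vapply(scales, function(s) {
    tr <- base
    tr$edge.length <- tr$edge.length * s
    phylo_distance(a, b, tr, weight_mode = "exponential", lambda = 1)
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-12))
  # in the zero-height limit every node has weight 1 and all mass matches
  expect_lt(dists[length(dists)], 0.05)
})

test_that("cosine distance matches hand values", {
  expect_equal(cosine_distance(c(2, 1, 3), c(2, 1, 3)), 0, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(0, 2)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero")
})

test_that("pairwise_distances agrees with single-pair calls and is metric-shaped", {
  set.seed(31)
  tab <- toy_table(s = 5, f = 6, seed = 13)
  tr <- generate_tree(6, seed = 4)
  tr$tip.label <- ft_features(tab)
  d <- pairwise_distances(tab, "phylo", tree = tr)
  m <- as.matrix(d)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_true(all(m >= 0 & m <= 1 + 1e-12))
  rel <- ft_matrix(normalize_relative(tab))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(m[i, j],
                   phylo_distance(rel[i, ], rel[j, ], tr),
                   tolerance = 1e-12)
    }
  }
  # duplicated samples give a zero matrix
  two <- feature_table(rbind(s1 = c(a = 3, b = 7), s2 = c(a = 3, b = 7)))
  expect_equal(unname(as.matrix(pairwise_distances(two, "cosine"))),
               matrix(0, 2, 2))
})
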