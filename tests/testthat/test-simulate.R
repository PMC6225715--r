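test_that("generate_tree builds reproducible bifurcating rooted trees", {
  tr2 <- generate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_true(ape::is.rooted(tr2))
  a <- ape::write.tree(generate_tree(20, seed = 5))
  b <- ape::write.tree(generate_tree(20, seed = 5))
  expect_identical(a, b)
  tr50 <- generate_tree(50, seed = 2)
  expect_equal(tr50$Nnode, 49) # n_internal = n_leaves - 1, root included
  expect_true(ape::is.binary(tr50))
  expect_true(all(tr50$edge.length >= 0))
  expect_error(generate_tree(1), "two")
})

test_that("study bundles are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_otus = 30, n_kos = 40, samples_per_group = 4, seed = 77,
                    n_diff_otus = 6)
  b1 <- generate_paired_study(cfg)
  b2 <- generate_paired_study(cfg)
  expect_identical(ft_matrix(b1$donor_otu), ft_matrix(b2$donor_otu))
  expect_identical(ft_matrix(b1$recipient_ko), ft_matrix(b2$recipient_ko))
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$truth, b2$truth)
})

test_that("bundle pieces are mutually consistent", {
  b <- tiny_bundle(seed = 10)
  expect_equal(nrow(validate_inputs(b$donor_otu, b$donor_ko, b$tree,
                                    b$donor_metadata, b$pathway_map,
                                    b$taxonomy)), 0)
  expect_setequal(ft_features(b$donor_otu), b$tree$tip.label)
  expect_true(all(ft_features(b$donor_ko) %in% b$pathway_map$ko))
  expect_equal(ft_samples(b$donor_otu), b$donor_metadata$sample_id)
  # taxonomy never contradicts itself: one family per genus
  cls <- unique(b$taxonomy[c("family", "genus")])
  expect_equal(anyDuplicated(cls$genus), 0)
})

test_that("otu_to_ko_table is the noisy normalized matrix product", {
  m <- matrix(c(2, 2, 1, 3), 2, 2,
              dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
  otu <- feature_table(m)
  ident <- diag(2)
  dimnames(ident) <- list(c("OTU_1", "OTU_2"), c("K1", "K2"))
  ko <- otu_to_ko_table(otu, ident, noise_cv = 0)
  expect_equal(unname(ft_matrix(ko)),
               unname(ft_matrix(normalize_relative(otu))), tolerance = 1e-12)

  # hand-computed 2 OTU x 3 KO product on relative abundances
  g <- matrix(c(1, 0, 2, 1, 0, 3), 2, 3,
              dimnames = list(c("OTU_1", "OTU_2"), c("K1", "K2", "K3")))
  res <- ft_matrix(otu_to_ko_table(otu, g, noise_cv = 0))
  rel <- ft_matrix(normalize_relative(otu))
  raw <- rel %*% g
  expect_equal(unname(res), unname(raw / rowSums(raw)), tolerance = 1e-12)
  expect_error(otu_to_ko_table(otu, -g), "nonnegative")
})

test_that("planted effects scale with the amplification parameter", {
  est_effects <- function(amp, seeds) {
    vapply(seeds, function(s) {
      b <- generate_paired_study(sim_config(
        n_otus = 60, n_kos = 30, samples_per_group = 10, n_diff_otus = 10,
        amplification = amp, include_p = FALSE, seed = s
      ))
      eff <- function(tab, md) {
        rel <- ft_matrix(normalize_relative(tab))
        plus <- b$truth$otus$otu_id[b$truth$otus$sign > 0]
        log2(mean(rel[md$group == "M", plus]) /
               mean(rel[md$group == "H", plus]))
      }
      eff(b$recipient_otu, b$recipient_metadata) /
        eff(b$donor_otu, b$donor_metadata)
    }, numeric(1))
  }
  # amplification 1: donor and recipient planted log-effects agree
  expect_lt(abs(mean(est_effects(1, 1:5)) - 1), 0.35)
  # amplification 3: the ratio of estimated effects recovers it
  expect_lt(abs(mean(est_effects(3, 1:5)) - 3), 1)
})

test_that("a null configuration plants nothing", {
  b <- generate_paired_study(sim_config(
    n_otus = 50, n_kos = 40, samples_per_group = 8, log2_effect = 0, seed = 31
  ))
  mk <- find_markers(b$donor_otu, b$donor_metadata, alpha = 0.1,
                     use_adjusted = TRUE)
  # BH at q < 0.1 under the null: discoveries are rare
  expect_lt(sum(mk$significant), 5)
})
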