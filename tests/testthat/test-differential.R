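test_that("wilcoxon rank-sum p-values match enumeration and conventions", {
  # fully separated 3 vs 3: 1 of C(6,3) = 20 splits is as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), "greater"), 0.05)
  x <- c(2, 2, 5, 9)
  expect_equal(wilcoxon_rank_sum(x, x, "two_sided"), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")

  set.seed(23)
  for (i in 1:8) {
    xx <- sample(seq(1, 400), 6)
    yy <- sample(setdiff(seq(1, 400), xx), 6)
    for (alt in c("two_sided", "greater", "less")) {
      p_exact <- wilcoxon_rank_sum(xx, yy, alt)
      expect_equal(p_exact, oracle_wilcoxon_p(xx, yy, alt), tolerance = 1e-12)
      # the normal approximation stays close to the exact value
      alt_r <- c(two_sided = "two.sided", greater = "greater",
                 less = "less")[alt]
      p_approx <- suppressWarnings(
        wilcox.test(xx, yy, alternative = alt_r, exact = FALSE,
                    correct = TRUE)$p.value
      )
      expect_lt(abs(p_exact - p_approx), 0.02)
    }
  }
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(24)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("find_markers filters, annotates and respects thresholds", {
  b <- tiny_bundle(seed = 2)
  res <- find_markers(b$donor_otu, b$donor_metadata, min_occurrence = 6,
                      alpha = 0.1, use_adjusted = TRUE)
  # occurrence filter: nothing below the threshold is ever tested
  m <- ft_matrix(b$donor_otu)
  prev <- colSums(m > 0)
  expect_true(all(prev[res$feature_id] >= 6))
  expect_false(any(names(prev)[prev < 6] %in% res$feature_id))
  expect_true(all(res$direction %in% c("up_in_M", "down_in_M")))
  expect_true(all((res$effect >= 0) == (res$direction == "up_in_M")))
  expect_equal(res$q, bh_adjust(res$p))
  # planted markers dominate the discoveries in a structured bundle
  sens <- mean(b$truth$otus$otu_id %in% res$feature_id[res$significant])
  expect_gt(sens, 0.6)
})

test_that("swapping group labels flips directions and preserves p", {
  b <- tiny_bundle(seed = 5)
  fwd <- find_markers(b$donor_otu, b$donor_metadata, "H", "M")
  rev <- find_markers(b$donor_otu, b$donor_metadata, "M", "H")
  shared <- intersect(fwd$feature_id[fwd$effect != 0], rev$feature_id)
  f <- fwd[match(shared, fwd$feature_id), ]
  r <- rev[match(shared, rev$feature_id), ]
  expect_equal(f$p, r$p, tolerance = 1e-12)
  expect_equal(f$effect, -r$effect, tolerance = 1e-12)
  expect_identical(f$direction == "up_in_M", r$direction == "down_in_H")
})

test_that("marker profiles encode the analysis-specific thresholds", {
  expect_equal(marker_profile("paper-otu"),
               list(alpha = 0.01, use_adjusted = TRUE))
  expect_equal(marker_profile("paper-ko"),
               list(alpha = 0.05, use_adjusted = FALSE))
  expect_equal(marker_profile("paper-network"),
               list(alpha = 0.01, use_adjusted = TRUE))
})
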