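test_that("mean between-group distance averages exactly the cross pairs", {
  m <- matrix(0.3, 4, 4) - diag(0.3, 4)
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  md <- toy_metadata(paste0("s", 1:4), c("H", "H", "M", "M"))
  expect_equal(mean_between_group_distance(m, md, "H", "M"), 0.3)

  m2 <- m
  m2["s1", "s3"] <- m2["s3", "s1"] <- 0.1
  m2["s1", "s4"] <- m2["s4", "s1"] <- 0.2
  m2["s2", "s3"] <- m2["s3", "s2"] <- 0.3
  m2["s2", "s4"] <- m2["s4", "s2"] <- 0.4
  expect_equal(mean_between_group_distance(m2, md, "H", "M"), 0.25)
  # invariant under sample reordering and label swap
  perm <- sample(1:4)
  expect_equal(
    mean_between_group_distance(m2[perm, perm], md, "M", "H"), 0.25)
  expect_error(mean_between_group_distance(m2, md, "H", "H"), "differ")
  expect_error(mean_between_group_distance(m2, md, "H", "P"), "empty")
})

test_that("amplification factor reproduces the headline arithmetic", {
  expect_equal(amplification_factor(0.104, 0.312), 3)
  f <- amplification_factor(0.017, 0.389)
  expect_equal(f, 0.389 / 0.017, tolerance = 1e-12)
  expect_equal(fold_label(f), 23)
  expect_equal(amplification_factor(0.2, 0.2), 1)
  expect_error(amplification_factor(0, 1), "positive")
  # reciprocal pairs multiply to one
  set.seed(51)
  for (i in 1:5) {
    a <- runif(1, 0.01, 1)
    b <- runif(1, 0.01, 1)
    expect_equal(amplification_factor(a, b) * amplification_factor(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("shared_features measures donor-attributable recipient abundance", {
  donor <- feature_table(matrix(
    c(5, 5, 0, 5, 5, 0), 2, 3, byrow = TRUE,
    dimnames = list(c("c1", "c2"), c("OTU_1", "OTU_2", "OTU_3"))
  ))
  d_md <- toy_metadata(c("c1", "c2"), c("H", "H"))
  r_md <- toy_metadata(c("m1", "m2"), c("H", "H"), host = "mouse")

  sub <- feature_table(matrix(
    c(3, 7, 3, 7), 2, 2, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("OTU_1", "OTU_2"))
  ))
  res <- shared_features(donor, sub, d_md, r_md, rank = "otu", groups = "H")
  expect_equal(res$shared_fraction_abundance, 1)
  expect_equal(res$shared_fraction_count, 1)

  disj <- feature_table(matrix(
    c(10, 10), 2, 1, dimnames = list(c("m1", "m2"), "OTU_9")
  ))
  res <- shared_features(donor, disj, d_md, r_md, rank = "otu", groups = "H")
  expect_equal(res$shared_fraction_abundance, 0)

  # recipient: 0.7 of abundance on donor taxa, 0.3 on a novel one
  mixed <- feature_table(matrix(
    c(4, 3, 3, 4, 3, 3), 2, 3, byrow = TRUE,
    dimnames = list(c("m1", "m2"), c("OTU_1", "OTU_2", "OTU_9"))
  ))
  res <- shared_features(donor, mixed, d_md, r_md, rank = "otu", groups = "H")
  expect_equal(res$shared_fraction_abundance, 0.7)
  expect_equal(res$shared_fraction_count, 2 / 3)
})

test_that("rank-level sharing goes through the taxonomy and unclassified never match", {
  donor <- feature_table(matrix(
    c(6, 4), 1, 2, dimnames = list("c1", c("OTU_1", "OTU_2"))
  ))
  recip <- feature_table(matrix(
    c(5, 5), 1, 2, dimnames = list("m1", c("OTU_3", "OTU_4"))
  ))
  tx <- tibble::tibble(
    otu_id = paste0("OTU_", 1:4),
    phylum = "Firmicutes",
    family = c("famA", "famB", "famA", NA),
    genus = c("genA", "genB", "genA", NA)
  )
  d_md <- toy_metadata("c1", "H")
  r_md <- toy_metadata("m1", "H", host = "mouse")
  res <- shared_features(donor, recip, d_md, r_md, taxonomy = tx,
                         rank = "family", groups = "H")
  # OTU_3 shares famA with the donor; OTU_4 is unclassified and matches nothing
  expect_equal(res$shared_fraction_abundance, 0.5)
  expect_error(shared_features(donor, recip, d_md, r_md, rank = "family"),
               "taxonomy")
})

test_that("concordant markers require significance and matching direction", {
  mk <- function(ids, dirs, sig = TRUE) tibble::tibble(
    feature_id = ids, p = 0.001, q = 0.001,
    direction = dirs, effect = ifelse(grepl("up", dirs), 1, -1),
    significant = sig
  )
  donor <- mk(c("K1", "K2", "K3"), c("up_in_M", "down_in_M", "up_in_M"))
  same <- concordant_markers(donor, donor)
  expect_setequal(same$taxon, c("K1", "K2", "K3"))

  flipped <- mk(c("K1", "K2", "K3"), c("down_in_M", "up_in_M", "down_in_M"))
  expect_equal(nrow(concordant_markers(donor, flipped)), 0)

  partial <- mk(c("K1", "K2", "K4"), c("up_in_M", "up_in_M", "down_in_M"))
  res <- concordant_markers(donor, partial)
  expect_equal(res$taxon, "K1")
  expect_equal(res$donor_direction, "up")
})

test_that("cross-host concordance recovers the non-flipped planted truth", {
  b <- generate_paired_study(sim_config(
    n_otus = 60, n_kos = 60, samples_per_group = 10, n_diff_otus = 12,
    recipient_flip_fraction = 0.5, seed = 9
  ))
  donor <- find_markers(b$donor_otu, b$donor_metadata)
  recip <- find_markers(b$recipient_otu, b$recipient_metadata)
  res <- concordant_markers(donor, recip)
  truth_conc <- b$truth$otus$otu_id[b$truth$otus$sign ==
                                      b$truth$otus$recipient_sign]
  expect_gt(mean(truth_conc %in% res$taxon), 0.7)
  truth_flipped <- setdiff(b$truth$otus$otu_id, truth_conc)
  expect_equal(sum(truth_flipped %in% res$taxon), 0)
})
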