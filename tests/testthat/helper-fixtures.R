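# Shared fixtures: everything is built in code at test time.

# star tree over n leaves named OTU_1..n, unit pendant branches
star_tree <- function(n, labels = paste0("OTU_", seq_len(n))) {
  txt <- paste0("(", paste0(labels, ":1", collapse = ","), "):0;")
  ape::read.tree(text = txt)
}

# random composition over n features (sums to 1)
random_composition <- function(n) {
  x <- rgamma(n, shape = 1)
  x / sum(x)
}

# small count table: s samples x f features
toy_table <- function(s = 4, f = 5, kind = "otu", seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(s * f, lambda = 20), s, f,
              dimnames = list(paste0("s", seq_len(s)),
                              paste0(toupper(kind), "_", seq_len(f))))
  feature_table(m, kind = kind)
}

toy_metadata <- function(sample_ids, groups, host = "cow") {
  tibble::tibble(sample_id = sample_ids, group = groups, host = host)
}

# small but fully structured bundle for stage tests
tiny_bundle <- function(seed = 1, ...) {
  generate_paired_study(sim_config(
    n_otus = 40, n_kos = 80, n_pathways = 8, samples_per_group = 8,
    n_diff_otus = 10, seed = seed, ...
  ))
}

# independent PERMANOVA oracle: McArdle-Anderson trace / projection form
# on the Gower-centered matrix, enumerating all two-group label splits
oracle_permanova_p <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  f_of <- function(grp) {
    x <- stats::model.matrix(~ grp - 1)
    h <- x %*% solve(crossprod(x)) %*% t(x)
    a <- length(unique(grp))
    ss_b <- sum(diag(h %*% g %*% h))
    ss_w <- sum(diag((diag(n) - h) %*% g %*% (diag(n) - h)))
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(factor(groups))
  labs <- unique(groups)
  n1 <- sum(groups == labs[1])
  picks <- combn(n, n1)
  f_all <- apply(picks, 2, function(ix) {
    grp <- rep(labs[2], n)
    grp[ix] <- labs[1]
    f_of(factor(grp))
  })
  mean(f_all >= f_obs - 1e-9)
}

# exact rank-sum enumeration oracle (tie-free): P over all splits of the
# pooled ranks that the x-group rank sum is as extreme as observed
oracle_wilcoxon_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  sums <- combn(length(pooled), nx, function(ix) sum(r[ix]))
  switch(alternative,
    greater = mean(sums >= obs),
    less = mean(sums <= obs),
    two_sided = min(1, 2 * min(mean(sums >= obs), mean(sums <= obs)))
  )
}

# brute-force BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  q <- vapply(seq_len(m), function(i) {
    min(vapply(which(p >= p[i] - 1e-15), function(j) {
      p[j] * m / rank(p, ties.method = "max")[j]
    }, numeric(1)), 1)
  }, numeric(1))
  q
}
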