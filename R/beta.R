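#' Phylogeny-weighted community similarity
#'
#' Measures how much of two relative-abundance profiles can be matched on a
#' rooted phylogeny, discounting matches that only happen at deep ancestors.
#' The recursion works post-order: at each leaf the overlap `min(a, b)` is
#' scored with full weight and the residuals propagate upward; at each internal
#' node the residual masses arriving from its children are matched against each
#' other and scored with the node weight, and whatever remains unmatched keeps
#' climbing. Node weights decay with node height h (the longest path from the
#' node down to one of its leaves): linearly, `w = max(0, 1 - h/H)` with H the
#' tree height, or exponentially, `w = exp(-lambda * h)`. Leaves have h = 0 and
#' weight 1; under linear decay the root has weight 0, so on a star tree the
#' similarity collapses to `sum(pmin(a, b))`, i.e. 1 - Bray-Curtis.
#'
#' This linear-decay similarity is this package's own concrete definition of a
#' phylogeny-weighted measure; no fidelity to any external binary is claimed.
#'
#' @param sample_a,sample_b Named relative-abundance vectors (each sums to 1);
#'   names must be leaves of `tree`.
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param weight_mode `"linear"` (default) or `"exponential"` decay of node
#'   weight with node height.
#' @param lambda Decay rate for `weight_mode = "exponential"`.
#' @return Similarity in \[0, 1\]; `phylo_distance()` returns 1 minus it.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1,C:1):0;")
#' a <- c(A = 0.6, B = 0.4, C = 0)
#' b <- c(A = 0.2, B = 0.2, C = 0.6)
#' phylo_similarity(a, b, tr) # 0.4 = 1 - Bray-Curtis on a star tree
phylo_similarity <- function(sample_a, sample_b, tree,
                             weight_mode = c("linear", "exponential"),
                             lambda = 1) {
  plan <- phylo_plan(tree, match.arg(weight_mode), lambda)
  a <- align_profile(sample_a, plan)
  b <- align_profile(sample_b, plan)
  phylo_match(a, b, plan)$score
}

#' @rdname phylo_similarity
#' @export
phylo_distance <- function(sample_a, sample_b, tree,
                           weight_mode = c("linear", "exponential"),
                           lambda = 1) {
  1 - phylo_similarity(sample_a, sample_b, tree, weight_mode, lambda)
}

# Precompute the traversal plan: postorder child lists, node heights, weights.
phylo_plan <- function(tree, weight_mode = "linear", lambda = 1) {
  validate_tree(tree)
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_all <- n_tip + tr$Nnode
  heights <- numeric(n_all)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]
    ch <- tr$edge[i, 2]
    heights[p] <- max(heights[p], heights[ch] + tr$edge.length[i])
  }
  root <- n_tip + 1L
  h_max <- heights[root]
  if (h_max <= 0) stop("tree height is zero; branch lengths are all zero")
  w <- switch(weight_mode,
    linear = pmax(0, 1 - heights / h_max),
    exponential = exp(-lambda * heights)
  )
  # parents in postorder appearance, each with its child node set
  parents <- unique(tr$edge[, 1])
  children <- split(tr$edge[, 2], factor(tr$edge[, 1], levels = parents))
  list(
    tip_label = tr$tip.label, n_tip = n_tip, n_all = n_all, root = root,
    parents = parents, children = children, weights = w, heights = heights
  )
}

align_profile <- function(sample, plan) {
  if (is.null(names(sample))) stop("samples must be named by OTU id")
  unknown <- setdiff(names(sample)[sample > 0], plan$tip_label)
  if (length(unknown) > 0) {
    stop("OTU ids not found among tree leaves: ",
         paste(unknown, collapse = ", "))
  }
  if (abs(sum(sample) - 1) > 1e-6) {
    stop("samples must be relative-normalized (sum to 1)")
  }
  out <- numeric(plan$n_tip)
  idx <- match(names(sample), plan$tip_label)
  ok <- !is.na(idx)
  out[idx[ok]] <- sample[ok]
  out
}

# Core recursion on tip-aligned vectors; returns the score and, for
# diagnostics, the matched mass per node and the unmatched residual at the
# root (matched total + root residual = total sample mass).
phylo_match <- function(a, b, plan) {
  ra <- numeric(plan$n_all)
  rb <- numeric(plan$n_all)
  ra[seq_len(plan$n_tip)] <- a
  rb[seq_len(plan$n_tip)] <- b
  matched <- numeric(plan$n_all)
  m_tip <- pmin(a, b)
  matched[seq_len(plan$n_tip)] <- m_tip
  ra[seq_len(plan$n_tip)] <- ra[seq_len(plan$n_tip)] - m_tip
  rb[seq_len(plan$n_tip)] <- rb[seq_len(plan$n_tip)] - m_tip
  score <- sum(m_tip * plan$weights[seq_len(plan$n_tip)])
  for (i in seq_along(plan$parents)) {
    p <- plan$parents[i]
    kids <- plan$children[[i]]
    s_a <- sum(ra[kids])
    s_b <- sum(rb[kids])
    m <- min(s_a, s_b)
    matched[p] <- m
    score <- score + m * plan$weights[p]
    ra[p] <- s_a - m
    rb[p] <- s_b - m
  }
  list(
    score = score, matched = matched,
    residual_a = ra[plan$root], residual_b = rb[plan$root]
  )
}

#' Cosine distance between two abundance vectors
#'
#' 1 - a.b / (|a| |b|); in \[0, 1\] for nonnegative vectors. Used for
#' functional (KO) beta diversity.
#'
#' @param ko_a,ko_b Nonnegative abundance vectors of equal length.
#' @return The cosine distance.
#' @export
cosine_distance <- function(ko_a, ko_b) {
  if (length(ko_a) != length(ko_b)) stop("vectors must have equal length")
  na <- sqrt(sum(ko_a^2))
  nb <- sqrt(sum(ko_b^2))
  if (na == 0 || nb == 0) stop("zero vector has no cosine distance")
  d <- 1 - sum(ko_a * ko_b) / (na * nb)
  # clip tiny negatives from floating point
  max(d, 0)
}

new_dist_matrix <- function(m, method, parameters = list()) {
  stopifnot(isSymmetric(unname(m)))
  structure(m, class = c("dist_matrix", "matrix"),
            method = method, parameters = parameters)
}

#' Pairwise sample distances
#'
#' Applies a distance to every sample pair of a table. `method = "phylo"`
#' needs `tree` and relative-normalizes the table first (the phylogenetic
#' similarity is defined on relative abundances); `"cosine"` and `"bray"`
#' (Bray-Curtis on relative abundances) need no tree.
#'
#' @param table A [feature_table()].
#' @param method `"phylo"`, `"cosine"` or `"bray"`.
#' @param tree Rooted [ape::phylo] tree covering the OTU ids (phylo only).
#' @inheritParams phylo_similarity
#' @return A `dist_matrix`: a symmetric matrix with zero diagonal, sample ids
#'   as dimnames and attributes `method` and `parameters`.
#' @export
pairwise_distances <- function(table, method = c("phylo", "cosine", "bray"),
                               tree = NULL,
                               weight_mode = c("linear", "exponential"),
                               lambda = 1) {
  method <- match.arg(method)
  weight_mode <- match.arg(weight_mode)
  m <- ft_matrix(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (method == "phylo") {
    if (is.null(tree)) stop("method = 'phylo' requires a tree")
    check_tree_covers(tree, ft_features(table))
    rel <- m / rowSums(m)
    plan <- phylo_plan(tree, weight_mode, lambda)
    prof <- t(apply(rel, 1, function(r) align_profile(setNames(r, colnames(rel)), plan)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - phylo_match(prof[i, ], prof[j, ], plan)$score
      }
    }
    params <- list(weight_mode = weight_mode, lambda = lambda)
  } else if (method == "cosine") {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- cosine_distance(m[i, ], m[j, ])
      }
    }
    params <- list()
  } else {
    rel <- m / rowSums(m)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - sum(pmin(rel[i, ], rel[j, ]))
      }
    }
    params <- list()
  }
  new_dist_matrix(d, method = method, parameters = params)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "method") <- NULL
  attr(m, "parameters") <- NULL
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("# dist_matrix (%s): %d samples\n", attr(x, "method"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @export
tidy.dist_matrix <- function(x, ...) {
  m <- as.matrix(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(m)[idx[, 1]],
    sample_b = colnames(m)[idx[, 2]],
    distance = m[idx]
  )
}
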