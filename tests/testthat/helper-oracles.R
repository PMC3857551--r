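# Independent brute-force oracles used to check the package's clustering,
# correlation and matching code paths.  These deliberately share no code
# with the implementation: naive O(n^3) agglomeration, explicit
# lowest-common-merge traversal, textbook covariance formulas, exhaustive
# permutation matching.

# Pearson correlation by the direct covariance formula
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# naive single-linkage agglomeration on a full distance matrix; returns
# merge heights (in merge order) and the full cophenetic matrix filled in
# by the lowest common merge of every leaf pair
oracle_single_linkage <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(members)
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        dab <- min(D[members[[a]], members[[b]]])
        if (dab < bestd) {
          bestd <- dab
          best <- c(a, b)
        }
      }
    }
    heights[step] <- bestd
    for (i in members[[best[1]]]) {
      for (j in members[[best[2]]]) {
        coph[i, j] <- coph[j, i] <- bestd
      }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  list(heights = heights, coph = coph)
}

# oracle cophenetic correlation: brute agglomeration + LCA + direct Pearson
oracle_ccc <- function(D) {
  n <- nrow(D)
  coph <- oracle_single_linkage(D)$coph
  orig <- D[lower.tri(D)]
  cd <- coph[lower.tri(coph)]
  oracle_pearson(orig, cd)
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n) {
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  D + t(D)
}

# exhaustive one-to-one matching of rows of A to rows of B maximizing
# total |Pearson r|; returns the per-pair |r| under the best permutation
oracle_best_matching <- function(A, B) {
  n <- nrow(A)
  stopifnot(n == nrow(B), n <= 7)
  C <- abs(stats::cor(t(A), t(B)))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  bestsum <- -Inf
  for (p in perms(seq_len(n))) {
    s <- sum(C[cbind(seq_len(n), p)])
    if (s > bestsum) {
      bestsum <- s
      best <- p
    }
  }
  C[cbind(seq_len(n), best)]
}

# empirical mutual information (nats) between a discrete vector and a
# binary vector
oracle_mi <- function(g, b) {
  n <- length(g)
  mi <- 0
  for (gv in unique(g)) {
    for (bv in c(0L, 1L)) {
      p <- sum(g == gv & b == bv) / n
      if (p > 0) mi <- mi + p * log(p / (sum(g == gv) / n * sum(b == bv) / n))
    }
  }
  mi
}

# small fast grids for unit tests; half-extent snaps to the spacing so
# voxel centres include the origin
test_grid <- function(spacing = 8, half = 40) {
  half <- spacing * ceiling(half / spacing)
  n <- as.integer(2 * half / spacing + 1)
  volume_grid(origin = rep(-half, 3), spacing = spacing, dims = rep(n, 3))
}

# a small planted corpus on a compact grid (fast, well separated)
test_corpus <- function(k = 3, e = 90, seed = 1, grid = test_grid(spacing = 6),
                        ...) {
  args <- list(
    k_networks = k, e_experiments = e, classes_per_network = 3L,
    blobs_per_network = c(1L, 2L), blob_spread = 10,
    min_network_separation = 30, peak_jitter_sd = 4,
    peaks_per_experiment = c(4L, 8L), seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(synth_config, args)
  list(config = cfg, grid = grid, corpus = build_corpus(cfg, grid))
}
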