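# Cross-decomposition fractionation: spatial correlation, parent
# assignment, network clustering, artifact flagging, per-group rates.

test_that("spatial cross-correlation behaves like a Pearson map similarity", {
  set.seed(31)
  v <- 500
  A <- matrix(rnorm(3 * v), 3)
  cc_self <- spatial_cross_correlation(A, A)
  expect_equal(unname(diag(unclass(cc_self))), rep(1, 3), tolerance = 1e-12)

  # positive rescaling leaves correlations unchanged
  B <- matrix(rnorm(2 * v), 2)
  cc1 <- spatial_cross_correlation(A, B)
  cc2 <- spatial_cross_correlation(A * 5.5, B)
  expect_equal(unclass(cc1), unclass(cc2), tolerance = 1e-12)
  expect_true(all(unclass(cc1) >= -1 & unclass(cc1) <= 1))

  # disjoint compact supports on a zero background, against the oracle
  x <- rep(0, v); y <- rep(0, v)
  x[10:40] <- dnorm(seq(-2, 2, length.out = 31))
  y[300:340] <- dnorm(seq(-2, 2, length.out = 41))
  cc <- spatial_cross_correlation(rbind(x), rbind(y))
  expect_equal(unclass(cc)[1, 1], oracle_pearson(x, y), tolerance = 1e-12)

  expect_error(spatial_cross_correlation(A, matrix(0, 2, v + 1)),
               "different grids")
  expect_warning(ccna <- spatial_cross_correlation(rbind(x, rep(1, v)), rbind(y)),
                 "constant")
  expect_true(is.na(unclass(ccna)[2, 1]))
})

test_that("parents are assigned by maximal correlation with stated tie rule", {
  cc <- matrix(c(0.9, 0.1, 0.2,
                 0.3, 0.8, 0.1), 2, 3, byrow = TRUE)
  pa <- assign_parents(cc)
  expect_equal(pa$parent, c(1L, 2L))
  expect_equal(pa$correlation, c(0.9, 0.8))

  # artifact high component gets no parent
  pa2 <- assign_parents(cc, artifact_high = 2)
  expect_true(is.na(pa2$parent[2]))
  expect_equal(pa2$parent[1], 1L)

  # artifact low components are excluded from the argmax
  pa3 <- assign_parents(cc, artifact_low = 1)
  expect_equal(pa3$parent, c(3L, 2L))   # 0.2 beats 0.1 once column 1 is out

  # exact tie goes to the lower low-order id
  cct <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(assign_parents(cct)$parent, 1L)

  expect_error(assign_parents(cc, artifact_low = 1:3), "every low-order")

  # invariance under simultaneous reordering of rows and artifact list
  set.seed(5)
  ccr <- matrix(runif(12), 4, 3)
  p <- c(3L, 1L, 4L, 2L)
  a <- assign_parents(ccr, artifact_high = 2)
  b <- assign_parents(ccr[p, ], artifact_high = which(p == 2))
  expect_equal(b$parent[order(p)], a$parent)
})

test_that("network clustering joins duplicated components at height zero", {
  set.seed(6)
  base <- matrix(rnorm(20), 5, 4)
  meta <- list(values = cbind(base, base[, 2]), d = 5)
  class(meta) <- "metadata_matrix"
  tree <- network_hca(meta)
  expect_equal(nrow(tree$merges), 4L)       # d - 1 merges
  expect_equal(min(tree$merges$height), 0)
  first <- unlist(tree$merges[1, c("left", "right")])
  expect_setequal(first, c(1, 4))           # 0-based ids of columns 2 and 5
  expect_error(network_hca(list(values = base[, 1, drop = FALSE], d = 1)),
               "at least 2")
})

test_that("components from the same planted family cluster together", {
  tc <- test_corpus(k = 2, e = 120, seed = 17,
                    grid = test_grid(spacing = 6, half = 54),
                    blobs_per_network = c(2L, 2L), blob_activation_prob = 0.7,
                    min_network_separation = 60)
  ma <- stack_corpus(tc$corpus, tc$grid)
  dec <- fit_ica(reduce_svd(ma, d = 4, center = FALSE), d = 4, seed = 3)
  meta <- project_metadata(tc$corpus$label_matrix,
                           experiment_weights(dec$experiment_modes, dec$mixing))
  # map each component to its generating network by spatial correlation
  truth <- t(vapply(tc$corpus$ground_truth, function(nw) {
    vol <- modeled_activation(nw$blob_centers, tc$grid, fwhm = 14)
    vol[tc$grid$mask_idx]
  }, numeric(tc$grid$n_voxels)))
  fam <- apply(abs(cor(t(dec$sources), t(truth))), 1, which.max)
  expect_setequal(unique(fam), 1:2)

  tree <- network_hca(meta)
  groups <- stats::cutree(tree$hclust, k = 2)
  # the metadata dendrogram cut reproduces the spatial family split
  expect_true(length(unique(paste(fam, groups))) == 2)
})

test_that("artifact flagging follows normalized metadata entropy", {
  uniform <- rep(0.3, 20)
  onehot <- c(1, rep(0, 19))
  dominant <- c(10, rep(1, 19))
  M <- cbind(uniform, onehot, dominant)
  ent <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) / log(20) }

  flags <- flag_artifacts(list(values = M), uniformity_threshold = 0.95)
  expect_equal(as.integer(flags), 1L)       # only the uniform column
  e <- attr(flags, "entropy")
  expect_equal(unname(e[1]), 1)
  expect_equal(unname(e[2]), 0)
  expect_equal(unname(e[3]), ent(dominant), tolerance = 1e-12)
  expect_lt(e[3], 0.95)

  # manual overrides win
  f2 <- flag_artifacts(list(values = M), 0.95, include = 3, exclude = 1)
  expect_equal(as.integer(f2), 3L)
})

test_that("fractionation rates divide sub-network counts by parent counts", {
  # 5 parents with 20 assigned children -> rate 4; zero children -> 0
  asg <- data.frame(high = 1:20, parent = rep(1:5, each = 4), correlation = 0.5)
  groups <- stats::setNames(c(rep("emo", 5), "idle"), 1:6)
  fs <- summarize_fractionation(asg, groups)
  expect_equal(fs$rate[fs$group == "emo"], 4)
  expect_equal(fs$n_subnetworks[fs$group == "idle"], 0L)
  expect_equal(fs$rate[fs$group == "idle"], 0)

  # 6 parents / 23 children -> 3.83 at the 2-decimal reporting precision
  asg2 <- data.frame(high = 1:23, parent = rep(1:6, length.out = 23),
                     correlation = 0.5)
  fs2 <- summarize_fractionation(asg2, stats::setNames(rep("cog", 6), 1:6))
  expect_equal(round(fs2$rate, 2), 3.83)
  expect_equal(fs2$rate, 23 / 6)            # full precision retained

  # a group with zero parents has an undefined rate
  fs3 <- summarize_fractionation(asg, factor(groups, levels = c("emo", "idle", "ghost")))
  expect_true(is.na(fs3$rate[fs3$group == "ghost"]))
  expect_error(summarize_fractionation(asg, groups[1:3]), "no group label")
})

test_that("assigned children plus flagged artifacts account for every component", {
  set.seed(9)
  d_high <- 12; d_low <- 4
  cc <- matrix(runif(d_high * d_low), d_high, d_low)
  art_high <- c(2L, 7L)
  asg <- assign_parents(cc, artifact_high = art_high)
  fs <- summarize_fractionation(asg, stats::setNames(c("a", "a", "b", "b"), 1:4))
  expect_equal(sum(fs$n_subnetworks) + length(art_high), d_high)
})
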