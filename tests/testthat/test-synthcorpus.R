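# Synthetic corpus generator: planted networks, experiments, labels.

test_that("ground truth planting respects counts, class disjointness and separation", {
  grid <- test_grid(spacing = 8, half = 64)

  cfg0 <- synth_config(k_networks = 0, e_experiments = 0)
  expect_identical(make_ground_truth(cfg0, grid), list())

  cfg <- synth_config(k_networks = 5, classes_per_network = 4L,
                      min_network_separation = 20, blob_spread = 8, seed = 42)
  nets <- make_ground_truth(cfg, grid)
  expect_length(nets, 5)

  ids <- unlist(lapply(nets, `[[`, "class_ids"))
  expect_length(ids, 20)
  expect_length(unique(ids), 20)           # disjoint across networks

  # brute-force pairwise centroid distances
  cents <- t(vapply(nets, function(nw) colMeans(nw$blob_centers), numeric(3)))
  for (a in 1:4) for (b in (a + 1):5) {
    expect_gte(sqrt(sum((cents[a, ] - cents[b, ])^2)), 20)
  }

  # all blob centres inside the grid bounding box
  for (nw in nets) {
    expect_true(all(nw$blob_centers >= -64 - 1e-9 & nw$blob_centers <= 64 + 1e-9))
    expect_gte(nrow(nw$blob_centers), 1)
  }

  # deterministic given seed
  nets2 <- make_ground_truth(cfg, grid)
  expect_identical(nets, nets2)
})

test_that("unsatisfiable separation fails after bounded rejection sampling", {
  grid <- test_grid(spacing = 8, half = 16)   # 32 mm box
  cfg <- synth_config(k_networks = 10, min_network_separation = 500,
                      blob_spread = 2, seed = 1)
  expect_error(make_ground_truth(cfg, grid), "rejection-sampling")
})

test_that("zero-noise experiment sampling hits blob centres and exact labels", {
  grid <- test_grid(spacing = 6)
  cfg <- synth_config(k_networks = 2, e_experiments = 4, peak_jitter_sd = 0,
                      label_fidelity = 1, false_label_rate = 0,
                      blob_activation_prob = 1, background_peak_rate = 0,
                      blob_spread = 10, min_network_separation = 25, seed = 3)
  nets <- make_ground_truth(cfg, grid)
  all_classes <- sort(unique(unlist(lapply(nets, `[[`, "class_ids"))))
  set.seed(99)
  ex <- sample_experiment(nets[[1]], cfg, grid, all_classes,
                          experiment_id = "e1")
  # every peak coincides exactly with one of the network's blob centres
  for (i in seq_len(nrow(ex$peaks))) {
    dmin <- min(sqrt(rowSums(sweep(nets[[1]]$blob_centers, 2, ex$peaks[i, ])^2)))
    expect_equal(dmin, 0)
  }
  # labels equal the network's classes exactly in the deterministic limit
  expect_identical(ex$labels, sort(nets[[1]]$class_ids))
})

test_that("label attachment rate matches the fidelity within a 99% binomial interval", {
  tc <- test_corpus(k = 3, e = 500, seed = 7, label_fidelity = 0.9,
                    false_label_rate = 0)
  corpus <- tc$corpus
  n_own <- 0L
  n_kept <- 0L
  for (j in seq_along(corpus$experiments)) {
    own <- corpus$ground_truth[[corpus$network_of[j]]]$class_ids
    n_own <- n_own + length(own)
    n_kept <- n_kept + sum(own %in% corpus$experiments[[j]]$labels)
  }
  ci <- qbinom(c(0.005, 0.995), n_own, 0.9)
  expect_gte(n_kept, ci[1])
  expect_lte(n_kept, ci[2])
})

test_that("corpus assembly is balanced, consistent and deterministic", {
  grid <- test_grid(spacing = 8)
  cfg <- synth_config(k_networks = 3, e_experiments = 10,
                      min_network_separation = 25, blob_spread = 8, seed = 5)
  corpus <- build_corpus(cfg, grid)

  # round-robin: counts differ by at most one, here {4, 3, 3}
  expect_identical(as.integer(table(corpus$network_of)), c(4L, 3L, 3L))

  # label matrix column j matches experiment j's labels exactly
  classes <- sort(unique(unlist(lapply(corpus$ground_truth, `[[`, "class_ids"))))
  for (j in seq_along(corpus$experiments)) {
    expect_identical(
      unname(corpus$label_matrix[, j] == 1L),
      classes %in% corpus$experiments[[j]]$labels
    )
  }

  # pure function of (config, grid)
  corpus2 <- build_corpus(cfg, grid)
  expect_identical(corpus, corpus2)

  # every peak lies within the grid bounding box after clipping
  lo <- grid$origin - 1e-9
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + 1e-9
  for (ex in corpus$experiments) {
    expect_true(all(sweep(ex$peaks, 2, lo, `>=`)))
    expect_true(all(sweep(ex$peaks, 2, hi, `<=`)))
  }
})

test_that("label/network mutual information rises with label fidelity", {
  mi_at <- function(fid) {
    tc <- test_corpus(k = 3, e = 240, seed = 11, label_fidelity = fid,
                      false_label_rate = 0)
    mean(vapply(seq_len(nrow(tc$corpus$label_matrix)), function(c_) {
      oracle_mi(tc$corpus$network_of, tc$corpus$label_matrix[c_, ])
    }, numeric(1)))
  }
  mis <- vapply(c(0.3, 0.6, 0.9), mi_at, numeric(1))
  expect_true(all(diff(mis) >= 0))
})

test_that("corpus round-trips through peaks.csv / labels.csv / ground_truth.json", {
  tc <- test_corpus(k = 2, e = 12, seed = 9)
  dir <- withr::local_tempdir()
  write_corpus(tc$corpus, dir)
  expect_true(all(file.exists(file.path(
    dir, c("peaks.csv", "labels.csv", "ground_truth.json")
  ))))
  back <- read_corpus(dir)
  expect_identical(dim(back$label_matrix), dim(tc$corpus$label_matrix))
  expect_true(all(back$label_matrix == tc$corpus$label_matrix))
  for (j in seq_along(back$experiments)) {
    expect_equal(unname(back$experiments[[j]]$peaks),
                 unname(tc$corpus$experiments[[j]]$peaks),
                 tolerance = 1e-12)
  }
  expect_length(back$ground_truth, 2)
  expect_equal(back$ground_truth[[1]]$blob_centers,
               unname(tc$corpus$ground_truth[[1]]$blob_centers))
})
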