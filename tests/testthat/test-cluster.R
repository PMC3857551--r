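# Correlation distances, single-linkage trees, cophenetic correlation,
# and the model-order scan.

test_that("class distances are 1 - Pearson r with the stated conventions", {
  M <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1), d = c(1, 2, 4))
  D <- as.matrix(class_distances(M))
  expect_equal(D["a", "b"], 0)              # proportional rows
  expect_equal(D["a", "c"], 2)              # anti-proportional rows
  r_oracle <- oracle_pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(D["a", "d"], 1 - r_oracle, tolerance = 1e-12)
  expect_equal(r_oracle, 0.98198051, tolerance = 1e-7)
  expect_true(all(D >= 0 & D <= 2))

  # constant row: distance 1 with a warning
  Mc <- rbind(a = c(1, 2, 3), z = c(5, 5, 5), b = c(3, 1, 2))
  expect_warning(Dc <- as.matrix(class_distances(Mc)), "constant")
  expect_equal(Dc["z", "a"], 1)
  expect_equal(Dc["z", "b"], 1)

  expect_error(class_distances(M[1, , drop = FALSE]), "at least 2")
})

test_that("single linkage reproduces the worked 3-item example", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 0.1
  D[1, 3] <- D[3, 1] <- 0.9
  D[2, 3] <- D[3, 2] <- 0.8
  tree <- single_linkage(as.dist(D))
  expect_equal(tree$merges$height, c(0.1, 0.8))
  # first merge joins leaves 0 and 1 (0-based ids)
  expect_setequal(unlist(tree$merges[1, c("left", "right")]), c(0, 1))
  expect_equal(tree$merges$size, c(2L, 3L))

  cd <- as.matrix(cophenetic_distances(tree))
  expect_equal(cd[1, 2], 0.1)
  expect_equal(cd[1, 3], 0.8)
  expect_equal(cd[2, 3], 0.8)

  # CC_c equals the direct Pearson of the two condensed vectors
  ccc <- cophenetic_cc(as.dist(D), cophenetic_distances(tree))
  expect_equal(ccc, oracle_pearson(c(0.1, 0.9, 0.8), c(0.1, 0.8, 0.8)),
               tolerance = 1e-12)
})

test_that("equidistant items merge at a single height", {
  D <- matrix(0.7, 4, 4); diag(D) <- 0
  tree <- single_linkage(as.dist(D))
  expect_equal(tree$merges$height, rep(0.7, 3))
  expect_equal(nrow(tree$merges), 3L)       # n - 1 merges
  expect_error(single_linkage(stats::as.dist(matrix(0, 1, 1))), "at least 2")
})

test_that("tree, cophenetic distances and CC_c match the brute-force oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    D <- random_distance_matrix(n)
    tree <- single_linkage(as.dist(D))
    orc <- oracle_single_linkage(D)
    expect_equal(tree$merges$height, orc$heights, tolerance = 1e-12)
    expect_equal(as.matrix(cophenetic_distances(tree)), orc$coph,
                 tolerance = 1e-12, ignore_attr = TRUE)
    ccc <- cophenetic_cc(as.dist(D), cophenetic_distances(tree))
    expect_equal(ccc, oracle_ccc(D), tolerance = 1e-10)
  }
})

test_that("cophenetic distances are ultrametric and fixed under relinkage", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    D <- random_distance_matrix(n)
    cd <- as.matrix(cophenetic_distances(single_linkage(as.dist(D))))
    # three-point condition
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      expect_lte(cd[i, k], max(cd[i, j], cd[j, k]) + 1e-12)
    }
    # ultrametric input is a fixed point: CC_c exactly 1
    tree2 <- single_linkage(stats::as.dist(cd))
    expect_equal(as.matrix(cophenetic_distances(tree2)), cd, tolerance = 1e-12)
    expect_equal(cophenetic_cc(stats::as.dist(cd), cophenetic_distances(tree2)),
                 1, tolerance = 1e-12)
  }
})

test_that("CC_c is permutation invariant and guards degenerate input", {
  set.seed(23)
  x <- runif(15); y <- runif(15)
  p <- sample(15)
  expect_equal(cophenetic_cc(x, y), cophenetic_cc(x[p], y[p]), tolerance = 1e-12)
  expect_warning(out <- cophenetic_cc(rep(1, 10), runif(10)), "constant")
  expect_true(is.na(out))
  expect_error(cophenetic_cc(1:4, 1:5), "length")
})

test_that("the model-order scan is deterministic and flags degenerate orders", {
  tc <- test_corpus(k = 3, e = 90, seed = 8)
  ma <- stack_corpus(tc$corpus, tc$grid)
  P <- tc$corpus$label_matrix

  scan <- scan_model_orders(ma, P, d_grid = 2:6, seed = 5)
  # d = 2: every pair of rows is collinear, CC_c uninformative
  expect_true(is.na(scan$ccc[scan$d_grid == 2]))
  expect_match(scan$failures[["2"]], "degenerate")
  expect_false(anyNA(scan$ccc[scan$d_grid > 2]))
  expect_true(all(scan$ccc >= -1 & scan$ccc <= 1, na.rm = TRUE))

  scan2 <- scan_model_orders(ma, P, d_grid = 2:6, seed = 5)
  expect_identical(scan$ccc, scan2$ccc)

  # a one-element grid makes that element the argmax trivially
  scan1 <- scan_model_orders(ma, P, d_grid = 4, seed = 5)
  expect_identical(scan1$argmax_order, 4L)

  # CC_c is invariant to relabelling of metadata classes
  perm <- sample(nrow(P))
  scan3 <- scan_model_orders(ma, P[perm, ], d_grid = 3:5, seed = 5)
  expect_equal(scan3$ccc, scan$ccc[scan$d_grid %in% 3:5], tolerance = 1e-10)
})

test_that("scan selection applies the mean + 2 sd rule and reports the argmax", {
  tc <- test_corpus(k = 3, e = 60, seed = 12)
  ma <- stack_corpus(tc$corpus, tc$grid)
  scan <- scan_model_orders(ma, tc$corpus$label_matrix, 3:7, seed = 2)
  expect_identical(scan$argmax_order,
                   scan$d_grid[which.max(replace(scan$ccc, is.na(scan$ccc), -2))])
  expect_true(all(scan$selected_orders %in%
                  scan$d_grid[!is.na(scan$ccc) &
                              scan$ccc > scan$mean_ccc + 2 * scan$sd_ccc]))
})

test_that("scan results serialize to CSV and JSON", {
  tc <- test_corpus(k = 3, e = 60, seed = 12)
  ma <- stack_corpus(tc$corpus, tc$grid)
  scan <- scan_model_orders(ma, tc$corpus$label_matrix, 3:5, seed = 2)
  dir <- withr::local_tempdir()
  write_scan_csv(scan, file.path(dir, "ccc.csv"))
  tab <- utils::read.csv(file.path(dir, "ccc.csv"))
  expect_equal(tab$d, 3:5)
  expect_equal(tab$ccc, scan$ccc)
  write_scan_json(scan, file.path(dir, "sel.json"))
  js <- jsonlite::read_json(file.path(dir, "sel.json"), simplifyVector = TRUE)
  expect_equal(js$argmax_order, scan$argmax_order)
  tree <- single_linkage(class_distances(rbind(a = c(1, 2, 1), b = c(2, 1, 4),
                                               c = c(0, 1, 2))))
  write_linkage_csv(tree, file.path(dir, "tree.csv"))
  expect_equal(nrow(utils::read.csv(file.path(dir, "tree.csv"))), 2L)
})
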