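# Hierarchical clustering of metadata classes, cophenetic correlation of
# the resulting dendrogram, and the model-order scan/selection built on
# them.  Distances are 1 - Pearson r between class rows of the metadata
# matrix; clustering is single linkage (average linkage available for
# sensitivity analysis).

#' Correlation distances between metadata classes
#'
#' Entry (i, j) is `1 - r` where `r` is the Pearson correlation between
#' rows i and j of the metadata matrix.  A zero-variance row leaves `r`
#' undefined; its distances are set to 1 (maximally uninformative under
#' `1 - r` without asserting anti-correlation) with a warning.
#'
#' @param meta a `metadata_matrix`, or a bare numeric matrix with items as
#'   rows.
#' @return A [stats::dist] object over the `n` rows, entries in `[0, 2]`.
#' @export
class_distances <- function(meta) {
  M <- if (inherits(meta, "metadata_matrix")) meta$values else as.matrix(meta)
  if (nrow(M) < 2) stopf("need at least 2 classes to compute distances")
  vars <- apply(M, 1, stats::var)
  C <- suppressWarnings(stats::cor(t(M)))
  if (any(vars == 0)) {
    warnf("%d constant class row(s); their correlation distances set to 1",
          sum(vars == 0))
    C[vars == 0, ] <- 0
    C[, vars == 0] <- 0
  }
  d <- stats::as.dist(1 - C)
  attr(d, "Labels") <- rownames(M) %||%
    (if (inherits(meta, "metadata_matrix")) meta$class_names else NULL)
  d
}

#' Agglomerative clustering by minimum inter-cluster distance
#'
#' Single linkage over a condensed distance vector (the default throughout
#' the package); `method = "average"` is available to probe sensitivity of
#' the model-order scan to the linkage rule.
#'
#' @param dist a [stats::dist] object.
#' @param method `"single"` (default) or `"average"`.
#' @return A `linkage_tree`: list with `hclust` (the [stats::hclust]
#'   object) and `merges`, the standard `(n-1) x 4` merge table
#'   (left, right, height, size) with 0-based ids -- leaves `0..n-1`,
#'   internal node from merge `j` labelled `n + j - 1`.
#' @export
single_linkage <- function(dist, method = c("single", "average")) {
  method <- match.arg(method)
  n <- attr(dist, "Size")
  if (is.null(n) || n < 2) stopf("need at least 2 items to cluster")
  hc <- stats::hclust(dist, method = method)
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = hc$height, size = integer(n - 1))
  sizes <- integer(n - 1)
  id <- function(x, row) if (x < 0) -x - 1L else n + x - 1L
  for (j in seq_len(n - 1)) {
    l <- hc$merge[j, 1]; r <- hc$merge[j, 2]
    sizes[j] <- (if (l < 0) 1L else sizes[l]) + (if (r < 0) 1L else sizes[r])
    merges$left[j] <- id(l)
    merges$right[j] <- id(r)
    merges$size[j] <- sizes[j]
  }
  structure(list(hclust = hc, merges = merges, method = method, n = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %s linkage over %d items (%d merges)\n",
              x$method, x$n, nrow(x$merges)))
  invisible(x)
}

#' Cophenetic distances of a linkage tree
#'
#' Entry (i, j) is the height of the lowest merge joining leaves i and j.
#'
#' @param tree a `linkage_tree`.
#' @return A [stats::dist] object in the original item order.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  stats::cophenetic(tree$hclust)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original condensed distances and the
#' cophenetic distances of the dendrogram built from them; values near 1
#' indicate the tree represents the distance structure faithfully.
#'
#' @param original condensed distances used to build the tree.
#' @param cophenetic condensed cophenetic distances
#'   ([cophenetic_distances()]).
#' @return A scalar in `[-1, 1]`, or `NA` with a warning when either
#'   vector is constant.
#' @export
cophenetic_cc <- function(original, cophenetic) {
  x <- as.vector(original)
  y <- as.vector(cophenetic)
  if (length(x) != length(y)) stopf("distance vectors differ in length")
  if (length(x) < 2) stopf("need at least 2 pairwise distances")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warnf("constant distance vector; cophenetic correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# one scan stage: decomposition -> metadata dendrogram -> CC_c
ccc_for_order <- function(red, d, label_matrix, seed, linkage = "single",
                          normalize = FALSE) {
  dec <- fit_ica(
    list(whitened = red$whitened[seq_len(d), , drop = FALSE],
         experiment_modes = red$experiment_modes[, seq_len(d), drop = FALSE],
         singular_values = red$singular_values),
    d = d, seed = substream_seed(seed, 11L, d)
  )
  w <- experiment_weights(dec$experiment_modes, dec$mixing)
  meta <- project_metadata(label_matrix, w, normalize = normalize,
                           provenance = list(seed = seed, d = d))
  dist0 <- class_distances(meta)
  # at d = 2 (and other collinear cases) every |r| is exactly 1: the
  # distances take at most two values, the dendrogram fit is trivially
  # perfect, and CC_c carries no information about this model order
  if (length(unique(round(as.vector(dist0), 12))) < 3)
    stopf("degenerate class distances at d = %d (fewer than 3 distinct values)", d)
  tree <- single_linkage(dist0, method = linkage)
  list(
    ccc = cophenetic_cc(dist0, cophenetic_distances(tree)),
    decomposition = dec, meta = meta, tree = tree
  )
}

#' Scan ICA model orders and select preferred orders by CC_c
#'
#' For every `d` in `d_grid`: SVD reduction, spatial ICA, metadata
#' projection, class dendrogram, cophenetic correlation.  The SVD is
#' computed once at `max(d_grid)` and subset per order (the top-`d`
#' factors of a matrix are the leading block of its full factorization).
#' Selected orders are those with `CC_c > mean + 2 sd` over the scan; the
#' global argmax is always reported, ties broken toward smaller `d`.
#' Orders whose class-distance vector is degenerate (fewer than 3 distinct
#' values, e.g. `d = 2` where every pair of rows is exactly collinear and
#' CC_c would be trivially 1) are recorded as failures rather than scored.
#'
#' @param ma an `ma_matrix` (or `v x e` matrix).
#' @param label_matrix `n x e` binary indicator matrix.
#' @param d_grid increasing vector of model orders.
#' @param seed integer seed (drives every per-order ICA substream).
#' @param linkage `"single"` (default) or `"average"`.
#' @param normalize passed to [project_metadata()].
#' @param keep_decompositions retain per-order decompositions and metadata
#'   matrices in the result (default FALSE to save memory).
#' @return A `ccc_scan`: list with `d_grid`, `ccc` (one value per order,
#'   `NA` where a stage failed), `mean_ccc`, `sd_ccc`, `selected_orders`,
#'   `argmax_order`, `failures` (named diagnostics), `seed`, and
#'   optionally `fits`.
#' @export
scan_model_orders <- function(ma, label_matrix, d_grid, seed = 1L,
                              linkage = c("single", "average"),
                              normalize = FALSE,
                              keep_decompositions = FALSE) {
  linkage <- match.arg(linkage)
  d_grid <- sort(unique(as.integer(d_grid)))
  if (length(d_grid) == 0) stopf("d_grid is empty")
  e <- if (inherits(ma, "ma_matrix")) ncol(ma$values) else ncol(ma)
  red <- reduce_svd(ma, d = min(max(d_grid), e))
  if (max(d_grid) > red$rank)
    stopf("max(d_grid) = %d exceeds the achievable rank %d",
          max(d_grid), red$rank)
  ccc <- rep(NA_real_, length(d_grid))
  fits <- vector("list", length(d_grid))
  failures <- list()
  for (i in seq_along(d_grid)) {
    res <- tryCatch(
      ccc_for_order(red, d_grid[i], label_matrix, seed, linkage, normalize),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[as.character(d_grid[i])]] <- conditionMessage(res)
      next
    }
    ccc[i] <- res$ccc
    if (keep_decompositions) fits[[i]] <- res
  }
  if (all(is.na(ccc))) stopf("every model order failed during the scan")
  m <- mean(ccc, na.rm = TRUE)
  s <- stats::sd(ccc, na.rm = TRUE)
  ok <- !is.na(ccc)
  selected <- if (is.na(s)) integer(0) else d_grid[ok & ccc > m + 2 * s]
  argmax <- d_grid[ok][which.max(ccc[ok])]   # which.max takes first => smaller d
  structure(
    list(
      d_grid = d_grid, ccc = ccc, mean_ccc = m, sd_ccc = s,
      selected_orders = selected, argmax_order = argmax,
      failures = failures, seed = as.integer(seed), linkage = linkage,
      fits = if (keep_decompositions) fits else NULL
    ),
    class = "ccc_scan"
  )
}

#' @export
print.ccc_scan <- function(x, ...) {
  cat(sprintf("<ccc_scan> %d orders (%s linkage): mean CC_c %.4f +/- %.4f\n",
              length(x$d_grid), x$linkage, x$mean_ccc, x$sd_ccc))
  cat(sprintf("  argmax d = %d (CC_c = %.4f); selected (> mean + 2 sd): %s\n",
              x$argmax_order, max(x$ccc, na.rm = TRUE),
              if (length(x$selected_orders)) paste(x$selected_orders, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Write scan results
#'
#' `write_scan_csv` writes the per-order table (d, ccc);
#' `write_scan_json` writes the selection metadata (mean, sd, selected
#' orders, argmax, seed).  `write_linkage_csv` writes a tree's standard
#' `(n-1) x 4` merge table.
#'
#' @param scan a `ccc_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(data.frame(d = scan$d_grid, ccc = scan$ccc), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_scan_json <- function(scan, path) {
  jsonlite::write_json(
    list(mean_ccc = scan$mean_ccc, sd_ccc = scan$sd_ccc,
         selected_orders = scan$selected_orders,
         argmax_order = scan$argmax_order, seed = scan$seed,
         linkage = scan$linkage, failures = scan$failures),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @param tree a `linkage_tree`.
#' @rdname write_scan_csv
#' @export
write_linkage_csv <- function(tree, path) {
  utils::write.csv(tree$merges, path, row.names = FALSE)
  invisible(path)
}
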