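# End-to-end orchestration: simulate a corpus (or take one supplied),
# build modeled-activation images, scan model orders, fractionate between
# the two preferred orders, and run the subsample robustness experiment.
# One root seed deterministically spawns every per-stage and
# per-replicate substream, so adding replicates never perturbs earlier
# stages.

#' Default model-order scan grid
#'
#' The full-database analysis grid is 20 to 200 in steps of 10 (19
#' orders).  That grid presumes thousands of experiments; for smaller
#' corpora the default shrinks so that the maximum order stays safely
#' below the achievable rank: orders `2 .. min(30, floor(e / 10))`
#' when `e < 2000`.
#'
#' @param e number of experiments.
#' @return Integer vector of model orders.
#' @export
default_model_order_grid <- function(e = 8637) {
  if (e >= 2000) return(seq(20L, 200L, by = 10L))
  hi <- max(3L, min(30L, as.integer(floor(e / 10))))
  seq(2L, hi)
}

#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end run.  Defaults follow the
#' package-wide analysis conventions: 12 mm FWHM kernels combined by
#' voxelwise max, z threshold 4, single-linkage clustering with the
#' `mean + 2 sd` selection rule, and a 10-replicate 90% subsample
#' robustness check.
#'
#' @param synth a [synth_config()] (ignored when a corpus is supplied to
#'   [run_pipeline()] directly).
#' @param spacing grid spacing in mm (default 4: the fast
#'   simulation-scale grid; use 2 for full-resolution analysis).
#' @param mask `"ellipsoid"` or `"box"` (see [default_grid()]).
#' @param fwhm kernel FWHM, mm (default 12).
#' @param combine peak combination rule, `"max"` or `"sum"`.
#' @param z_threshold significance threshold for component maps
#'   (default 4).
#' @param d_grid model-order grid; `NULL` (default) picks
#'   [default_model_order_grid()] for the corpus size.
#' @param linkage `"single"` (default) or `"average"`.
#' @param uniformity_threshold entropy cut-off for artifact flagging.
#' @param n_parent_groups number of functional groups to cut the
#'   low-order network dendrogram into when `parent_groups` is not given.
#' @param parent_groups optional named mapping parent id -> group label
#'   (the semantic grouping; inferred structurally by `cutree` otherwise).
#' @param subsample_fraction,subsample_reps robustness experiment
#'   parameters (defaults 0.9 and 10).
#' @param seed root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            spacing = 4, mask = "ellipsoid",
                            fwhm = 12, combine = "max",
                            z_threshold = 4,
                            d_grid = NULL,
                            linkage = "single",
                            uniformity_threshold = 0.95,
                            n_parent_groups = 4L,
                            parent_groups = NULL,
                            subsample_fraction = 0.9,
                            subsample_reps = 10L,
                            seed = 1L) {
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stopf("subsample_fraction must lie in (0, 1]")
  cfg <- list(
    synth = synth, spacing = spacing, mask = mask, fwhm = fwhm,
    combine = combine, z_threshold = z_threshold, d_grid = d_grid,
    linkage = linkage, uniformity_threshold = uniformity_threshold,
    n_parent_groups = as.integer(n_parent_groups),
    parent_groups = parent_groups,
    subsample_fraction = subsample_fraction,
    subsample_reps = as.integer(subsample_reps),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror the arguments of [pipeline_config()]; keys under
#' `synth:` mirror [synth_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- do.call(synth_config, y$synth %||% list())
  y$synth <- NULL
  do.call(pipeline_config, c(list(synth = synth), y))
}

log_stage <- function(log_path, ...) {
  msg <- sprintf(...)
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
      file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full pipeline
#'
#' Simulate (or accept) a corpus, build the modeled-activation matrix,
#' scan the model-order grid by CC_c, pick the two best orders
#' (selected by the `mean + 2 sd` rule when possible, topped up by rank
#' otherwise), compute z-maps for both, flag artifacts, assign parents by
#' spatial cross-correlation, group parents, and summarize fractionation.
#' All artifacts are written under `out_dir` together with a
#' machine-readable `manifest.json` (config echo, seeds, package version)
#' and a structured `run.log`.  Outputs are byte-reproducible given
#' (config, seed), timestamps in the log aside.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; default a tempdir).
#' @param corpus optional pre-built `corpus`; by default one is simulated
#'   from `config$synth`.
#' @return Invisibly, a list with `scan`, `fractionation` (summary),
#'   `assignment`, `orders` (the two compared orders), `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("coactnet_run_"),
                         corpus = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  grid <- default_grid(spacing = config$spacing, mask = config$mask)

  if (is.null(corpus)) {
    synth <- config$synth
    synth$seed <- substream_seed(config$seed, 1L)
    corpus <- build_corpus(synth, grid)
    log_stage(log_path, "simulate: %d experiments, %d classes, %d clipped peaks",
              length(corpus$experiments), nrow(corpus$label_matrix),
              corpus$n_clipped)
  }
  write_corpus(corpus, out_dir)
  e <- length(corpus$experiments)

  ma <- stack_corpus(corpus, grid, fwhm = config$fwhm, combine = config$combine)
  log_stage(log_path, "build-ma: %d voxels x %d experiments", nrow(ma$values), e)

  d_grid <- config$d_grid %||% default_model_order_grid(e)
  if (max(d_grid) > e) stopf("max(d_grid) = %d exceeds e = %d", max(d_grid), e)
  scan <- scan_model_orders(ma, corpus$label_matrix, d_grid,
                            seed = substream_seed(config$seed, 2L),
                            linkage = config$linkage)
  write_scan_csv(scan, file.path(out_dir, "ccc.csv"))
  write_scan_json(scan, file.path(out_dir, "selection.json"))
  log_stage(log_path, "scan: argmax d = %d, selected: %s", scan$argmax_order,
            paste(scan$selected_orders, collapse = ", "))

  # two orders to compare: the selection rule's picks, topped up by CC_c rank
  ok <- !is.na(scan$ccc)
  by_rank <- scan$d_grid[ok][order(scan$ccc[ok], decreasing = TRUE)]
  orders <- unique(c(scan$selected_orders, by_rank))
  orders <- orders[seq_len(min(2L, length(orders)))]
  if (length(orders) == 1L) orders <- rep(orders, 2L)  # degenerate grid: self-comparison
  orders <- sort(orders)
  d_low <- orders[1]; d_high <- orders[2]

  red <- reduce_svd(ma, d = max(orders))
  frac <- NULL; assignment <- NULL
  seed_scan <- substream_seed(config$seed, 2L)
  fit_at <- function(d) {
    ccc_for_order(red, d, corpus$label_matrix, seed_scan, config$linkage)
  }
  low <- fit_at(d_low)
  high <- if (d_high > d_low) fit_at(d_high) else low
  z_low <- to_zmaps(low$decomposition, threshold = config$z_threshold)
  z_high <- to_zmaps(high$decomposition, threshold = config$z_threshold)
  write_ma_nifti(z_low$zvalues, file.path(out_dir, sprintf("zmaps_d%02d.nii.gz", d_low)),
                 grid = grid)
  if (d_high > d_low)
    write_ma_nifti(z_high$zvalues,
                   file.path(out_dir, sprintf("zmaps_d%02d.nii.gz", d_high)),
                   grid = grid)
  write_metadata_matrix(low$meta, file.path(out_dir, sprintf("metadata_d%02d.csv", d_low)))
  if (d_high > d_low)
    write_metadata_matrix(high$meta,
                          file.path(out_dir, sprintf("metadata_d%02d.csv", d_high)))

  art_low <- flag_artifacts(low$meta, config$uniformity_threshold)
  art_high <- flag_artifacts(high$meta, config$uniformity_threshold)
  cc <- spatial_cross_correlation(z_high, z_low)
  write_fractionation_csv(cc, file.path(out_dir, "cross_correlation.csv"))
  assignment <- assign_parents(cc, artifact_high = art_high,
                               artifact_low = art_low)
  write_fractionation_csv(assignment, file.path(out_dir, "parents.csv"))

  net_tree_low <- network_hca(low$meta)
  write_linkage_csv(net_tree_low, file.path(out_dir,
                    sprintf("network_dendrogram_d%02d.csv", d_low)))
  if (d_high > d_low) {
    net_tree_high <- network_hca(high$meta)
    write_linkage_csv(net_tree_high, file.path(out_dir,
                      sprintf("network_dendrogram_d%02d.csv", d_high)))
  }
  groups <- config$parent_groups
  if (is.null(groups)) {
    k <- min(config$n_parent_groups, d_low)
    ct <- stats::cutree(net_tree_low$hclust, k = k)
    groups <- stats::setNames(sprintf("group_%d", ct), seq_len(d_low))
  }
  keep <- setdiff(seq_len(d_low), art_low)
  frac <- summarize_fractionation(assignment, groups[as.character(keep)])
  write_fractionation_csv(frac, file.path(out_dir, "fractionation_summary.csv"))
  log_stage(log_path, "fractionate: d %d -> %d, %d artifact high components",
            d_low, d_high, length(art_high))

  manifest <- list(
    package = "coactnet",
    version = as.character(utils::packageVersion("coactnet")),
    seed = config$seed,
    config = config[setdiff(names(config), "parent_groups")],
    d_grid = d_grid,
    orders_compared = orders,
    files = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(scan = scan, fractionation = frac, assignment = assignment,
                 orders = orders, out_dir = out_dir))
}

#' Subsample robustness of the model-order scan
#'
#' Repeats the scan on random subsets of the experiments (without
#' replacement) and reports per-replicate CC_c curves and their mean,
#' mirroring the database-subsampling consistency analysis.
#'
#' @param corpus a `corpus`.
#' @param grid a [volume_grid()].
#' @param d_grid model-order grid (must fit the subset size).
#' @param fraction subset fraction in `(0, 1]` (default 0.9).
#' @param reps number of replicates (default 10).
#' @param seed root seed.  Replicate `r` draws its subset from an
#'   independent substream, while every replicate's scan runs with the
#'   root seed itself -- the same ICA streams a full scan would use -- so
#'   CC_c differences across replicates reflect the data subsets, not ICA
#'   restarts, and `fraction = 1` reproduces the full scan exactly.
#' @param fwhm,combine,linkage forwarded to the stages.
#' @return A `subsample_robustness`: list with `d_grid`, `curves`
#'   (`reps x |d_grid|` matrix), `mean_curve`, `argmax_orders` (one per
#'   replicate), `mean_argmax_order` (argmax of the mean curve),
#'   `fraction`, `seed`.
#' @export
subsample_robustness <- function(corpus, grid, d_grid, fraction = 0.9,
                                 reps = 10L, seed = 1L, fwhm = 12,
                                 combine = "max", linkage = "single") {
  e <- length(corpus$experiments)
  m <- as.integer(floor(fraction * e))
  d_grid <- sort(unique(as.integer(d_grid)))
  if (m < max(d_grid))
    stopf("subset size %d is below max(d_grid) = %d", m, max(d_grid))
  ma <- stack_corpus(corpus, grid, fwhm = fwhm, combine = combine)
  curves <- matrix(NA_real_, reps, length(d_grid),
                   dimnames = list(NULL, d_grid))
  argmax <- integer(reps)
  for (r in seq_len(reps)) {
    idx <- sort(with_seed(substream_seed(seed, 33L, r), sample.int(e, m)))
    sub_ma <- ma$values[, idx, drop = FALSE]
    sub_P <- corpus$label_matrix[, idx, drop = FALSE]
    sc <- scan_model_orders(sub_ma, sub_P, d_grid, seed = seed,
                            linkage = linkage)
    curves[r, ] <- sc$ccc
    argmax[r] <- sc$argmax_order
  }
  mean_curve <- colMeans(curves, na.rm = TRUE)
  structure(
    list(
      d_grid = d_grid, curves = curves, mean_curve = mean_curve,
      argmax_orders = argmax,
      mean_argmax_order = d_grid[which.max(mean_curve)],
      fraction = fraction, reps = reps, seed = as.integer(seed)
    ),
    class = "subsample_robustness"
  )
}

#' @export
print.subsample_robustness <- function(x, ...) {
  cat(sprintf(
    "<subsample_robustness> %d replicates at %.0f%%: mean-curve argmax d = %d (replicates: %s)\n",
    x$reps, 100 * x$fraction, x$mean_argmax_order,
    paste(x$argmax_orders, collapse = ", ")
  ))
  invisible(x)
}
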