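# Synthetic coordinate corpora.  Experiments are drawn from planted latent
# spatial networks: each network is a small set of Gaussian "blobs"
# (co-activation foci) plus an associated set of metadata classes.  Peaks
# are jittered copies of blob centres; labels are noisy copies of the
# network's class set.  This reproduces the statistical structure the
# downstream analysis assumes -- spatially coherent co-activation with
# label/network correlation of configurable fidelity -- without any
# database access.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe a small but realistic desk-scale corpus: a few hundred
#' experiments, 6-12 peaks each, 6 mm peak jitter (reported stereotactic
#' coordinates scatter on roughly that scale across laboratories), labels
#' kept with probability 0.9 and foreign labels added at rate 0.05.
#'
#' @param k_networks number of planted networks.
#' @param e_experiments number of experiments.
#' @param peaks_per_experiment integer range `c(min, max)` of peaks drawn
#'   per experiment (uniform).
#' @param blobs_per_network integer range `c(min, max)` of Gaussian foci
#'   per network.
#' @param peak_jitter_sd isotropic Gaussian jitter sd around a focus, mm.
#' @param label_fidelity probability each of the generating network's
#'   classes is attached to an experiment.
#' @param false_label_rate probability each foreign class is attached.
#' @param classes_per_network metadata classes owned by each network;
#'   either a scalar or a length-`k_networks` vector (unequal values
#'   emulate the uneven class-frequency profile of real taxonomies).
#' @param blob_spread sd (mm) of blob-centre placement around the network
#'   centroid: networks are compact clusters of foci, and neighbouring
#'   networks' foci may approach each other, as real co-activation
#'   networks share cortical territory.
#' @param min_network_separation minimum pairwise distance between network
#'   centroids, mm.
#' @param blob_activation_prob probability each blob of the generating
#'   network is active in a given experiment (at least one is always
#'   kept).  Values below 1 make foci co-activate only partially, so a
#'   network is a statistical composite of its sub-patterns -- the
#'   hierarchical structure that lets low model orders recover whole
#'   networks and high orders their sub-networks.
#' @param background_peak_rate probability any given peak is an
#'   idiosyncratic background focus -- uniform over the mask instead of
#'   network-derived -- emulating the scattered non-network activations
#'   real experiments report.  Gives every voxel activation support, so
#'   component backgrounds have a genuine null scale.
#' @param mixture_prob probability an experiment draws peaks from two
#'   networks instead of one (off by default: single-network experiments
#'   keep the planted structure recoverable).
#' @param seed integer seed; the corpus is a pure function of
#'   (config, grid).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(k_networks = 5,
                         e_experiments = 300,
                         peaks_per_experiment = c(6L, 12L),
                         blobs_per_network = c(2L, 4L),
                         peak_jitter_sd = 6,
                         label_fidelity = 0.9,
                         false_label_rate = 0.02,
                         classes_per_network = 4L,
                         blob_spread = 18,
                         min_network_separation = 40,
                         blob_activation_prob = 0.6,
                         background_peak_rate = 0.15,
                         mixture_prob = 0,
                         seed = 1L) {
  cfg <- list(
    k_networks = as.integer(k_networks),
    e_experiments = as.integer(e_experiments),
    peaks_per_experiment = as.integer(peaks_per_experiment),
    blobs_per_network = as.integer(blobs_per_network),
    peak_jitter_sd = peak_jitter_sd,
    label_fidelity = label_fidelity,
    false_label_rate = false_label_rate,
    classes_per_network = as.integer(classes_per_network),
    blob_spread = blob_spread,
    min_network_separation = min_network_separation,
    blob_activation_prob = blob_activation_prob,
    background_peak_rate = background_peak_rate,
    mixture_prob = mixture_prob,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$k_networks < 0) stopf("k_networks must be >= 0")
  if (cfg$e_experiments < 0) stopf("e_experiments must be >= 0")
  for (p in c("label_fidelity", "false_label_rate", "mixture_prob",
              "background_peak_rate", "blob_activation_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("'%s' must lie in [0, 1]", p)
  if (cfg$peak_jitter_sd < 0) stopf("peak_jitter_sd must be >= 0")
  if (cfg$blob_spread < 0) stopf("blob_spread must be >= 0")
  if (cfg$min_network_separation < 0) stopf("min_network_separation must be >= 0")
  for (r in c("peaks_per_experiment", "blobs_per_network")) {
    rng <- cfg[[r]]
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1)
      stopf("'%s' must be a non-empty positive integer range c(min, max)", r)
  }
  if (!length(cfg$classes_per_network) %in% c(1L, cfg$k_networks) ||
      any(cfg$classes_per_network < 1))
    stopf("classes_per_network must be a positive scalar or one value per network")
  invisible(cfg)
}

#' Plant ground-truth networks in a grid
#'
#' Draws `k_networks` networks by rejection sampling: a network is a
#' compact cluster of blob centres scattered (`blob_spread` mm sd) around
#' a seed point uniform over in-mask voxel centres, clipped to the mask.
#' A candidate is accepted only if its blob centroid lies at least
#' `min_network_separation` mm from all previously accepted centroids
#' (foci of neighbouring networks may still interleave, as in real
#' cortical topography).  Each network owns `classes_per_network` metadata
#' classes, disjoint across networks.
#'
#' @param config a [synth_config()].
#' @param grid a [volume_grid()].
#' @return List of `ground_truth_network` objects, each with fields
#'   `network_id`, `blob_centers` (matrix, mm), `blob_sigma`, `class_ids`.
#' @export
make_ground_truth <- function(config, grid) {
  stopifnot(inherits(config, "synth_config"), inherits(grid, "volume_grid"))
  if (config$k_networks == 0) return(list())
  coords <- grid_coords(grid)
  cpn <- rep_len(config$classes_per_network, config$k_networks)
  class_hi <- cumsum(cpn)
  class_lo <- class_hi - cpn + 1L
  with_seed(substream_seed(config$seed, 101L), {
    centroids <- matrix(NA_real_, 0, 3)
    nets <- vector("list", config$k_networks)
    max_tries <- 1000L * config$k_networks
    tries <- 0L
    k <- 1L
    while (k <= config$k_networks) {
      tries <- tries + 1L
      if (tries > max_tries)
        stopf(paste0(
          "could not place %d networks with min separation %g mm in the mask ",
          "after %d rejection-sampling attempts"),
          config$k_networks, config$min_network_separation, max_tries)
      nb <- sample(config$blobs_per_network[1]:config$blobs_per_network[2], 1)
      seed_ctr <- coords[sample.int(nrow(coords), 1), ]
      # foci scatter around a seed point; clip keeps them in-mask
      ctr <- matrix(rep(seed_ctr, each = nb), nb, 3) +
        matrix(stats::rnorm(3 * nb, sd = config$blob_spread), nb, 3)
      for (b in seq_len(nb))
        ctr[b, ] <- clip_to_mask(grid, ctr[b, ], coords)$xyz
      cen <- colMeans(ctr)
      if (nrow(centroids) > 0) {
        d <- sqrt(rowSums(sweep(centroids, 2, cen)^2))
        if (any(d < config$min_network_separation)) next
      }
      centroids <- rbind(centroids, cen)
      nets[[k]] <- structure(
        list(
          network_id = k,
          blob_centers = ctr,
          blob_sigma = max(config$peak_jitter_sd, 1e-8),
          class_ids = seq.int(class_lo[k], class_hi[k])
        ),
        class = "ground_truth_network"
      )
      k <- k + 1L
    }
    nets
  })
}

# all class ids across a ground-truth list
all_class_ids <- function(networks) {
  sort(unique(unlist(lapply(networks, `[[`, "class_ids"))))
}

#' Sample one experiment from a planted network
#'
#' Peak count is uniform on the configured range; each peak is a uniformly
#' chosen centre among the experiment's active blobs (each blob of the
#' network participates with probability `blob_activation_prob`) plus
#' isotropic Gaussian jitter; a configurable
#' fraction of peaks are instead uniform background foci.  Each of the
#' network's classes is kept with probability `label_fidelity`; each
#' foreign class is attached with probability `false_label_rate`.  Uses the
#' current RNG state (callers seed it; [build_corpus()] does so per
#' experiment so corpora are reproducible).
#'
#' @param network a `ground_truth_network`.
#' @param config a [synth_config()].
#' @param grid a [volume_grid()]; jittered peaks falling outside the mask
#'   are clipped to the nearest in-mask voxel centre (preserves peak count
#'   and determinism).
#' @param all_classes integer vector of every class id in the corpus.
#' @param mask_coords optional precomputed [grid_coords()] for clipping.
#' @param experiment_id identifier to attach.
#' @return An `experiment`: list with `experiment_id`, `peaks`
#'   (matrix n x 3, mm), `labels` (integer class ids), `n_clipped`.
#' @export
sample_experiment <- function(network, config, grid, all_classes,
                              mask_coords = NULL, experiment_id = NA) {
  n_peaks <- sample(config$peaks_per_experiment[1]:config$peaks_per_experiment[2], 1)
  nb <- nrow(network$blob_centers)
  active <- which(stats::runif(nb) < config$blob_activation_prob)
  if (length(active) == 0) active <- sample.int(nb, 1)
  idx <- active[sample.int(length(active), n_peaks, replace = TRUE)]
  peaks <- network$blob_centers[idx, , drop = FALSE]
  if (config$background_peak_rate > 0) {
    bg <- stats::runif(n_peaks) < config$background_peak_rate
    if (any(bg)) {
      if (is.null(mask_coords)) mask_coords <- grid_coords(grid)
      peaks[bg, ] <- mask_coords[sample.int(nrow(mask_coords), sum(bg),
                                            replace = TRUE), , drop = FALSE]
    }
  }
  if (config$peak_jitter_sd > 0)
    peaks <- peaks + matrix(stats::rnorm(3 * n_peaks, sd = config$peak_jitter_sd),
                            n_peaks, 3)
  n_clipped <- 0L
  for (i in seq_len(n_peaks)) {
    cl <- clip_to_mask(grid, peaks[i, ], mask_coords)
    if (cl$clipped) {
      peaks[i, ] <- cl$xyz
      n_clipped <- n_clipped + 1L
    }
  }
  own <- network$class_ids
  keep <- own[stats::runif(length(own)) < config$label_fidelity]
  foreign <- setdiff(all_classes, own)
  false_pos <- foreign[stats::runif(length(foreign)) < config$false_label_rate]
  structure(
    list(
      experiment_id = experiment_id,
      peaks = peaks,
      labels = sort(c(keep, false_pos)),
      n_clipped = n_clipped
    ),
    class = "experiment"
  )
}

#' Build a synthetic corpus
#'
#' Plants ground-truth networks, assigns experiments to networks
#' round-robin (balanced within one experiment), samples each experiment,
#' and assembles the binary class-by-experiment label matrix `P`.
#'
#' @param config a [synth_config()].
#' @param grid a [volume_grid()].
#' @return A `corpus`: list with `experiments` (list of `experiment`),
#'   `label_matrix` (binary n classes x e experiments, dimnames set),
#'   `class_names`, `ground_truth` (list of networks),
#'   `network_of` (integer, generating network per experiment),
#'   `n_clipped` (total clipped peaks).
#' @export
build_corpus <- function(config, grid) {
  stopifnot(inherits(config, "synth_config"), inherits(grid, "volume_grid"))
  networks <- make_ground_truth(config, grid)
  if (length(networks) == 0 && config$e_experiments > 0)
    stopf("cannot sample experiments from zero networks")
  classes <- all_class_ids(networks)
  n <- length(classes)
  e <- config$e_experiments
  mask_coords <- grid_coords(grid)
  network_of <- if (e > 0) ((seq_len(e) - 1L) %% config$k_networks) + 1L else integer(0)
  experiments <- vector("list", e)
  for (j in seq_len(e)) {
    experiments[[j]] <- with_seed(substream_seed(config$seed, 202L, j), {
      net <- networks[[network_of[j]]]
      if (config$mixture_prob > 0 && config$k_networks > 1 &&
          stats::runif(1) < config$mixture_prob) {
        other <- networks[[sample(setdiff(seq_along(networks), net$network_id), 1)]]
        mix <- net
        mix$blob_centers <- rbind(net$blob_centers, other$blob_centers)
        mix$class_ids <- sort(union(net$class_ids, other$class_ids))
        net <- mix
      }
      sample_experiment(net, config, grid, classes, mask_coords,
                        experiment_id = sprintf("exp%04d", j))
    })
  }
  P <- matrix(0L, n, e,
              dimnames = list(sprintf("class%03d", classes),
                              vapply(experiments, `[[`, "", "experiment_id")))
  for (j in seq_len(e)) P[match(experiments[[j]]$labels, classes), j] <- 1L
  structure(
    list(
      experiments = experiments,
      label_matrix = P,
      class_names = rownames(P),
      ground_truth = networks,
      network_of = network_of,
      n_clipped = sum(vapply(experiments, `[[`, 0L, "n_clipped")),
      config = config
    ),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus> %d experiments, %d metadata classes, %d planted networks (%d clipped peaks)\n",
    length(x$experiments), nrow(x$label_matrix),
    length(x$ground_truth), x$n_clipped
  ))
  invisible(x)
}

#' Export / import a corpus as plain text
#'
#' Writes `peaks.csv` (experiment_id, x, y, z; one row per peak),
#' `labels.csv` (class x experiment binary table, experiment ids as
#' header), and, when present, `ground_truth.json`.
#'
#' @param corpus a `corpus`.
#' @param dir output directory (created if needed).
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` returns a
#'   `corpus` (without planted ground truth unless the JSON file exists).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pk <- do.call(rbind, lapply(corpus$experiments, function(ex) {
    data.frame(experiment_id = ex$experiment_id,
               x = ex$peaks[, 1], y = ex$peaks[, 2], z = ex$peaks[, 3])
  }))
  utils::write.csv(pk, file.path(dir, "peaks.csv"), row.names = FALSE)
  lab <- data.frame(class = rownames(corpus$label_matrix), corpus$label_matrix,
                    check.names = FALSE)
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  if (length(corpus$ground_truth) > 0) {
    gt <- lapply(corpus$ground_truth, function(nw) list(
      network_id = nw$network_id,
      blob_centers = unname(apply(nw$blob_centers, 1, as.numeric, simplify = FALSE)),
      blob_sigma = nw$blob_sigma,
      class_ids = nw$class_ids
    ))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  pk <- utils::read.csv(file.path(dir, "peaks.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"), check.names = FALSE)
  P <- as.matrix(lab[, -1, drop = FALSE])
  storage.mode(P) <- "integer"
  rownames(P) <- lab$class
  ids <- colnames(P)
  experiments <- lapply(ids, function(id) {
    rows <- pk$experiment_id == id
    structure(
      list(
        experiment_id = id,
        peaks = as.matrix(pk[rows, c("x", "y", "z")]),
        labels = which(P[, id] == 1L),
        n_clipped = 0L
      ),
      class = "experiment"
    )
  })
  gt <- list()
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- lapply(seq_len(nrow(raw)), function(i) {
      bc <- raw$blob_centers[[i]]
      if (!is.matrix(bc)) bc <- do.call(rbind, bc)
      structure(
        list(
          network_id = raw$network_id[i],
          blob_centers = bc,
          blob_sigma = raw$blob_sigma[i],
          class_ids = raw$class_ids[[i]]
        ),
        class = "ground_truth_network"
      )
    })
  }
  structure(
    list(
      experiments = experiments, label_matrix = P, class_names = rownames(P),
      ground_truth = gt, network_of = NULL,
      n_clipped = 0L, config = NULL
    ),
    class = "corpus"
  )
}
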