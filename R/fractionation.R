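# Fractionation tracking between a low-order and a high-order
# decomposition: spatial cross-correlation of unthresholded z-maps,
# parent assignment by maximal correlation, metadata-space clustering of
# networks, entropy-based artifact flagging, and per-group fractionation
# rates.

#' Spatial cross-correlation between two sets of component maps
#'
#' Entry (i, j) is the Pearson correlation over in-mask voxels between
#' unthresholded z-map `i` of the high-order decomposition and z-map `j`
#' of the low-order one (the `fslcc`-style similarity).  An optional
#' threshold zeroes sub-threshold voxels first (sensitivity analysis;
#' default uses the full unthresholded maps).
#'
#' @param zmaps_high,zmaps_low `zmaps` objects on the same grid (their
#'   `zvalues` must have the same number of voxels).
#' @param threshold optional z threshold applied before correlating.
#' @return Numeric matrix `d_high x d_low` of class `cross_corr`, entries
#'   in `[-1, 1]`, `NA` where a map is constant (with a warning).
#' @export
spatial_cross_correlation <- function(zmaps_high, zmaps_low, threshold = NULL) {
  Zh <- if (inherits(zmaps_high, "zmaps")) zmaps_high$zvalues else as.matrix(zmaps_high)
  Zl <- if (inherits(zmaps_low, "zmaps")) zmaps_low$zvalues else as.matrix(zmaps_low)
  if (ncol(Zh) != ncol(Zl))
    stopf("map sets are on different grids (%d vs %d voxels)", ncol(Zh), ncol(Zl))
  if (!is.null(threshold)) {
    Zh[Zh <= threshold] <- 0
    Zl[Zl <= threshold] <- 0
  }
  const_h <- apply(Zh, 1, function(r) max(r) == min(r))
  const_l <- apply(Zl, 1, function(r) max(r) == min(r))
  if (any(const_h) || any(const_l))
    warnf("constant map(s): %d high, %d low; their correlations are NA",
          sum(const_h), sum(const_l))
  cc <- suppressWarnings(stats::cor(t(Zh), t(Zl)))
  cc[const_h, ] <- NA_real_
  cc[, const_l] <- NA_real_
  rownames(cc) <- sprintf("high%02d", seq_len(nrow(cc)))
  colnames(cc) <- sprintf("low%02d", seq_len(ncol(cc)))
  class(cc) <- c("cross_corr", class(cc))
  cc
}

#' Assign each high-order component to its low-order parent
#'
#' The parent of a non-artifact high-order component is the non-artifact
#' low-order component with the largest cross-correlation; exact ties go
#' to the lower component id.  Components listed as artifacts receive no
#' parent.
#'
#' @param cc a `cross_corr` matrix (`d_high x d_low`).
#' @param artifact_high,artifact_low integer ids of components excluded
#'   from assignment.
#' @return A `parent_assignment` data.frame: `high`, `parent` (`NA` for
#'   artifacts), `correlation`.
#' @export
assign_parents <- function(cc, artifact_high = integer(0),
                           artifact_low = integer(0)) {
  cc <- unclass(cc)
  d_high <- nrow(cc); d_low <- ncol(cc)
  keep_low <- setdiff(seq_len(d_low), artifact_low)
  if (length(keep_low) == 0) stopf("every low-order component is an artifact")
  out <- data.frame(high = seq_len(d_high), parent = NA_integer_,
                    correlation = NA_real_)
  for (i in seq_len(d_high)) {
    if (i %in% artifact_high) next
    r <- cc[i, keep_low]
    if (all(is.na(r))) stopf("component %d correlates NA with every parent", i)
    best <- keep_low[which.max(r)]   # first max => lower id on ties
    out$parent[i] <- best
    out$correlation[i] <- cc[i, best]
  }
  class(out) <- c("parent_assignment", class(out))
  out
}

#' Cluster networks (components) in metadata space
#'
#' Transposes the metadata matrix and reuses the class-clustering
#' machinery: single-linkage over `1 - Pearson r` distances between
#' component columns of `P_d`.
#'
#' @param meta a `metadata_matrix` with `d >= 2`.
#' @param method linkage, `"single"` (default) or `"average"`.
#' @return A `linkage_tree` over the `d` components.
#' @export
network_hca <- function(meta, method = "single") {
  M <- if (is.list(meta) && !is.null(meta$values)) meta$values else as.matrix(meta)
  if (ncol(M) < 2) stopf("need at least 2 components for network clustering")
  tm <- t(M)
  rownames(tm) <- sprintf("component%02d", seq_len(nrow(tm)))
  single_linkage(class_distances(tm), method = method)
}

#' Flag artifact components by metadata uniformity
#'
#' A component whose metadata column weights every class near-equally is
#' uninterpretable as a functional network.  The flag criterion is the
#' normalized Shannon entropy of the absolute column weights
#' (`H / log(n)`, 1 for perfectly uniform, 0 for one-hot) exceeding
#' `uniformity_threshold`.  Manual overrides win over the entropy rule.
#'
#' @param meta a `metadata_matrix`.
#' @param uniformity_threshold entropy cut-off in `[0, 1]` (default 0.95).
#' @param include component ids always flagged; `exclude` never flagged.
#' @return Integer vector of flagged component ids, with the per-component
#'   entropies attached as attribute `"entropy"`.
#' @export
flag_artifacts <- function(meta, uniformity_threshold = 0.95,
                           include = integer(0), exclude = integer(0)) {
  M <- if (is.list(meta) && !is.null(meta$values)) meta$values else as.matrix(meta)
  n <- nrow(M)
  ent <- apply(abs(M), 2, function(col) {
    s <- sum(col)
    if (s == 0) return(1)          # no metadata signal at all: uniform limit
    p <- col[col > 0] / s
    -sum(p * log(p)) / log(n)
  })
  flagged <- which(ent > uniformity_threshold)
  flagged <- sort(setdiff(union(flagged, include), exclude))
  attr(flagged, "entropy") <- ent
  flagged
}

#' Per-group fractionation summary
#'
#' For each functional group of low-order parents: the number of parents,
#' the number of high-order sub-networks assigned to those parents, and
#' the fractionation rate `n_subnetworks / n_parents`.  Rates are held at
#' full precision; the print method and CSV writer round to 2 decimals.
#'
#' @param assignment a `parent_assignment`.
#' @param group_of_parent named mapping (names = parent ids, values =
#'   group labels) or a vector of group labels indexed by parent id; every
#'   parent id occurring in `assignment` must be covered.  A factor with
#'   unused levels reports those groups with zero parents and an
#'   undefined (`NA`) rate.
#' @return A `fractionation_summary` data.frame: `group`, `n_parents`,
#'   `n_subnetworks`, `rate` (`NA` for groups with zero parents).
#' @export
summarize_fractionation <- function(assignment, group_of_parent) {
  if (is.null(names(group_of_parent)))
    names(group_of_parent) <- seq_along(group_of_parent)
  assigned <- assignment$parent[!is.na(assignment$parent)]
  miss <- setdiff(as.character(assigned), names(group_of_parent))
  if (length(miss))
    stopf("no group label for parent component(s): %s", paste(miss, collapse = ", "))
  groups <- if (is.factor(group_of_parent)) levels(group_of_parent)
            else unique(unname(group_of_parent))
  group_of_parent <- stats::setNames(as.character(group_of_parent),
                                     names(group_of_parent))
  out <- data.frame(group = groups, n_parents = 0L, n_subnetworks = 0L,
                    rate = NA_real_)
  for (g in seq_along(groups)) {
    parents <- as.integer(names(group_of_parent)[group_of_parent == groups[g]])
    out$n_parents[g] <- length(parents)
    out$n_subnetworks[g] <- sum(assigned %in% parents)
    if (out$n_parents[g] > 0)
      out$rate[g] <- out$n_subnetworks[g] / out$n_parents[g]
  }
  class(out) <- c("fractionation_summary", class(out))
  out
}

#' @export
print.fractionation_summary <- function(x, ...) {
  df <- as.data.frame(unclass(x))
  df$rate <- round(df$rate, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write fractionation outputs
#'
#' @param x a `cross_corr`, `parent_assignment`, or
#'   `fractionation_summary`.
#' @param path output CSV path (for the summary a sibling `.json` is also
#'   written when `json = TRUE`).
#' @param json also write the summary as JSON (default TRUE).
#' @return `path`, invisibly.
#' @export
write_fractionation_csv <- function(x, path, json = TRUE) {
  if (inherits(x, "cross_corr")) {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  } else if (inherits(x, "fractionation_summary")) {
    df <- as.data.frame(unclass(x))
    df$rate <- round(df$rate, 2)
    utils::write.csv(df, path, row.names = FALSE)
    if (json)
      jsonlite::write_json(df, sub("\\.csv$", ".json", path),
                           auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  }
  invisible(path)
}
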