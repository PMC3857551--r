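# Modeled-activation (MA) images: each experiment's peak coordinates are
# replaced by an unnormalized Gaussian kernel of unit peak height, and the
# per-experiment volumes are stacked into the voxels x experiments matrix
# that spatial ICA consumes.

#' Convert a Gaussian FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * ln 2))`.
#'
#' @param fwhm full width at half maximum, mm (> 0).
#' @return Standard deviation in mm.
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (!is.numeric(fwhm) || any(fwhm <= 0)) stopf("'fwhm' must be positive")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Modeled-activation volume for one peak list
#'
#' Each peak contributes `exp(-||x - peak||^2 / (2 sigma^2))` evaluated at
#' voxel centres (unit height at the peak, value 0.5 at distance
#' `fwhm / 2`).  Contributions from multiple peaks combine voxelwise by
#' `max` (default; an experiment with many nearby peaks cannot exceed 1) or
#' `sum`.  Kernels are truncated at `6 sigma`, below 2e-8 of peak height.
#' Out-of-mask voxels are zero.
#'
#' @param peaks numeric matrix `n x 3` of mm coordinates (>= 1 row).
#' @param grid a [volume_grid()].
#' @param fwhm kernel FWHM in mm (default 12).
#' @param combine `"max"` or `"sum"`.
#' @return Numeric array of dimension `grid$dims`.
#' @export
modeled_activation <- function(peaks, grid, fwhm = 12, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  stopifnot(inherits(grid, "volume_grid"))
  peaks <- rbind(peaks)
  if (nrow(peaks) == 0) stopf("at least one peak is required")
  if (ncol(peaks) != 3 || !all(is.finite(peaks))) stopf("peaks must be finite n x 3")
  sigma <- fwhm_to_sigma(fwhm)
  trunc_mm <- 6 * sigma
  vol <- array(0, dim = grid$dims)
  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  for (p in seq_len(nrow(peaks))) {
    pk <- peaks[p, ]
    rng <- lapply(1:3, function(a) {
      which(abs(ax[[a]] - pk[a]) <= trunc_mm)
    })
    if (any(lengths(rng) == 0)) next
    gx <- exp(-(ax[[1]][rng[[1]]] - pk[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - pk[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - pk[3])^2 / (2 * sigma^2))
    patch <- outer(outer(gx, gy), gz)
    if (combine == "max") {
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        pmax(vol[rng[[1]], rng[[2]], rng[[3]]], patch)
    } else {
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        vol[rng[[1]], rng[[2]], rng[[3]]] + patch
    }
  }
  vol[!grid$mask] <- 0
  vol
}

#' Stack a corpus into a modeled-activation matrix
#'
#' Column `j` is the masked flattening of
#' `modeled_activation(corpus$experiments[[j]]$peaks)`; column order equals
#' experiment order.
#'
#' @param corpus a `corpus` (or any list with `experiments`).
#' @param grid a [volume_grid()].
#' @inheritParams modeled_activation
#' @return An `ma_matrix`: list with `values` (v in-mask voxels x
#'   e experiments), `grid`, `voxel_index` (linear index into the grid
#'   array per matrix row), `fwhm`, `combine`.
#' @export
stack_corpus <- function(corpus, grid, fwhm = 12, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  exps <- corpus$experiments
  e <- length(exps)
  if (e == 0) stopf("corpus has no experiments")
  for (ex in exps)
    if (is.null(ex$peaks) || nrow(rbind(ex$peaks)) == 0)
      stopf("experiment '%s' has no peaks", ex$experiment_id)
  values <- matrix(0, grid$n_voxels, e)
  for (j in seq_len(e)) {
    vol <- modeled_activation(exps[[j]]$peaks, grid, fwhm, combine)
    values[, j] <- vol[grid$mask_idx]
  }
  colnames(values) <- vapply(exps, function(ex) as.character(ex$experiment_id), "")
  structure(
    list(values = values, grid = grid, voxel_index = grid$mask_idx,
         fwhm = fwhm, combine = combine),
    class = "ma_matrix"
  )
}

#' @export
print.ma_matrix <- function(x, ...) {
  cat(sprintf("<ma_matrix> %d voxels x %d experiments (FWHM %g mm, combine=%s)\n",
              nrow(x$values), ncol(x$values), x$fwhm, x$combine))
  invisible(x)
}

# unflatten one masked column back to a full 3D array
unmask_volume <- function(v, grid) {
  vol <- array(0, dim = grid$dims)
  vol[grid$mask_idx] <- v
  vol
}

#' Write a stacked MA matrix (or z-maps) as 4D NIfTI-1
#'
#' The 4th dimension indexes experiments (or components).
#'
#' @param x an `ma_matrix`, or a numeric matrix `m x v` with rows as
#'   volumes together with `grid`.
#' @param path output `.nii` / `.nii.gz` file.
#' @param grid required when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_ma_nifti <- function(x, path, grid = NULL) {
  if (inherits(x, "ma_matrix")) {
    grid <- x$grid
    m <- t(x$values)
  } else {
    stopifnot(inherits(grid, "volume_grid"))
    m <- x
  }
  arr <- array(0, dim = c(grid$dims, nrow(m)))
  for (i in seq_len(nrow(m))) arr[, , , i] <- unmask_volume(m[i, ], grid)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(rep(grid$spacing, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI written by [write_ma_nifti()] back into a matrix
#'
#' @param path NIfTI file.
#' @param grid the [volume_grid()] the file was written on.
#' @return Numeric matrix `v x n` (in-mask voxels x volumes).
#' @export
read_ma_nifti <- function(path, grid) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  n <- if (length(dim(arr)) == 4) dim(arr)[4] else 1
  out <- matrix(0, grid$n_voxels, n)
  for (i in seq_len(n)) {
    vol <- if (length(dim(arr)) == 4) arr[, , , i] else arr
    out[, i] <- vol[grid$mask_idx]
  }
  out
}
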