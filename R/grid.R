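# Volume grids: the sampling lattice and analysis mask that modeled
# activation images live on.  Coordinates are millimetres in a
# Talairach-like stereotactic frame; the grid is isotropic.

#' Construct a volume grid
#'
#' A `volume_grid` holds an isotropic 3D sampling lattice and a binary
#' analysis mask.  Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param origin numeric length-3, mm coordinate of the first voxel centre.
#' @param spacing positive scalar, isotropic voxel size in mm.
#' @param dims integer length-3, number of voxels along x, y, z.
#' @param mask logical array of dimension `dims`, or `NULL` for all-true.
#' @return An object of class `volume_grid` with fields `origin`, `spacing`,
#'   `dims`, `mask`, and cached `mask_idx` (linear indices of in-mask
#'   voxels) and `n_voxels` (their count).
#' @seealso [default_grid()] for the standard whole-brain grid.
#' @export
volume_grid <- function(origin, spacing, dims, mask = NULL) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stopf("'spacing' must be a positive scalar (mm)")
  dims <- as.integer(dims)
  if (any(dims < 1)) stopf("'dims' must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!identical(dim(mask), dims)) stopf("mask dimensions do not match 'dims'")
  mask <- array(as.logical(mask), dim = dims)
  if (!any(mask)) stopf("mask must contain at least one voxel")
  g <- list(
    origin = as.numeric(origin), spacing = as.numeric(spacing),
    dims = dims, mask = mask,
    mask_idx = which(mask), n_voxels = sum(mask)
  )
  class(g) <- "volume_grid"
  g
}

#' Standard whole-brain grid
#'
#' An isotropic grid over the Talairach-like bounding box
#' x in \[-90, 90\], y in \[-126, 90\], z in \[-72, 108\] mm with an
#' ellipsoidal brain-shaped analysis mask inscribed in the box.  2 mm
#' spacing is the analysis default; 4 mm gives a fast grid for simulation
#' studies and tests.
#'
#' @param spacing voxel size in mm (default 2).
#' @param mask one of `"ellipsoid"` (default) or `"box"`.
#' @return A [volume_grid()].
#' @export
default_grid <- function(spacing = 2, mask = c("ellipsoid", "box")) {
  mask <- match.arg(mask)
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  dims <- floor((hi - lo) / spacing) + 1L
  g <- volume_grid(origin = lo, spacing = spacing, dims = dims)
  if (mask == "ellipsoid") {
    ctr <- lo + (dims - 1) * spacing / 2
    semi <- (dims - 1) * spacing / 2
    cx <- (grid_axis(g, 1) - ctr[1]) / semi[1]
    cy <- (grid_axis(g, 2) - ctr[2]) / semi[2]
    cz <- (grid_axis(g, 3) - ctr[3]) / semi[3]
    r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    g <- volume_grid(lo, spacing, dims, mask = r2 <= 1)
  }
  g
}

# voxel-centre coordinates along one axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing
}

#' Millimetre coordinates of in-mask voxel centres
#'
#' @param grid a [volume_grid()].
#' @return Numeric matrix `n_voxels x 3` (mm), rows in the same order as
#'   the rows of a modeled-activation matrix built on this grid.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  ijk <- arrayInd(grid$mask_idx, grid$dims)
  sweep(sweep(ijk - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# nearest voxel index (1-based triple) for an mm coordinate, clamped to grid
nearest_voxel <- function(grid, xyz) {
  ijk <- round((xyz - grid$origin) / grid$spacing) + 1
  pmin(pmax(ijk, 1), grid$dims)
}

# clip an mm coordinate to the nearest in-mask voxel centre; returns
# list(xyz, clipped)
clip_to_mask <- function(grid, xyz, mask_coords = NULL) {
  ijk <- nearest_voxel(grid, xyz)
  lin <- ijk[1] + grid$dims[1] * (ijk[2] - 1 + grid$dims[2] * (ijk[3] - 1))
  hi <- grid$origin + (grid$dims - 1) * grid$spacing
  inside <- all(xyz >= grid$origin - 1e-9) && all(xyz <= hi + 1e-9) &&
    grid$mask[lin]
  if (inside) return(list(xyz = xyz, clipped = FALSE))
  if (is.null(mask_coords)) mask_coords <- grid_coords(grid)
  d2 <- (mask_coords[, 1] - xyz[1])^2 + (mask_coords[, 2] - xyz[2])^2 +
    (mask_coords[, 3] - xyz[3])^2
  list(xyz = mask_coords[which.min(d2), ], clipped = TRUE)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels at %g mm, %d in mask (%.0f%%)\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_voxels,
    100 * x$n_voxels / prod(x$dims)
  ))
  invisible(x)
}

#' Write / read a grid mask as NIfTI-1
#'
#' @param grid a [volume_grid()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `write_mask_nifti` returns `path` invisibly; `read_mask_nifti`
#'   returns a [volume_grid()].
#' @export
write_mask_nifti <- function(grid, path) {
  img <- RNifti::asNifti(array(as.numeric(grid$mask), dim = grid$dims),
                         reference = NULL)
  img <- RNifti::`pixdim<-`(img, rep(grid$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param origin mm coordinate of the first voxel centre to attach on read
#'   (NIfTI origin handling is deliberately not interpreted).
#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, origin = c(-90, -126, -72)) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img) != 0, dim = dim(img))
  volume_grid(origin, RNifti::pixdim(img)[1], dim(img), mask = arr)
}
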