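#' Reconstruction grid specification
#'
#' Defines the voxel lattice of a reconstructed SPECT volume: the number of
#' voxels along each axis and the physical voxel spacing in millimetres.
#' Voxel centres are at `(i - 0.5) * spacing` along each axis, so the grid
#' extent along axis `k` is `shape[k] * spacing[k]` mm.
#'
#' The default (128^3 voxels at 3.3 mm isotropic) mirrors a 128 x 128
#' clinical acquisition matrix reconstructed with a zoom factor of 1.5.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3 (or 1, recycled), mm per voxel.
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(c(64, 64, 64), 3.3)
#' voxel_volume_mL(g)
#' @export
grid_spec <- function(shape = c(128L, 128L, 128L), spacing = 3.3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be three positive integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(list(shape = shape, spacing = spacing), class = "grid_spec")
}

#' Voxel volume of a grid in millilitres
#'
#' @param grid a [grid_spec()].
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  prod(grid$spacing) / 1000
}

#' Physical extent of a grid in mm per axis
#' @param grid a [grid_spec()].
#' @return numeric length 3, mm.
#' @export
grid_extent_mm <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$shape * grid$spacing
}

#' Voxel-centre coordinates along one axis
#' @keywords internal
axis_centres <- function(grid, axis) {
  (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("SPECT reconstruction grid: %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  voxel volume %.6g mL, extent %.4g x %.4g x %.4g mm\n",
              voxel_volume_mL(x), grid_extent_mm(x)[1], grid_extent_mm(x)[2],
              grid_extent_mm(x)[3]))
  invisible(x)
}

#' Construct an activity volume
#'
#' Container for a reconstructed count map: a 3-D array of non-negative voxel
#' counts plus its [grid_spec()] and simulation provenance (blur FWHM, noise
#' flag, seed).
#'
#' @param values numeric 3-D array of voxel counts (non-negative, finite).
#' @param grid a [grid_spec()] whose shape matches `dim(values)`.
#' @param meta list of provenance fields (fwhm_mm, noise, seed, ...).
#' @return An `activity_volume` object.
#' @export
activity_volume <- function(values, grid, meta = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!all(dim(values) == grid$shape))
    stop("values dimensions do not match grid shape")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("values must be non-negative")
  structure(list(values = values, grid = grid, meta = meta),
            class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("Activity volume (reconstructed counts)\n")
  print(x$grid)
  cat(sprintf("  total counts %.6g, max %.6g\n", sum(x$values), max(x$values)))
  if (length(x$meta)) {
    keys <- vapply(names(x$meta), function(k)
      sprintf("%s=%s", k, format(x$meta[[k]])), character(1))
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}
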