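#' Label 6-connected components of a 3-D mask
#'
#' Flood-fill labelling with face (6-) connectivity. Used to keep only the
#' largest connected object after iso-contour thresholding.
#'
#' @param mask logical 3-D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1; attribute `n_components`.
#' @export
label_components <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3-D array")
  .label_components6(mask, as.integer(dim(mask)))
}

#' Fixed-threshold iso-contour segmentation
#'
#' Segments the object in an activity volume by thresholding at a fixed
#' percentage of the reference maximum (the maximum voxel value inside the
#' analysis box, or the whole grid when no box is given), then keeping the
#' largest 6-connected component. The estimated volume is exactly the mask
#' voxel count times the voxel volume; no sub-voxel interpolation is done.
#'
#' Thresholding relative to the maximum within `roi_box` (rather than the
#' image maximum) lets liver and spleen be contoured independently from one
#' scan.
#'
#' Alongside the contour itself, a spill-out *capture region* is recorded:
#' the mask dilated by `capture_margin_mm` (by default the blur FWHM carried
#' in the volume's metadata, so unblurred volumes get no margin). System blur
#' pushes part of an object's counts just outside its iso-contour; activity
#' quantification integrates over the capture region to recover that boundary
#' layer, while the volume estimate stays tied to the undilated contour.
#'
#' @param vol an [activity_volume()].
#' @param threshold_pct threshold as % of the reference maximum, in (0, 100].
#' @param roi_box optional analysis box, `list(lo = c(i, j, k), hi = c(i, j, k))`
#'   in voxel indices (inclusive); must lie inside the grid.
#' @param capture_margin_mm dilation margin for the activity-capture region
#'   (mm); `NULL` (default) uses the volume's blur FWHM, 0 disables it.
#' @return A `segmentation_result` with fields `mask` (logical array over the
#'   full grid), `threshold_pct`, `estimated_volume_mL`, `total_counts`,
#'   `mean_counts_per_voxel`, `reference_max`, `n_voxels`, `capture_counts`
#'   (voxel counts over the dilated capture region), `capture_margin_mm`, and
#'   `empty` (TRUE when the threshold exceeded every voxel).
#' @export
iso_contour_segment <- function(vol, threshold_pct, roi_box = NULL,
                                capture_margin_mm = NULL) {
  stopifnot(inherits(vol, "activity_volume"))
  if (!is.finite(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100)
    stop("threshold_pct must lie in (0, 100]")
  shape <- vol$grid$shape
  box <- check_roi_box(roi_box, shape)
  sub <- vol$values[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                    box$lo[3]:box$hi[3], drop = FALSE]
  ref_max <- max(sub)
  if (ref_max <= 0) stop("no signal: analysis region is all zero")
  cutoff <- threshold_pct / 100 * ref_max
  above <- sub >= cutoff
  if (is.null(capture_margin_mm)) {
    capture_margin_mm <- vol$meta$fwhm_mm
    if (is.null(capture_margin_mm)) capture_margin_mm <- 0
  }
  if (!is.finite(capture_margin_mm) || capture_margin_mm < 0)
    stop("capture_margin_mm must be >= 0")
  if (!any(above)) {
    mask <- array(FALSE, dim = shape)
    return(new_segmentation_result(mask, threshold_pct, numeric(0),
                                   numeric(0), capture_margin_mm, ref_max,
                                   vol, empty = TRUE))
  }
  labels <- label_components(above)
  n_comp <- attr(labels, "n_components")
  if (n_comp > 1L) {
    sizes <- tabulate(labels[labels > 0L], nbins = n_comp)
    keep <- which.max(sizes)
    above <- labels == keep
  }
  mask <- array(FALSE, dim = shape)
  mask[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- above
  capture <- if (capture_margin_mm > 0)
    dilate_mask(mask, capture_margin_mm, vol$grid$spacing) else mask
  new_segmentation_result(mask, threshold_pct, vol$values[mask],
                          vol$values[capture], capture_margin_mm, ref_max,
                          vol, empty = FALSE)
}

new_segmentation_result <- function(mask, threshold_pct, masked_counts,
                                    capture_counts, capture_margin_mm,
                                    ref_max, vol, empty) {
  n_voxels <- length(masked_counts)
  total <- sum(masked_counts)
  structure(list(
    mask = mask,
    threshold_pct = threshold_pct,
    n_voxels = n_voxels,
    estimated_volume_mL = n_voxels * voxel_volume_mL(vol$grid),
    total_counts = total,
    mean_counts_per_voxel = if (n_voxels > 0) total / n_voxels else 0,
    reference_max = ref_max,
    masked_counts = masked_counts,
    capture_counts = capture_counts,
    capture_margin_mm = capture_margin_mm,
    empty = empty,
    grid = vol$grid
  ), class = "segmentation_result")
}

#' Dilate a binary mask by a physical margin
#'
#' Iterative 6-neighbour dilation: along each axis the mask grows by
#' `round(margin_mm / spacing)` voxels, approximating a ball of the given
#' radius.
#'
#' @param mask logical 3-D array.
#' @param margin_mm dilation radius in mm.
#' @param spacing voxel spacing per axis, mm.
#' @return dilated logical array.
#' @export
dilate_mask <- function(mask, margin_mm, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  k <- round(margin_mm / spacing)
  d <- dim(mask)
  shift_or <- function(m, axis) {
    n <- d[axis]
    idx_lo <- c(1L, seq_len(n - 1L))   # neighbour below
    idx_hi <- c(seq_len(n - 1L) + 1L, n)  # neighbour above
    m | slice_index(m, axis, idx_lo) | slice_index(m, axis, idx_hi)
  }
  for (it in seq_len(max(k))) {
    for (axis in 1:3) if (it <= k[axis]) mask <- shift_or(mask, axis)
  }
  mask
}

slice_index <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Iso-contour at %.1f%%: empty segmentation (threshold above all voxels)\n",
                x$threshold_pct))
  } else {
    cat(sprintf("Iso-contour at %.1f%% of reference max %.4g\n",
                x$threshold_pct, x$reference_max))
    cat(sprintf("  %d voxels, %.4g mL, total counts %.6g, mean counts/voxel %.5g\n",
                x$n_voxels, x$estimated_volume_mL, x$total_counts,
                x$mean_counts_per_voxel))
  }
  invisible(x)
}

check_roi_box <- function(roi_box, shape) {
  if (is.null(roi_box))
    return(list(lo = c(1L, 1L, 1L), hi = shape))
  lo <- as.integer(roi_box$lo); hi <- as.integer(roi_box$hi)
  if (length(lo) != 3L || length(hi) != 3L || any(is.na(c(lo, hi))))
    stop("roi_box must have integer lo and hi of length 3")
  if (any(lo < 1L) || any(hi > shape) || any(lo > hi))
    stop("roi_box must lie inside the grid with lo <= hi")
  list(lo = lo, hi = hi)
}

#' Default threshold grid for standardization (% of maximum)
#' @return numeric vector, 19 to 52 in steps of 1.
#' @export
default_threshold_grid <- function() seq(19, 52, by = 1)

#' Threshold sweep against a known true volume
#'
#' Runs [iso_contour_segment()] over a grid of thresholds and reports the
#' threshold whose estimated volume is closest to the truth; ties are broken
#' toward the lower threshold.
#'
#' @param vol an [activity_volume()].
#' @param true_volume_mL known object volume (mL, > 0).
#' @param thresholds thresholds in % of reference max (default 19-52 step 1).
#' @param roi_box optional analysis box (see [iso_contour_segment()]).
#' @return A `sweep_result`: data.frame `sweep` (threshold_pct,
#'   estimated_mL, abs_error_mL), `best_threshold`, `best_abs_error_mL`.
#' @export
threshold_sweep <- function(vol, true_volume_mL,
                            thresholds = default_threshold_grid(),
                            roi_box = NULL) {
  if (!is.finite(true_volume_mL) || true_volume_mL <= 0)
    stop("true_volume_mL must be positive")
  if (!length(thresholds) || any(thresholds <= 0) || any(thresholds > 100))
    stop("thresholds must be non-empty, each in (0, 100]")
  est <- vapply(thresholds, function(t)
    iso_contour_segment(vol, t, roi_box)$estimated_volume_mL, numeric(1))
  err <- abs(est - true_volume_mL)
  best <- which(err == min(err))[1]  # ties -> lower threshold
  structure(list(
    sweep = data.frame(threshold_pct = thresholds, estimated_mL = est,
                       abs_error_mL = err),
    true_volume_mL = true_volume_mL,
    best_threshold = thresholds[best],
    best_abs_error_mL = err[best]
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Threshold sweep over %d thresholds (true volume %.4g mL)\n",
              nrow(x$sweep), x$true_volume_mL))
  cat(sprintf("  best threshold %.1f%% (abs error %.4g mL, %.2f%%)\n",
              x$best_threshold, x$best_abs_error_mL,
              100 * x$best_abs_error_mL / x$true_volume_mL))
  invisible(x)
}

#' Standardize iso-contour thresholds per volume range
#'
#' For each volume range, selects the single threshold that minimizes the
#' summed absolute volume error over all phantoms in the range (ties toward
#' the lower threshold), then reports the Pearson correlation between
#' estimated and true volumes at that threshold. This is the phantom
#' standardization step that fixes the per-range contouring threshold used
#' for patient scans.
#'
#' @param series list of `list(spec =, vol =)` entries as produced by
#'   [generate_phantom_series()].
#' @param ranges list of `c(low, high)` volume ranges in mL (default the
#'   three reference ranges).
#' @param thresholds candidate thresholds (default 19-52 step 1).
#' @return data.frame with one row per range: `range_low_mL`, `range_high_mL`,
#'   `n_phantoms`, `best_threshold`, `mean_abs_error_mL`,
#'   `mean_abs_error_pct`, `volume_correlation_r`.
#' @export
standardize_thresholds <- function(series,
                                   ranges = default_volume_ranges(),
                                   thresholds = default_threshold_grid()) {
  if (!length(series)) stop("empty phantom series")
  true_v <- vapply(series, function(e) e$spec$true_volume_mL, numeric(1))
  # estimated volume for every phantom x threshold
  est <- vapply(series, function(e)
    vapply(thresholds, function(t)
      iso_contour_segment(e$vol, t)$estimated_volume_mL, numeric(1)),
    numeric(length(thresholds)))
  est <- matrix(est, nrow = length(thresholds))
  rows <- lapply(ranges, function(rg) {
    in_range <- which(true_v >= rg[1] * (1 - 1e-9) &
                        true_v <= rg[2] * (1 + 1e-9))
    if (length(in_range) < 2L)
      stop(sprintf("range %g-%g mL contains fewer than 2 phantoms",
                   rg[1], rg[2]))
    abs_err <- abs(est[, in_range, drop = FALSE] -
                     matrix(true_v[in_range], nrow = length(thresholds),
                            ncol = length(in_range), byrow = TRUE))
    tot <- rowSums(abs_err)
    best <- which(tot == min(tot))[1]
    est_best <- est[best, in_range]
    r <- if (stats::sd(est_best) > 0 && stats::sd(true_v[in_range]) > 0)
      stats::cor(est_best, true_v[in_range]) else NA_real_
    data.frame(range_low_mL = rg[1], range_high_mL = rg[2],
               n_phantoms = length(in_range),
               best_threshold = thresholds[best],
               mean_abs_error_mL = mean(abs_err[best, ]),
               mean_abs_error_pct = mean(100 * abs_err[best, ] / true_v[in_range]),
               volume_correlation_r = r)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a segmentation mask as NIfTI
#'
#' @param seg a `segmentation_result`.
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_result"))
  m <- array(as.integer(seg$mask), dim = dim(seg$mask))
  attr(m, "pixdim") <- seg$grid$spacing
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  invisible(path)
}
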