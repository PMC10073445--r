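#' Digital phantom specification
#'
#' Describes one fillable hot object of a Jaszczak-style phantom experiment:
#' a sphere or axis-aligned cylinder of known analytic volume, filled with a
#' known activity concentration against a (possibly zero) background
#' concentration. Concentrations are canonical uCi/mL; use
#' [convert_activity()] for kBq/mL inputs.
#'
#' @param geometry list: `list(type = "sphere", center_mm =, radius_mm =)` or
#'   `list(type = "cylinder", center_mm =, radius_mm =, height_mm =)`
#'   (cylinder axis along z).
#' @param concentration_uCi_mL activity concentration in the object (uCi/mL).
#' @param background_uCi_mL background concentration (uCi/mL, >= 0, at most
#'   `concentration_uCi_mL`; equality gives a constant, contrast-free
#'   volume).
#' @param true_volume_mL optional declared volume; checked against the
#'   analytic geometry volume to 0.1% if supplied, otherwise derived.
#' @return A `phantom_spec` object with field `true_volume_mL`.
#' @examples
#' sphere_spec(1000, c(200, 200, 200), concentration_uCi_mL = 2)
#' @export
phantom_spec <- function(geometry, concentration_uCi_mL,
                         background_uCi_mL = 0, true_volume_mL = NULL) {
  if (!is.list(geometry) || is.null(geometry$type))
    stop("geometry must be a list with a 'type' field")
  if (!geometry$type %in% c("sphere", "cylinder"))
    stop("geometry type must be 'sphere' or 'cylinder'")
  if (length(geometry$center_mm) != 3L || any(!is.finite(geometry$center_mm)))
    stop("geometry$center_mm must be 3 finite coordinates (mm)")
  if (!is.finite(geometry$radius_mm) || geometry$radius_mm <= 0)
    stop("geometry$radius_mm must be positive")
  if (geometry$type == "cylinder" &&
      (!is.finite(geometry$height_mm) || geometry$height_mm <= 0))
    stop("cylinder needs a positive height_mm")
  v_analytic <- analytic_volume_mL(geometry)
  if (is.null(true_volume_mL)) {
    true_volume_mL <- v_analytic
  } else if (abs(true_volume_mL - v_analytic) > 1e-3 * v_analytic) {
    stop(sprintf("declared volume %.4g mL differs from analytic %.4g mL by >0.1%%",
                 true_volume_mL, v_analytic))
  }
  if (!is.finite(concentration_uCi_mL) || concentration_uCi_mL <= 0)
    stop("concentration must be positive")
  if (!is.finite(background_uCi_mL) || background_uCi_mL < 0)
    stop("background concentration must be >= 0")
  if (concentration_uCi_mL < background_uCi_mL)
    stop("object concentration must not be below background concentration")
  structure(list(geometry = geometry,
                 true_volume_mL = true_volume_mL,
                 concentration_uCi_mL = concentration_uCi_mL,
                 background_uCi_mL = background_uCi_mL),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param volume_mL target sphere volume in mL (radius derived analytically).
#' @param center_mm sphere centre, mm.
#' @export
sphere_spec <- function(volume_mL, center_mm, concentration_uCi_mL,
                        background_uCi_mL = 0) {
  if (!is.finite(volume_mL) || volume_mL <= 0) stop("volume_mL must be positive")
  r <- (3 * volume_mL * 1000 / (4 * pi))^(1 / 3)
  phantom_spec(list(type = "sphere", center_mm = center_mm, radius_mm = r),
               concentration_uCi_mL, background_uCi_mL)
}

#' Analytic volume of a phantom geometry in mL
#' @param geometry geometry list as in [phantom_spec()].
#' @return volume in mL.
#' @export
analytic_volume_mL <- function(geometry) {
  mm3 <- switch(geometry$type,
    sphere = 4 / 3 * pi * geometry$radius_mm^3,
    cylinder = pi * geometry$radius_mm^2 * geometry$height_mm,
    stop("unknown geometry type"))
  mm3 / 1000
}

#' @export
print.phantom_spec <- function(x, ...) {
  g <- x$geometry
  dims <- if (g$type == "sphere") sprintf("r = %.3g mm", g$radius_mm)
          else sprintf("r = %.3g mm, h = %.3g mm", g$radius_mm, g$height_mm)
  cat(sprintf("Phantom %s (%s): %.4g mL at %.4g uCi/mL (background %.4g)\n",
              g$type, dims, x$true_volume_mL, x$concentration_uCi_mL,
              x$background_uCi_mL))
  invisible(x)
}

# logical 3-D array of voxels whose centres lie inside the geometry
geometry_mask <- function(geometry, grid) {
  cx <- axis_centres(grid, 1) - geometry$center_mm[1]
  cy <- axis_centres(grid, 2) - geometry$center_mm[2]
  cz <- axis_centres(grid, 3) - geometry$center_mm[3]
  if (geometry$type == "sphere") {
    r2 <- geometry$radius_mm^2
    d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
    d2 <= r2
  } else {
    r2 <- geometry$radius_mm^2
    inplane <- outer(cx^2, cy^2, `+`) <= r2
    inz <- abs(cz) <= geometry$height_mm / 2
    outer(inplane, inz, `&`)
  }
}

check_geometry_fits <- function(geometry, grid) {
  ext <- grid_extent_mm(grid)
  half <- switch(geometry$type,
    sphere = rep(geometry$radius_mm, 3),
    cylinder = c(geometry$radius_mm, geometry$radius_mm,
                 geometry$height_mm / 2))
  lo <- geometry$center_mm - half
  hi <- geometry$center_mm + half
  bad <- which(lo < 0 | hi > ext)
  if (length(bad))
    stop(sprintf("phantom geometry exceeds grid extent along axis %s",
                 paste(c("x", "y", "z")[bad], collapse = ", ")))
  invisible(TRUE)
}

#' Rasterize a phantom onto a reconstruction grid
#'
#' Produces the ideal (noiseless, unblurred) reconstructed count map of a
#' phantom: voxels whose centres lie inside the geometry carry the forward
#' calibration of the object concentration, all others the forward
#' calibration of the background concentration. Counts per voxel are
#' counts-per-cc times the voxel volume in cc, so the calibration intercept
#' appears as a background count plateau even at zero background
#' concentration, as in real attenuation-corrected reconstructions.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()]; the geometry must fit inside its extent.
#' @param forward_model a [calibration_model()] mapping uCi/cc to counts/cc.
#' @return An [activity_volume()] of noiseless voxel counts.
#' @export
rasterize_phantom <- function(spec, grid, forward_model) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_spec"),
            inherits(forward_model, "calibration_model"))
  check_geometry_fits(spec$geometry, grid)
  vox_cc <- voxel_volume_mL(grid)  # 1 mL == 1 cc
  hot <- concentration_to_counts(forward_model, spec$concentration_uCi_mL) * vox_cc
  bg <- concentration_to_counts(forward_model, spec$background_uCi_mL) * vox_cc
  inside <- geometry_mask(spec$geometry, grid)
  values <- array(bg, dim = grid$shape)
  values[inside] <- hot
  activity_volume(values, grid,
                  meta = list(fwhm_mm = 0, noise = FALSE, seed = NA_integer_))
}

#' Apply system resolution blur to an activity volume
#'
#' Convolves the count map with an isotropic Gaussian of the given full width
#' at half maximum (sigma = fwhm / 2.3548 per axis, in mm), emulating the
#' resolution loss of a reconstructed SPECT image. Boundaries are handled by
#' reflection and the separable kernels are renormalised after truncation at
#' 4 sigma, so total counts are conserved to float precision.
#'
#' @param vol an [activity_volume()].
#' @param fwhm_mm full width at half maximum in mm (>= 0; 0 is the identity).
#' @return A blurred [activity_volume()].
#' @export
apply_system_blur <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "activity_volume"))
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) {
    out <- vol
    out$meta$fwhm_mm <- 0
    return(out)
  }
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  values <- vol$values
  for (axis in 1:3) {
    K <- reflect_conv_matrix(vol$grid$shape[axis],
                             sigma_mm / vol$grid$spacing[axis])
    values <- apply_along_axis(values, axis, K)
  }
  activity_volume(values, vol$grid,
                  meta = utils::modifyList(vol$meta, list(fwhm_mm = fwhm_mm)))
}

# n x n convolution matrix for a Gaussian of sd `sigma` (in voxels) with
# reflecting boundary; kernel truncated at 4 sigma and renormalised so each
# row (and by symmetry each column) sums to 1 -> exact count conservation.
reflect_conv_matrix <- function(n, sigma) {
  p <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-p, p), sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in seq(-p, p)) {
    j <- reflect_index(idx + d, n)
    ij <- cbind(idx, j)
    K[ij] <- K[ij] + w[d + p + 1L]
  }
  K
}

# reflect out-of-range indices back into 1..n (half-sample symmetric)
reflect_index <- function(i, n) {
  period <- 2L * n
  i <- ((i - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(i < n, i + 1L, period - i)
}

# multiply K along the given axis of a 3-D array
apply_along_axis <- function(a, axis, K) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

#' Add Poisson counting noise
#'
#' Replaces each voxel count by a Poisson draw with that mean; deterministic
#' for a fixed seed.
#'
#' @param vol an [activity_volume()] with non-negative values.
#' @param seed integer RNG seed.
#' @return A noisy [activity_volume()].
#' @export
add_poisson_noise <- function(vol, seed) {
  stopifnot(inherits(vol, "activity_volume"))
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  values <- array(stats::rpois(length(vol$values), vol$values),
                  dim = dim(vol$values))
  activity_volume(values * 1.0, vol$grid,
                  meta = utils::modifyList(vol$meta,
                                           list(noise = TRUE, seed = seed)))
}

#' Reference phantom volume ranges
#'
#' The three activity-volume ranges used for threshold standardization:
#' 6-30 mL, 500-1500 mL and 2400-3200 mL.
#'
#' @return list of `c(low, high)` pairs in mL.
#' @export
default_volume_ranges <- function() {
  list(small = c(6, 30), medium = c(500, 1500), large = c(2400, 3200))
}

#' Default phantom volumes spanning the reference ranges (mL)
#' @return numeric vector of sphere volumes in mL.
#' @export
default_phantom_volumes <- function() {
  c(6, 16, 30, 500, 1000, 1500, 2400, 2800, 3200)
}

#' Generate a series of simulated phantom reconstructions
#'
#' One volume per (volume, concentration) pair: spheres of the requested
#' volumes are rasterized at each concentration, blurred with the system
#' FWHM, and optionally degraded with Poisson noise. Ground-truth specs are
#' retained alongside each simulated reconstruction.
#'
#' @param volumes_mL sphere volumes in mL (default spans 6-3200 mL).
#' @param concentrations activity concentrations (default 100 kBq/mL).
#' @param conc_unit unit of `concentrations` (default `"kBq/mL"`).
#' @param grid a [grid_spec()] (default 128^3 at 3.3 mm).
#' @param forward_model [calibration_model()] used as the forward map
#'   (default: the standardized regression, slope 6807.3, intercept 39.0).
#' @param fwhm_mm system blur FWHM in mm (default 8, a typical
#'   post-reconstruction resolution for a Butterworth-filtered SPECT/CT).
#' @param noise add Poisson noise (default TRUE).
#' @param seed integer seed; each phantom uses a distinct sub-seed derived
#'   from it, so the whole series is reproducible.
#' @param background_frac background concentration as a fraction of each
#'   phantom concentration (default 0).
#' @return list of entries `list(spec =, vol =, seed =)`.
#' @export
generate_phantom_series <- function(volumes_mL = default_phantom_volumes(),
                                    concentrations = 100,
                                    conc_unit = "kBq/mL",
                                    grid = grid_spec(),
                                    forward_model = calibration_model(6807.3, 39.0),
                                    fwhm_mm = 8, noise = TRUE, seed = 1L,
                                    background_frac = 0) {
  if (!length(volumes_mL) || !length(concentrations))
    stop("volumes_mL and concentrations must be non-empty")
  if (any(volumes_mL <= 0)) stop("volumes must be positive")
  if (background_frac < 0 || background_frac >= 1)
    stop("background_frac must be in [0, 1)")
  conc_uCi <- convert_activity(concentrations, conc_unit, "uCi/mL")
  centre <- grid_extent_mm(grid) / 2
  combos <- expand.grid(volume = volumes_mL, conc = conc_uCi,
                        KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    spec <- sphere_spec(combos$volume[i], centre, combos$conc[i],
                        background_uCi_mL = background_frac * combos$conc[i])
    vol <- rasterize_phantom(spec, grid, forward_model)
    if (fwhm_mm > 0) vol <- apply_system_blur(vol, fwhm_mm)
    sub_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    if (noise) vol <- add_poisson_noise(vol, sub_seed)
    out[[i]] <- list(spec = spec, vol = vol, seed = sub_seed)
  }
  out
}
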