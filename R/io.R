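#' Read and write activity volumes as NIfTI
#'
#' Volumes are stored as 3-D 32-bit float NIfTI with the voxel spacing in the
#' header; values and spacing round-trip losslessly (within float32
#' precision of the stored counts).
#'
#' @param vol an [activity_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [activity_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "activity_volume"))
  values <- vol$values
  attr(values, "pixdim") <- vol$grid$spacing
  RNifti::writeNifti(RNifti::asNifti(values, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume header lacks positive voxel spacings")
  grid <- grid_spec(d, spacing)
  activity_volume(array(as.numeric(img), dim = d), grid)
}

#' Run configuration for the end-to-end workflow
#'
#' Bundles the seed, units and stage parameters of a full standardization +
#' quantification + cohort-analysis run. The configuration serialises to JSON
#' and every pipeline output embeds its hash, so reruns are verifiably
#' identical.
#'
#' @param seed integer master seed.
#' @param grid_shape,grid_spacing reconstruction grid (kept small by default
#'   so a full run stays interactive; see [grid_spec()]).
#' @param fwhm_mm system blur FWHM (mm).
#' @param noise simulate Poisson counting noise.
#' @param phantom_volumes_mL phantom sphere volumes for standardization.
#' @param concentration_kBq_mL phantom fill concentration.
#' @param thresholds candidate iso-contour thresholds (% of max).
#' @param ranges volume ranges for per-range standardization.
#' @param decay_correction decay-correct injected doses.
#' @param cohort_n,cohort_preset cohort simulation size and preset.
#' @param out_dir output directory for [run_pipeline()].
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L,
                       grid_shape = c(96L, 96L, 96L),
                       grid_spacing = 3.3,
                       fwhm_mm = 8,
                       noise = TRUE,
                       phantom_volumes_mL = default_phantom_volumes(),
                       concentration_kBq_mL = 100,
                       thresholds = default_threshold_grid(),
                       ranges = default_volume_ranges(),
                       decay_correction = TRUE,
                       cohort_n = 109L,
                       cohort_preset = "table1_strata",
                       out_dir = "qspect_run") {
  structure(list(seed = as.integer(seed), grid_shape = as.integer(grid_shape),
                 grid_spacing = grid_spacing, fwhm_mm = fwhm_mm,
                 noise = noise, phantom_volumes_mL = phantom_volumes_mL,
                 concentration_kBq_mL = concentration_kBq_mL,
                 thresholds = thresholds, ranges = ranges,
                 decay_correction = decay_correction,
                 cohort_n = as.integer(cohort_n),
                 cohort_preset = cohort_preset, out_dir = out_dir),
            class = "run_config")
}

#' Serialise a run configuration to canonical JSON and hash it
#'
#' The output directory is excluded from the hash: it locates the artifacts
#' but is not a parameter of the computation, so runs into different
#' directories remain byte-identical.
#'
#' @param config a [run_config()].
#' @return list with `json` (string) and `hash` (md5).
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fields <- unclass(config)
  fields$out_dir <- NULL
  json <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(as.character(json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(json = as.character(json), hash = hash)
}
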