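# File interchange: activity images and sinograms as single-slice NIfTI
# (pixel size in the header) or plain CSV grids; sinograms carry a YAML
# sidecar recording the geometry; kernels export as CSV for inspection.

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Write an activity image to NIfTI or CSV
#'
#' NIfTI files (`.nii`/`.nii.gz`) store the image as a single-slice volume
#' with the pixel size in the header; `.csv` writes the bare grid (the
#' pixel size must then be supplied again on reading).
#'
#' @param image An [activity_image()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "activity_image"))
  if (.is_nifti_path(path)) {
    arr <- array(image$values, dim = c(dim(image$values), 1L))
    attr(arr, "pixdim") <- c(image$pixel_size_mm, image$pixel_size_mm, 1)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else if (grepl("\\.csv$", path)) {
    utils::write.table(image$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported image format: use .nii, .nii.gz or .csv")
  }
  invisible(path)
}

#' Read an activity image from NIfTI or CSV
#'
#' @param path Input path (`.nii`, `.nii.gz` or `.csv`).
#' @param pixel_size_mm Pixel size override; required for CSV, read from
#'   the header for NIfTI.
#' @return An [activity_image()].
#' @export
read_image <- function(path, pixel_size_mm = NULL) {
  if (.is_nifti_path(path)) {
    nii <- RNifti::readNifti(path)
    v <- as.array(nii)
    if (length(dim(v)) == 3) v <- v[, , 1]
    v <- matrix(as.numeric(v), nrow(v), ncol(v))  # drop NIfTI attributes
    px <- pixel_size_mm %||% RNifti::pixdim(nii)[1]
    activity_image(pmax(v, 0), px, label = basename(path))
  } else if (grepl("\\.csv$", path)) {
    if (is.null(pixel_size_mm)) {
      stop("'pixel_size_mm' is required when reading CSV images")
    }
    v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    activity_image(pmax(v, 0), pixel_size_mm, label = basename(path))
  } else {
    stop("unsupported image format")
  }
}

.sidecar_path <- function(path) {
  paste0(sub("\\.(nii(\\.gz)?|csv)$", "", path), "_geometry.yaml")
}

#' Write a sinogram with its geometry sidecar
#'
#' The counts grid goes to NIfTI or CSV; the geometry (angles, bin size,
#' line sigma) goes to a `*_geometry.yaml` sidecar next to it.
#'
#' @param sino A [sinogram()].
#' @param path Output path (`.nii`, `.nii.gz` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  if (.is_nifti_path(path)) {
    arr <- array(sino$counts, dim = c(dim(sino$counts), 1L))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
  } else if (grepl("\\.csv$", path)) {
    utils::write.table(sino$counts, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop("unsupported sinogram format")
  }
  yaml::write_yaml(
    list(angles_deg = as.numeric(g$angles_deg),
         n_radial_bins = g$n_radial_bins,
         bin_size_mm = g$bin_size_mm,
         line_sigma_px = g$line_sigma_px,
         identity = g$identity),
    .sidecar_path(path))
  invisible(path)
}

#' Read a sinogram and its geometry sidecar
#'
#' @param path Path previously written by [write_sinogram()].
#' @return A [sinogram()].
#' @export
read_sinogram <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("missing geometry sidecar: ", side)
  g <- yaml::read_yaml(side)
  geom <- if (isTRUE(g$identity)) {
    projection_geometry(identity = TRUE, line_sigma_px = g$line_sigma_px)
  } else {
    projection_geometry(angles_deg = g$angles_deg,
                        n_radial_bins = g$n_radial_bins,
                        bin_size_mm = g$bin_size_mm,
                        line_sigma_px = g$line_sigma_px)
  }
  counts <- if (.is_nifti_path(path)) {
    v <- as.array(RNifti::readNifti(path))
    if (length(dim(v)) == 3) v <- v[, , 1]
    matrix(as.numeric(v), nrow(v), ncol(v))
  } else {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  }
  sinogram(pmax(counts, 0), geom)
}

#' Export a PSF kernel's weights as CSV
#'
#' @param kernel A [psf_kernel()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "psf_kernel"))
  utils::write.table(kernel$weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
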