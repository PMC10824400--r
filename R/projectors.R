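# Parallel-beam line-integral projectors.
#
# The forward operator is a pixel-driven discrete Radon transform: each
# pixel's activity (times pixel area / radial bin size, so profiles carry
# line-integral units of mm x activity) is linearly interpolated into the
# two radial bins bracketing the projection of its centre,
# s = x cos(phi) + y sin(phi). The same sparse matrix serves forward and
# back projection, so the pair is exactly adjoint -- a requirement for the
# convergence properties of the EM-family algorithms built on it.

#' Parallel-beam projection geometry
#'
#' Describes a (virtual or native) 2-D parallel-beam scanner: the projection
#' angle set, radial sampling, and an optional Gaussian line-thickness
#' parameter applied in image space before projection (and after back
#' projection, keeping the operator pair adjoint). With `identity = TRUE`
#' the geometry degenerates to the identity operator (sinogram == image),
#' which makes the synthesized reconstruction algebraically identical to
#' Richardson-Lucy deconvolution and is used as a cross-check.
#'
#' @param angles_deg Strictly increasing projection angles in degrees, each
#'   in (0, 180]. Default: 1 to 180 in 1 degree steps (native sampling).
#' @param n_radial_bins Number of radial detector bins. Must cover the image
#'   diagonal; see [default_geometry()] for an automatic choice.
#' @param bin_size_mm Radial sampling pitch in mm (defaults to the image
#'   pixel size when used via [default_geometry()]).
#' @param line_sigma_px Gaussian line-thickness sigma in pixels (0 = thin
#'   lines).
#' @param identity If `TRUE`, the operator is the identity on images and all
#'   other fields are ignored.
#'
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(angles_deg = 1:180, n_radial_bins,
                                bin_size_mm = 1, line_sigma_px = 0,
                                identity = FALSE) {
  if (!identity) {
    angles_deg <- as.numeric(angles_deg)
    if (length(angles_deg) < 1 || any(diff(angles_deg) <= 0)) {
      stop("'angles_deg' must be strictly increasing")
    }
    if (any(angles_deg <= 0 | angles_deg > 180)) {
      stop("angles must lie in (0, 180] degrees")
    }
    if (missing(n_radial_bins) || n_radial_bins < 1) {
      stop("'n_radial_bins' must be a positive integer")
    }
    if (bin_size_mm <= 0) stop("'bin_size_mm' must be positive")
    if (line_sigma_px < 0) stop("'line_sigma_px' must be >= 0")
  } else {
    angles_deg <- numeric(0)
    n_radial_bins <- NA_integer_
    bin_size_mm <- NA_real_
    if (line_sigma_px < 0) stop("'line_sigma_px' must be >= 0")
  }
  structure(
    list(angles_deg = angles_deg,
         n_radial_bins = if (identity) NA_integer_ else as.integer(n_radial_bins),
         bin_size_mm = bin_size_mm,
         line_sigma_px = line_sigma_px,
         identity = identity),
    class = "projection_geometry"
  )
}

#' @export
print.projection_geometry <- function(x, ...) {
  if (x$identity) {
    cat("<projection_geometry> identity operator\n")
  } else {
    cat(sprintf(
      "<projection_geometry> %d angles [%g..%g deg], %d radial bins @ %g mm%s\n",
      length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
      x$n_radial_bins, x$bin_size_mm,
      if (x$line_sigma_px > 0)
        sprintf(", line sigma %g px", x$line_sigma_px) else ""))
  }
  invisible(x)
}

#' Geometry matched to an image grid
#'
#' Convenience constructor: radial bin size equal to the pixel size and
#' enough radial bins (odd count) to cover the image diagonal, so no
#' activity falls off the detector at any angle.
#'
#' @param grid_size Image side length in pixels, or an [activity_image()].
#' @param pixel_size_mm Pixel size in mm (taken from the image if one is
#'   given).
#' @inheritParams projection_geometry
#' @return A [projection_geometry()].
#' @export
default_geometry <- function(grid_size, pixel_size_mm = 1,
                             angles_deg = 1:180, line_sigma_px = 0) {
  if (inherits(grid_size, "activity_image")) {
    pixel_size_mm <- grid_size$pixel_size_mm
    grid_size <- nrow(grid_size$values)
  }
  n_r <- 2L * ceiling(sqrt(2) * grid_size / 2) + 3L
  projection_geometry(angles_deg = angles_deg, n_radial_bins = n_r,
                      bin_size_mm = pixel_size_mm,
                      line_sigma_px = line_sigma_px)
}

#' Sinogram container
#'
#' A 2-D array of line-integral measurements, indexed (radial bin, angle),
#' together with the [projection_geometry()] that produced or interprets it.
#'
#' @param counts Numeric matrix, `n_radial_bins` x `length(angles_deg)`,
#'   all entries `>= 0`.
#' @param geometry The associated [projection_geometry()].
#'
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(counts, geometry) {
  counts <- as.matrix(counts)
  stopifnot(inherits(geometry, "projection_geometry"))
  if (any(counts < 0)) stop("sinogram entries must be nonnegative")
  if (!geometry$identity &&
      (nrow(counts) != geometry$n_radial_bins ||
       ncol(counts) != length(geometry$angles_deg))) {
    stop("sinogram shape does not match its geometry")
  }
  structure(list(counts = unname(counts), geometry = geometry),
            class = "sinogram")
}

#' @export
dim.sinogram <- function(x) dim(x$counts)

#' @export
as.matrix.sinogram <- function(x, ...) x$counts

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d radial bins x %d angles, total %.6g\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.sinogram <- function(x, main = "sinogram", ...) {
  image(seq_len(ncol(x$counts)), seq_len(nrow(x$counts)), t(x$counts),
        col = gray.colors(256), xlab = "angle index", ylab = "radial bin",
        main = main, useRaster = TRUE, ...)
  invisible(x)
}

# cache key for a (geometry, grid) system matrix
.geom_key <- function(geom, n, px) {
  paste0("A|", n, "|", signif(px, 12), "|", geom$n_radial_bins, "|",
         signif(geom$bin_size_mm, 12), "|",
         paste(signif(geom$angles_deg, 12), collapse = ","))
}

# Sparse system matrix (n_radial * n_angles) x (n * n) for a thin-line
# pixel-driven Radon transform; memoised in the package cache. The
# line-thickness blur is NOT part of the matrix -- it is applied in image
# space by the forward/back wrappers.
.system_matrix <- function(geom, n, px) {
  key <- .geom_key(geom, n, px)
  hit <- .synthrr_cache[[key]]
  if (!is.null(hit)) return(hit)

  n_r <- geom$n_radial_bins
  bin <- geom$bin_size_mm
  diag_mm <- sqrt(2) * n * px
  if (n_r * bin < diag_mm) {
    stop(sprintf(
      "geometry has %d bins of %g mm; image diagonal is %.1f mm (uncovered)",
      n_r, bin, diag_mm))
  }
  co <- .pixel_coords_mm(n, px)
  xv <- as.vector(co$x)        # column-major vec() of the image
  yv <- as.vector(co$y)
  centre <- (n_r + 1) / 2
  wscale <- px^2 / bin
  n_ang <- length(geom$angles_deg)
  npix <- n * n
  jj <- rep.int(seq_len(npix), 2L)

  ilist <- vector("list", n_ang)
  jlist <- vector("list", n_ang)
  xlist <- vector("list", n_ang)
  for (a in seq_len(n_ang)) {
    ph <- geom$angles_deg[a] * pi / 180
    t <- (xv * cos(ph) + yv * sin(ph)) / bin + centre
    i0 <- floor(t)
    w <- t - i0
    ii <- c(i0, i0 + 1)
    xx <- c(1 - w, w) * wscale
    ok <- ii >= 1 & ii <= n_r & xx > 0
    ilist[[a]] <- (a - 1L) * n_r + ii[ok]
    jlist[[a]] <- jj[ok]
    xlist[[a]] <- xx[ok]
  }
  A <- sparseMatrix(i = unlist(ilist), j = unlist(jlist), x = unlist(xlist),
                    dims = c(n_r * n_ang, npix))
  .synthrr_cache[[key]] <- A
  A
}

# optional image-space Gaussian line-thickness blur (sigma in pixels)
.line_blur <- function(values, sigma_px) {
  if (sigma_px <= 0) return(values)
  k <- .gaussian_weights_px(sigma_px, truncation_sigmas = 4)
  .conv2_same(values, k)
}

#' Forward projection (discrete Radon transform)
#'
#' Projects an activity image into a sinogram under a parallel line-integral
#' model. If the geometry carries a line-thickness `line_sigma_px > 0`, the
#' image is first convolved with an isotropic Gaussian of that sigma. The
#' operation is linear in the image.
#'
#' @param image An [activity_image()].
#' @param geometry A [projection_geometry()].
#' @return A [sinogram()].
#' @export
forward_project <- function(image, geometry) {
  stopifnot(inherits(image, "activity_image"),
            inherits(geometry, "projection_geometry"))
  v <- .line_blur(image$values, geometry$line_sigma_px)
  if (geometry$identity) {
    return(sinogram(pmax(v, 0), geometry))
  }
  A <- .system_matrix(geometry, nrow(v), image$pixel_size_mm)
  p <- as.vector(A %*% as.vector(v))
  sinogram(matrix(pmax(p, 0), geometry$n_radial_bins,
                  length(geometry$angles_deg)),
           geometry)
}

#' Back projection (adjoint of the forward projector)
#'
#' Applies the exact transpose of [forward_project()] with the same
#' geometry, including the line-thickness blur (whose adjoint is the same
#' symmetric Gaussian, applied after the ray accumulation).
#'
#' @param sino A [sinogram()].
#' @param geometry The [projection_geometry()] (defaults to the sinogram's).
#' @param grid_size Output image side length in pixels.
#' @param pixel_size_mm Output pixel size in mm (default: radial bin size).
#' @return An [activity_image()].
#' @export
back_project <- function(sino, geometry = sino$geometry, grid_size,
                         pixel_size_mm = geometry$bin_size_mm) {
  stopifnot(inherits(sino, "sinogram"),
            inherits(geometry, "projection_geometry"))
  if (geometry$identity) {
    v <- .line_blur(sino$counts, geometry$line_sigma_px)
    return(activity_image(pmax(v, 0), pixel_size_mm %||% 1, "backprojection"))
  }
  if (nrow(sino$counts) != geometry$n_radial_bins ||
      ncol(sino$counts) != length(geometry$angles_deg)) {
    stop("sinogram shape does not match 'geometry'")
  }
  A <- .system_matrix(geometry, grid_size, pixel_size_mm)
  b <- as.vector(crossprod(A, as.vector(sino$counts)))
  v <- .line_blur(matrix(b, grid_size, grid_size), geometry$line_sigma_px)
  activity_image(pmax(v, 0), pixel_size_mm, "backprojection")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Sensitivity image
#'
#' The back projection of an all-ones sinogram (`X^T 1`), followed by the
#' PSF adjoint when a kernel is supplied (`P^T X^T 1`). This is the
#' normalizing denominator of the EM-family algorithms; results are
#' memoised per (geometry, grid, PSF).
#'
#' @param geometry A [projection_geometry()].
#' @param grid_size Image side length in pixels.
#' @param psf Optional [psf_kernel()].
#' @param pixel_size_mm Pixel size in mm (default: radial bin size).
#' @return An [activity_image()]; strictly positive inside the field of
#'   view.
#' @export
sensitivity_image <- function(geometry, grid_size, psf = NULL,
                              pixel_size_mm = geometry$bin_size_mm) {
  px <- pixel_size_mm %||% 1
  key <- paste0("sens|", .geom_key(geometry, grid_size, px), "|",
                if (geometry$identity) "I" else "", "|",
                if (is.null(psf)) "nopsf"
                else paste(psf$model,
                           paste(vapply(psf$params, format, "", digits = 12),
                                 collapse = ","),
                           nrow(psf$weights), sep = ":"))
  hit <- .synthrr_cache[[key]]
  if (!is.null(hit)) return(hit)

  if (geometry$identity) {
    ones <- sinogram(matrix(1, grid_size, grid_size), geometry)
  } else {
    ones <- sinogram(matrix(1, geometry$n_radial_bins,
                            length(geometry$angles_deg)), geometry)
  }
  s <- back_project(ones, geometry, grid_size, px)
  if (!is.null(psf)) s <- apply_psf_adjoint(s, psf)
  s$label <- "sensitivity"
  .synthrr_cache[[key]] <- s
  s
}
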