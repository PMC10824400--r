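#' Activity image container
#'
#' A 2-D nonnegative grid of radiotracer activity concentration on a square
#' pixel grid with a physical pixel size. All reconstruction algorithms and
#' phantom generators in the package produce and consume this class.
#'
#' @param values Square numeric matrix of activity values, all `>= 0`.
#' @param pixel_size_mm Physical edge length of one pixel in millimetres.
#' @param label Free-text provenance tag.
#'
#' @return An object of class `activity_image`: a list with elements
#'   `values`, `pixel_size_mm` and `label`.
#' @export
#' @examples
#' img <- activity_image(matrix(1, 8, 8), pixel_size_mm = 2)
#' dim(img)
activity_image <- function(values, pixel_size_mm = 1, label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be a numeric matrix without NAs")
  }
  if (nrow(values) != ncol(values)) {
    stop("activity images must be square")
  }
  if (any(values < 0)) {
    stop("activity values must be nonnegative")
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1 ||
      pixel_size_mm <= 0) {
    stop("'pixel_size_mm' must be a single positive number")
  }
  structure(
    list(values = unname(values), pixel_size_mm = pixel_size_mm,
         label = as.character(label)),
    class = "activity_image"
  )
}

#' @export
dim.activity_image <- function(x) dim(x$values)

#' @export
as.matrix.activity_image <- function(x, ...) x$values

#' @export
print.activity_image <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<activity_image> %dx%d, pixel %.4g mm%s\n", n, n,
              x$pixel_size_mm,
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  cat(sprintf("  values in [%.4g, %.4g], total activity %.4g\n",
              min(x$values), max(x$values),
              sum(x$values) * x$pixel_size_mm^2))
  invisible(x)
}

#' @export
plot.activity_image <- function(x, main = x$label, ...) {
  n <- nrow(x$values)
  ext <- n * x$pixel_size_mm / 2
  # transpose/flip so row 1 is displayed at the top
  image(seq(-ext, ext, length.out = n), seq(-ext, ext, length.out = n),
        t(x$values[n:1, , drop = FALSE]),
        col = gray.colors(256, start = 0, end = 1), asp = 1,
        xlab = "x (mm)", ylab = "y (mm)", main = main, useRaster = TRUE, ...)
  invisible(x)
}

# internal: wrap a raw matrix using the metadata of a template image
.as_image <- function(values, template, label = template$label) {
  activity_image(pmax(values, 0), template$pixel_size_mm, label)
}

# internal: pixel-centre coordinates in mm relative to the grid centre.
# x increases with column index, y increases upwards (decreasing row).
.pixel_coords_mm <- function(n, pixel_size_mm) {
  c0 <- (n + 1) / 2
  x <- (seq_len(n) - c0) * pixel_size_mm
  list(x = matrix(x, n, n, byrow = TRUE),
       y = matrix(rev(x), n, n))
}

#' Region-of-interest mask
#'
#' A named set of pixels over which bias, standard deviation and RMSE are
#' evaluated. The study design uses three sizes: `global` (every pixel),
#' `medium` (70 pixels inside a high-contrast feature) and `small`
#' (6 pixels adjacent to it).
#'
#' @param mask Logical matrix, `TRUE` for member pixels.
#' @param name ROI name; conventionally one of `"global"`, `"medium"`,
#'   `"small"`.
#'
#' @return An object of class `roi_mask` with elements `mask` and `name`.
#' @export
roi_mask <- function(mask, name) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("'mask' must be a logical matrix")
  }
  if (!any(mask)) stop("an ROI must contain at least one pixel")
  structure(list(mask = unname(mask), name = as.character(name)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d of %d pixels\n", x$name, sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' Number of member pixels of an ROI
#' @param x An `roi_mask`.
#' @return Integer pixel count.
#' @export
roi_size <- function(x) {
  stopifnot(inherits(x, "roi_mask"))
  sum(x$mask)
}
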