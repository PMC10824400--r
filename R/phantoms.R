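# Digital phantoms used as ground truth in the simulation study.
# All generators are deterministic and work in normalized coordinates
# ([-1, 1] across the grid), so refining the grid while shrinking the pixel
# size preserves the structures.

# Modified (high-contrast) Shepp-Logan ellipse table.
# Columns: additive intensity A, semi-axes a and b (normalized units),
# centre (x0, y0), rotation phi in degrees. This is the widely used
# high-contrast variant of the classic head phantom: intensities are chosen
# so the summed image stays in [0, 1] with visible internal structure.
.SHEPP_LOGAN_MOD <- matrix(c(
  #  A       a       b       x0      y0     phi
   1.0,   0.6900, 0.9200,  0.00,   0.0000,   0,
  -0.8,   0.6624, 0.8740,  0.00,  -0.0184,   0,
  -0.2,   0.1100, 0.3100,  0.22,   0.0000, -18,
  -0.2,   0.1600, 0.4100, -0.22,   0.0000,  18,
   0.1,   0.2100, 0.2500,  0.00,   0.3500,   0,
   0.1,   0.0460, 0.0460,  0.00,   0.1000,   0,
   0.1,   0.0460, 0.0460,  0.00,  -0.1000,   0,
   0.1,   0.0460, 0.0230, -0.08,  -0.6050,   0,
   0.1,   0.0230, 0.0230,  0.00,  -0.6050,   0,
   0.1,   0.0230, 0.0460,  0.06,  -0.6050,   0
), ncol = 6, byrow = TRUE,
   dimnames = list(NULL, c("A", "a", "b", "x0", "y0", "phi")))

# normalized pixel-centre coordinates on [-1, 1]
.norm_coords <- function(n) {
  s <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  list(x = matrix(s, n, n, byrow = TRUE), y = matrix(rev(s), n, n))
}

.check_grid <- function(grid_size, pixel_size_mm, min_grid) {
  if (!is.numeric(grid_size) || length(grid_size) != 1 ||
      grid_size != round(grid_size) || grid_size < min_grid) {
    stop(sprintf("'grid_size' must be an integer >= %d", min_grid))
  }
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1 ||
      pixel_size_mm <= 0) {
    stop("'pixel_size_mm' must be a single positive number")
  }
}

# signed sum of ellipse intensities at given normalized coordinates
.ellipse_sum <- function(x, y, table) {
  v <- numeric(length(x))
  for (i in seq_len(nrow(table))) {
    e <- table[i, ]
    ph <- e["phi"] * pi / 180
    xr <- (x - e["x0"]) * cos(ph) + (y - e["y0"]) * sin(ph)
    yr <- -(x - e["x0"]) * sin(ph) + (y - e["y0"]) * cos(ph)
    v <- v + e["A"] * ((xr / e["a"])^2 + (yr / e["b"])^2 <= 1)
  }
  v
}

#' Modified Shepp-Logan phantom
#'
#' Rasterizes the high-contrast ("modified") Shepp-Logan head phantom on a
#' square grid. Each pixel takes the signed sum of intensities of the
#' ellipses containing its centre; the result is nonnegative with zero
#' background.
#'
#' @param grid_size Side length in pixels (`>= 8`).
#' @param pixel_size_mm Pixel size in millimetres.
#'
#' @return An [activity_image()].
#' @export
#' @examples
#' sl <- make_shepp_logan(64, 2)
#' range(as.matrix(sl))
make_shepp_logan <- function(grid_size, pixel_size_mm) {
  .check_grid(grid_size, pixel_size_mm, 8L)
  co <- .norm_coords(grid_size)
  v <- .ellipse_sum(as.vector(co$x), as.vector(co$y), .SHEPP_LOGAN_MOD)
  # intensity sums are nonnegative analytically; zap float residue like
  # 1 - 0.8 - 0.2
  v <- pmax(v, 0)
  activity_image(matrix(v, grid_size, grid_size), pixel_size_mm,
                 label = "shepp-logan")
}

# Hexagonally packed rod centres for one Derenzo sector, in mm, before
# rotation. Rows of rods stacked from r0 outward; pitch between rod centres
# is twice the rod diameter (standard Derenzo convention).
.derenzo_sector_rods <- function(d, r0, r_max, wedge_half) {
  pitch <- 2 * d
  centres <- NULL
  j <- 0
  repeat {
    y <- r0 + j * pitch * sqrt(3) / 2
    if (y + d / 2 > r_max) break
    x <- seq(-j * d, j * d, by = pitch)
    rho <- sqrt(x^2 + y^2)
    ang <- atan2(x, y)
    # keep rods (with a half-diameter margin) inside the sector wedge
    keep <- abs(ang) + asin(pmin(1, (d / 2) / rho)) <= wedge_half
    if (any(keep)) centres <- rbind(centres, cbind(x = x[keep], y = y[keep]))
    j <- j + 1
  }
  centres
}

#' Derenzo-style rod phantom
#'
#' A background disc with angular sectors of hexagonally packed hot rods,
#' one sector per rod diameter, used to assess spatial resolution. Rod
#' activity is `contrast_ratio` times the background; rod centre spacing is
#' twice the rod diameter.
#'
#' @param rod_diameters_mm Rod diameters in mm, one sector each. The default
#'   is the 1.1--4.7 mm micro-PET set. An empty vector yields a uniform
#'   background disc.
#' @param contrast_ratio Rod-to-background activity ratio (default 4).
#' @param grid_size Side length in pixels.
#' @param pixel_size_mm Pixel size in mm. Sub-millimetre sampling is needed
#'   for the smallest rods; the default study grid is 240 pixels at 0.25 mm.
#'
#' @return An [activity_image()].
#' @export
#' @examples
#' dz <- make_derenzo(c(2.3, 4.7), grid_size = 120, pixel_size_mm = 0.5)
#' sort(unique(as.vector(as.matrix(dz))))
make_derenzo <- function(rod_diameters_mm = c(1.1, 1.5, 2.3, 3.1, 3.9, 4.7),
                         contrast_ratio = 4,
                         grid_size = 240, pixel_size_mm = 0.25) {
  .check_grid(grid_size, pixel_size_mm, 16L)
  if (!is.numeric(contrast_ratio) || length(contrast_ratio) != 1 ||
      contrast_ratio <= 0) {
    stop("'contrast_ratio' must be a single positive number")
  }
  d_all <- sort(as.numeric(rod_diameters_mm))
  if (any(d_all <= 0)) stop("rod diameters must be positive")

  fov <- grid_size * pixel_size_mm
  R <- 0.46 * fov            # background disc radius, mm
  r0 <- 0.22 * R             # innermost rod-row radius
  co <- .pixel_coords_mm(grid_size, pixel_size_mm)
  rr2 <- co$x^2 + co$y^2

  img <- matrix(0, grid_size, grid_size)
  img[rr2 <= R^2] <- 1

  k <- length(d_all)
  if (k > 0) {
    wedge_half <- pi / k * 0.92  # small gap between sectors
    sector_angle <- (seq_len(k) - 1) * 2 * pi / k
    for (s in seq_len(k)) {
      d <- d_all[s]
      rods <- .derenzo_sector_rods(d, r0 + d / 2, R - d, wedge_half)
      if (is.null(rods) || nrow(rods) == 0) {
        stop(sprintf(
          "rod diameter %.3g mm does not fit the field of view (%.3g mm)",
          d, fov))
      }
      ca <- cos(sector_angle[s]); sa <- sin(sector_angle[s])
      cx <- rods[, "x"] * ca - rods[, "y"] * sa
      cy <- rods[, "x"] * sa + rods[, "y"] * ca
      for (i in seq_along(cx)) {
        hit <- (co$x - cx[i])^2 + (co$y - cy[i])^2 <= (d / 2)^2
        img[hit] <- contrast_ratio
      }
    }
  }
  activity_image(img, pixel_size_mm, label = "derenzo")
}

#' Thorax-like phantom
#'
#' A procedurally generated 2-D thorax slice: a soft-tissue body ellipse,
#' two low-activity lungs, a cardiac region and a hot lesion in the right
#' lung. It stands in for voxel-atlas thorax phantoms while providing the
#' structures the evaluation needs -- in particular a high-contrast feature
#' large enough to host the medium and small ROIs of [make_roi_masks()].
#'
#' Activity levels: background 0, lungs 0.25, body 1, cardiac region 1.5,
#' lesion 4 (arbitrary units).
#'
#' @param grid_size Side length in pixels (`>= 64`).
#' @param pixel_size_mm Pixel size in millimetres.
#'
#' @return An [activity_image()] carrying a `features` attribute with the
#'   lesion centre (row/col) and radius in pixels, used by
#'   [make_roi_masks()].
#' @export
make_thorax <- function(grid_size, pixel_size_mm) {
  .check_grid(grid_size, pixel_size_mm, 64L)
  co <- .norm_coords(grid_size)
  x <- co$x; y <- co$y
  img <- matrix(0, grid_size, grid_size)

  inside <- function(x0, y0, a, b) ((x - x0) / a)^2 + ((y - y0) / b)^2 <= 1
  img[inside(0, -0.05, 0.88, 0.66)] <- 1.00            # body
  img[inside(-0.42, 0.02, 0.30, 0.42)] <- 0.25         # left lung
  img[inside(0.42, 0.02, 0.30, 0.42)] <- 0.25          # right lung
  img[inside(0.02, -0.18, 0.20, 0.24)] <- 1.50         # cardiac region

  # hot lesion in the right lung; radius chosen so a 70-pixel disc ROI fits
  # inside it down to 64x64 grids
  les_x <- 0.42; les_y <- 0.18; les_r <- 0.165
  img[inside(les_x, les_y, les_r, les_r)] <- 4.00

  out <- activity_image(img, pixel_size_mm, label = "thorax")
  c0 <- (grid_size + 1) / 2
  attr(out, "features") <- list(
    lesion_row = c0 - les_y * grid_size / 2,
    lesion_col = c0 + les_x * grid_size / 2,
    lesion_radius_px = les_r * grid_size / 2
  )
  out
}

#' Evaluation ROI masks for the thorax phantom
#'
#' Returns the three regions of interest used for quantitative evaluation:
#' the whole image (`global`), a 70-pixel disc inside the hot lesion
#' (`medium`), and the 6 pixels immediately adjacent to that disc
#' (`small`). Medium and small masks are disjoint by construction.
#'
#' @param image An image produced by [make_thorax()] (it carries the lesion
#'   location as an attribute).
#'
#' @return A named list of three [roi_mask()] objects: `global`, `medium`,
#'   `small`.
#' @export
make_roi_masks <- function(image) {
  stopifnot(inherits(image, "activity_image"))
  feat <- attr(image, "features")
  if (is.null(feat)) {
    stop("'image' must come from make_thorax() (missing feature metadata)")
  }
  n <- nrow(image$values)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d2 <- (rows - feat$lesion_row)^2 + (cols - feat$lesion_col)^2
  ord <- order(d2)

  medium <- matrix(FALSE, n, n); medium[ord[1:70]] <- TRUE
  small <- matrix(FALSE, n, n); small[ord[71:76]] <- TRUE
  list(
    global = roi_mask(matrix(TRUE, n, n), "global"),
    medium = roi_mask(medium, "medium"),
    small = roi_mask(small, "small")
  )
}
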