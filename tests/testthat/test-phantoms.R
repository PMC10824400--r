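test_that("modified Shepp-Logan matches an independent ellipse-membership oracle", {
  n <- 128
  img <- make_shepp_logan(n, 1)
  v <- as.matrix(img)
  expect_equal(min(v), 0)
  expect_equal(max(v), 1)  # outer skull rim carries the largest intensity

  # independent point-in-ellipse evaluation at 50 random pixels
  tab <- synthrr:::.SHEPP_LOGAN_MOD
  set.seed(99)
  rows <- sample(n, 50, replace = TRUE)
  cols <- sample(n, 50, replace = TRUE)
  for (i in seq_len(50)) {
    x <- (cols[i] - (n + 1) / 2) / (n / 2)
    y <- ((n + 1) / 2 - rows[i]) / (n / 2)
    s <- 0
    for (e in seq_len(nrow(tab))) {
      ph <- tab[e, "phi"] * pi / 180
      xr <- (x - tab[e, "x0"]) * cos(ph) + (y - tab[e, "y0"]) * sin(ph)
      yr <- -(x - tab[e, "x0"]) * sin(ph) + (y - tab[e, "y0"]) * cos(ph)
      if ((xr / tab[e, "a"])^2 + (yr / tab[e, "b"])^2 <= 1) {
        s <- s + tab[e, "A"]
      }
    }
    expect_equal(v[rows[i], cols[i]], max(s, 0), tolerance = 1e-10)
  }
})

test_that("phantom generators accept degenerate sizes and reject bad arguments", {
  img <- make_shepp_logan(8, 1)
  expect_equal(dim(img), c(8L, 8L))
  expect_true(all(as.matrix(img) >= 0))
  expect_error(make_shepp_logan(4, 1), "grid_size")
  expect_error(make_shepp_logan(128, -1), "pixel_size_mm")
  expect_error(make_thorax(32, 1), "grid_size")
})

test_that("Derenzo phantom has the specified contrast and rod geometry", {
  dz <- make_derenzo(c(1.1, 1.5, 2.3, 3.1, 3.9, 4.7), 4, 240, 0.25)
  vals <- sort(unique(as.vector(as.matrix(dz))))
  expect_equal(vals, c(0, 1, 4))  # background disc 1, rods 4:1

  # single-diameter phantom: pixel-counted area per rod vs analytic disc area
  d <- 2.3
  one <- make_derenzo(d, 4, 240, 0.25)
  v <- as.matrix(one)
  n_rod_px <- sum(v == 4)
  # count rods by the analytic area they should each occupy
  area_px <- pi * (d / 2)^2 / 0.25^2
  n_rods <- round(n_rod_px / area_px)
  expect_gt(n_rods, 3)
  expect_lt(abs(n_rod_px / n_rods - area_px) / area_px, 0.15)

  # empty rod list: uniform background disc
  bg <- make_derenzo(numeric(0), 4, 120, 0.5)
  expect_equal(sort(unique(as.vector(as.matrix(bg)))), c(0, 1))

  expect_error(make_derenzo(200, 4, 240, 0.25), "does not fit")
})

test_that("thorax phantom orders its activity levels and hosts the ROIs", {
  th <- make_thorax(128, 1)
  v <- as.matrix(th)
  levels <- sort(unique(as.vector(v)))
  expect_gte(length(levels), 4)
  lung <- 0.25; body <- 1; hot <- max(v)
  expect_true(all(c(lung, body) %in% levels))
  expect_lt(lung, body)
  expect_lt(body, hot)

  masks <- make_roi_masks(th)
  expect_equal(roi_size(masks$global), 128L^2)
  expect_equal(roi_size(masks$medium), 70L)
  expect_equal(roi_size(masks$small), 6L)
  expect_false(any(masks$medium$mask & masks$small$mask))
  # the hot feature fully contains the medium ROI
  expect_true(all(v[masks$medium$mask] == hot))
  expect_error(make_roi_masks(make_shepp_logan(128, 1)), "make_thorax")
})

test_that("phantoms are deterministic and consistent under grid refinement", {
  expect_identical(as.matrix(make_thorax(64, 2)), as.matrix(make_thorax(64, 2)))
  expect_identical(as.matrix(make_derenzo(4.7, 4, 120, 0.5)),
                   as.matrix(make_derenzo(4.7, 4, 120, 0.5)))

  # rasterize at 128 px / 1 mm, 2x2-average down to 64 px / 2 mm: structures
  # must agree with the directly generated coarse image
  fine <- as.matrix(make_shepp_logan(128, 1))
  coarse <- as.matrix(make_shepp_logan(64, 2))
  down <- 0.25 * (fine[seq(1, 127, 2), seq(1, 127, 2)] +
                  fine[seq(2, 128, 2), seq(1, 127, 2)] +
                  fine[seq(1, 127, 2), seq(2, 128, 2)] +
                  fine[seq(2, 128, 2), seq(2, 128, 2)])
  # point-sampled rasterization differs from area averaging at the
  # ellipse edges, so agreement is strong but not exact
  expect_gt(stats::cor(as.vector(down), as.vector(coarse)), 0.9)
})
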