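# Independent brute-force oracles and small fixtures shared across tests.
# Everything here is deliberately naive (dense matrices, double loops) so it
# cannot share code paths with the package internals it checks.

# Dense parallel-beam projection matrix, built row-of-pixels at a time with
# plain arithmetic: project each pixel centre onto the radial axis and split
# its mass (pixel_area / bin_size) linearly between the two bracketing bins.
dense_radon_matrix <- function(n, px, geom) {
  n_r <- geom$n_radial_bins
  bin <- geom$bin_size_mm
  angs <- geom$angles_deg
  A <- matrix(0, n_r * length(angs), n * n)
  c0 <- (n + 1) / 2
  for (col in seq_len(n)) {
    for (row in seq_len(n)) {
      x <- (col - c0) * px
      y <- (c0 - row) * px
      j <- row + (col - 1) * n
      for (a in seq_along(angs)) {
        ph <- angs[a] * pi / 180
        t <- (x * cos(ph) + y * sin(ph)) / bin + (n_r + 1) / 2
        i0 <- floor(t)
        w <- t - i0
        if (i0 >= 1 && i0 <= n_r) {
          A[(a - 1) * n_r + i0, j] <- A[(a - 1) * n_r + i0, j] +
            (1 - w) * px^2 / bin
        }
        if (i0 + 1 >= 1 && i0 + 1 <= n_r) {
          A[(a - 1) * n_r + i0 + 1, j] <- A[(a - 1) * n_r + i0 + 1, j] +
            w * px^2 / bin
        }
      }
    }
  }
  A
}

# Dense matrix of "same"-size zero-padded 2-D convolution with kernel k on
# an n x n image, from the definition out[i,j] = sum k[a,b] x[i-a', j-b'].
dense_conv_matrix <- function(n, k) {
  kh <- (nrow(k) - 1) / 2
  M <- matrix(0, n * n, n * n)
  for (oc in seq_len(n)) for (orow in seq_len(n)) {
    oi <- orow + (oc - 1) * n
    for (dc in -kh:kh) for (dr in -kh:kh) {
      ir <- orow - dr; ic <- oc - dc
      if (ir >= 1 && ir <= n && ic >= 1 && ic <= n) {
        M[oi, ir + (ic - 1) * n] <- k[dr + kh + 1, dc + kh + 1]
      }
    }
  }
  M
}

# uniform disc image of radius r_mm on an n x n grid
disc_image <- function(n, px, r_mm, value = 1) {
  c0 <- (n + 1) / 2
  x <- matrix((seq_len(n) - c0) * px, n, n, byrow = TRUE)
  y <- matrix(rev((seq_len(n) - c0) * px), n, n)
  activity_image(value * (x^2 + y^2 <= r_mm^2), px, "disc")
}

# small random nonnegative image
rand_image <- function(n, px = 1, seed = 1) {
  set.seed(seed)
  activity_image(matrix(runif(n * n), n, n), px, "random")
}

# coarse geometry for quick reconstruction tests
quick_geom <- function(img_or_n, px = 1, by = 12, sigma = 0) {
  default_geometry(img_or_n, px, angles_deg = seq(1, 180, by = by),
                   line_sigma_px = sigma)
}

# wrap a bare matrix as a single-iterate recon_result (metrics tests)
fake_result <- function(values, iterations = 1) {
  rec <- stats::setNames(rep(list(as.matrix(values)), length(iterations)),
                         iterations)
  structure(
    list(final_image = activity_image(pmax(as.matrix(values), 0), 1),
         recorded_iterates = rec,
         log = data.frame(iteration = iterations, loglik = 0),
         algorithm = "fake", config = recon_config(max(iterations))),
    class = "recon_result")
}
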