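# the four EM-family algorithms share one update loop; these tests pin the
# loop (fixed points, likelihood monotonicity, conservation laws) and the
# per-algorithm plumbing around it

noisy_fixture <- function(n = 12, by = 20, counts = 3e4, seed = 2) {
  truth <- make_shepp_logan(n, 1)
  g <- quick_geom(n, by = by)
  psf <- gaussian_kernel(2.4, 1)
  m <- simulate_acquisition(truth, psf, g, count_level("t", counts), seed)
  list(truth = truth, g = g, psf = psf, m = m, n = n)
}

test_that("noiseless consistent data are fixed points of all four algorithms", {
  f <- noisy_fixture()
  tol <- 1e-8 * max(f$truth$values)

  m0 <- forward_project(f$truth, f$g)
  r <- mlem(sinogram(m0$counts, f$g), f$g,
            recon_config(1, initial_image = f$truth), grid_size = f$n)
  expect_lt(max(abs(r$final_image$values - f$truth$values)), tol)

  blur <- apply_psf(f$truth, f$psf)
  mp <- forward_project(blur, f$g)
  r2 <- mlem_psf(sinogram(mp$counts, f$g), f$g, f$psf,
                 recon_config(1, initial_image = f$truth), grid_size = f$n)
  expect_lt(max(abs(r2$final_image$values - f$truth$values)), tol)

  # RL fixed point: the blurred input is consistent with the truth under
  # the PSF forward model, so the truth does not move
  r3 <- richardson_lucy(blur, f$psf, recon_config(1, initial_image = f$truth))
  expect_lt(max(abs(r3$final_image$values - f$truth$values)), tol)

  r4 <- synthesized_recon(f$truth, f$g, NULL,
                          recon_config(1, initial_image = f$truth))
  expect_lt(max(abs(r4$final_image$values - f$truth$values)), tol)
})

test_that("the Poisson log-likelihood is nondecreasing for the EM family", {
  f <- noisy_fixture(n = 8, by = 23, counts = 5e3)
  for (res in list(
    mlem(f$m, f$g, recon_config(50), grid_size = 8),
    mlem_psf(f$m, f$g, f$psf, recon_config(50), grid_size = 8),
    synthesized_recon(get_iterate(mlem(f$m, f$g, recon_config(20),
                                       grid_size = 8), 20),
                      f$g, f$psf, recon_config(50)))) {
    dll <- diff(res$log$loglik)
    expect_true(all(dll >= -1e-7 * abs(res$log$loglik[-1])),
                label = paste(res$algorithm, "monotone log-likelihood"))
  }
})

test_that("MLEM preserves total counts and iterates stay nonnegative", {
  f <- noisy_fixture(n = 12, by = 18, counts = 2e4)
  r <- mlem(f$m, f$g, recon_config(30), grid_size = 12)
  for (k in c(1, 10, 30)) {
    it <- get_iterate(r, k)
    expect_true(all(it$values >= 0))
    tot <- sum(forward_project(it, f$g)$counts)
    expect_lt(abs(tot - sum(f$m$counts)) / sum(f$m$counts), 1e-6)
  }
})

test_that("Richardson-Lucy conserves flux for interior-supported inputs", {
  n <- 33
  inner <- matrix(0, n, n)
  inner[13:21, 13:21] <- matrix(runif(81, 0.5, 2), 9)
  inp <- activity_image(inner, 1)
  psf <- gaussian_kernel(2.0, 1)
  r <- richardson_lucy(inp, psf, recon_config(40))
  for (k in c(1, 20, 40)) {
    tot <- sum(get_iterate(r, k)$values)
    expect_lt(abs(tot - sum(inner)) / sum(inner), 1e-6)
  }
})

test_that("the algebraic equivalence chain ties the five update equations together", {
  f <- noisy_fixture(n = 10, by = 18, counts = 1e4)
  iters <- 60

  # P = I collapses MLEM+PSF onto MLEM (bitwise: same code path)
  a <- mlem(f$m, f$g, recon_config(iters), grid_size = 10)
  b <- mlem_psf(f$m, f$g, identity_kernel(1), recon_config(iters),
                grid_size = 10)
  expect_identical(a$final_image$values, b$final_image$values)

  # psf absent collapses the synthesized problem onto MLEM on m_syn
  inp <- get_iterate(a, 30)
  msyn <- synthesize_data(inp, f$g)
  c1 <- synthesized_recon(inp, f$g, NULL, recon_config(iters))
  c2 <- mlem(msyn, f$g, recon_config(iters), grid_size = 10)
  expect_identical(c1$final_image$values, c2$final_image$values)

  # S = I collapses the synthesized problem onto Richardson-Lucy
  gi <- projection_geometry(identity = TRUE)
  d1 <- synthesized_recon(inp, gi, f$psf,
                          recon_config(iters, initial_image = inp))
  d2 <- richardson_lucy(inp, f$psf, recon_config(iters))
  for (k in c(1, 25, iters)) {
    expect_lt(max(abs(d1$recorded_iterates[[as.character(k)]] -
                      d2$recorded_iterates[[as.character(k)]])),
              1e-8 * max(d2$recorded_iterates[[as.character(k)]]))
  }

  # identity PSF makes every RL iterate the input itself
  e <- richardson_lucy(inp, identity_kernel(1), recon_config(5))
  expect_equal(e$final_image$values, inp$values, tolerance = 1e-14)

  # sigma = 0 virtual data are the plain forward projection
  expect_identical(synthesize_data(inp, f$g)$counts,
                   forward_project(inp, f$g)$counts)
  zero <- activity_image(matrix(0, 10, 10), 1)
  expect_equal(sum(synthesize_data(zero, f$g)$counts), 0)
})

test_that("reconstruction is scale-equivariant in the data", {
  f <- noisy_fixture(n = 10, by = 23, counts = 8e3)
  c3 <- sinogram(f$m$counts * 3, f$g)
  r1 <- mlem(f$m, f$g, recon_config(20), grid_size = 10)
  r3 <- mlem(c3, f$g, recon_config(20), grid_size = 10)
  expect_equal(r3$final_image$values, 3 * r1$final_image$values,
               tolerance = 1e-12)
})

test_that("resolution modeling recovers what unmodeled MLEM cannot", {
  # noiseless blurred acquisition: MLEM+PSF must beat MLEM's best iterate
  n <- 24
  truth <- make_shepp_logan(n, 1)
  g <- quick_geom(n, by = 8)
  psf <- gaussian_kernel(2.9, 1)
  m0 <- forward_project(apply_psf(truth, psf), g)
  rmse_to <- function(v) sqrt(sum((v - truth$values)^2) /
                              sum(truth$values^2))
  r_plain <- mlem(sinogram(m0$counts, g), g, recon_config(300), grid_size = n)
  r_psf <- mlem_psf(sinogram(m0$counts, g), g, psf, recon_config(300),
                    grid_size = n)
  best_plain <- min(vapply(r_plain$recorded_iterates, rmse_to, 0))
  expect_lt(rmse_to(r_psf$final_image$values), best_plain)

  # RL deconvolution improves a blurred image (noiseless)
  sharp <- matrix(0, n, n)
  sharp[10:15, 10:15] <- 2
  sharp_img <- activity_image(sharp, 1)
  blurred <- apply_psf(sharp_img, psf)
  rl <- richardson_lucy(blurred, psf, recon_config(500))
  rmse_sharp <- function(v) sqrt(sum((v - sharp)^2) / sum(sharp^2))
  expect_lt(rmse_sharp(rl$final_image$values), rmse_sharp(blurred$values))

  # synthesized reconstruction recovers a PSF-blurred input end to end
  sy <- synthesized_recon(blurred, g, psf, recon_config(500))
  expect_lt(min(vapply(sy$recorded_iterates, rmse_sharp, 0)),
            rmse_sharp(blurred$values))
})

test_that("inputs are validated and results carry their bookkeeping", {
  f <- noisy_fixture(n = 8, by = 30, counts = 2e3)
  neg <- f$m; neg$counts[1] <- -1
  expect_error(mlem(neg, f$g, recon_config(2), grid_size = 8), "negative")

  r <- mlem(f$m, f$g, recon_config(20, record_every = 5), grid_size = 8)
  expect_equal(names(r$recorded_iterates), as.character(seq(5, 20, 5)))
  expect_error(get_iterate(r, 3), "not recorded")
  expect_equal(coef(r), r$final_image$values)
  expect_output(print(r), "mlem")
  expect_output(summary(r), "monotone")

  rf <- mlem(f$m, f$g, recon_config(5, record_every = NA), grid_size = 8)
  expect_length(rf$recorded_iterates, 0)
})
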