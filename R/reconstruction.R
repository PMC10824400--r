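# EM-family reconstruction algorithms.
#
# All four algorithms share one multiplicative update,
#   theta <- theta / sens * Adj(data / Fwd(theta)),
# differing only in the forward model:
#   MLEM:             Fwd = X,     sens = X^T 1,       data = m
#   MLEM+PSF:         Fwd = X P,   sens = P^T X^T 1,   data = m
#   Richardson-Lucy:  Fwd = P,     sens = P^T 1,       data = theta^(K)
#   synthesized:      Fwd = S P,   sens = P^T S^T 1,   data = S theta^(K)
# They therefore run through one guarded loop, which also makes the
# algebraic equivalences (S = I collapses the synthesized problem onto RL;
# P = I collapses MLEM+PSF onto MLEM) hold to machine precision.

#' Reconstruction configuration
#'
#' @param n_iterations Number of multiplicative updates (`>= 1`). Several
#'   hundred are typically needed for convergence of the EM family; the
#'   package default is 500 with no implicit stopping rule.
#' @param epsilon Relative division guard: denominators are clamped below
#'   at `epsilon * max(denominator)`.
#' @param record_every Stride at which iterates are recorded (1 keeps every
#'   iterate, needed for per-iteration metrics; `NA` records only the
#'   final image).
#' @param initial_image Optional [activity_image()] starting estimate. The
#'   default is uniform ones over the support of the sensitivity image for
#'   the sinogram-domain algorithms, and the input image itself for
#'   Richardson-Lucy.
#'
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 500, epsilon = 1e-12,
                         record_every = 1, initial_image = NULL) {
  if (n_iterations < 1 || n_iterations != round(n_iterations)) {
    stop("'n_iterations' must be a positive integer")
  }
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (!is.null(record_every) && !is.na(record_every) &&
      (record_every < 1 || record_every != round(record_every))) {
    stop("'record_every' must be NA or a positive integer")
  }
  if (!is.null(initial_image)) stopifnot(inherits(initial_image,
                                                  "activity_image"))
  structure(list(n_iterations = as.integer(n_iterations), epsilon = epsilon,
                 record_every = record_every, initial_image = initial_image),
            class = "recon_config")
}

# The shared guarded multiplicative-update loop. fwd/adj map matrices to
# matrices (image -> data and data -> image); data, sens, init are plain
# matrices. Returns final image, recorded iterates, and the Poisson
# log-likelihood sum(data * log q - q) per iteration.
.em_loop <- function(data, fwd, adj, sens, init, config, algorithm,
                     template) {
  eps <- config$epsilon
  live <- sens > eps * max(sens)
  denom <- pmax(sens, eps * max(sens))
  theta <- init
  theta[!live] <- 0

  rec_every <- config$record_every
  record <- !is.null(rec_every) && !is.na(rec_every)
  iters <- config$n_iterations
  recorded <- if (record) {
    vector("list", length(seq(rec_every, iters, by = rec_every)))
  } else list()
  rec_names <- integer(0)
  loglik <- numeric(iters)
  ri <- 0L

  for (k in seq_len(iters)) {
    q <- fwd(theta)
    qc <- pmax(q, eps * max(q, 0) + .Machine$double.xmin)
    loglik[k] <- sum(data[data > 0] * log(qc[data > 0])) - sum(q)
    theta <- theta / denom * adj(data / qc)
    theta[!live] <- 0
    if (record && k %% rec_every == 0) {
      ri <- ri + 1L
      recorded[[ri]] <- theta
      rec_names[ri] <- k
    }
  }
  recorded <- recorded[seq_len(ri)]
  names(recorded) <- rec_names
  structure(
    list(final_image = .as_image(theta, template, label = algorithm),
         recorded_iterates = recorded,
         log = data.frame(iteration = seq_len(iters), loglik = loglik),
         algorithm = algorithm,
         config = config),
    class = "recon_result"
  )
}

.uniform_init <- function(config, sens_values) {
  if (!is.null(config$initial_image)) return(config$initial_image$values)
  init <- matrix(0, nrow(sens_values), ncol(sens_values))
  init[sens_values > 0] <- 1
  init
}

.infer_grid <- function(geometry) {
  # largest square grid whose diagonal the radial window covers; inverse of
  # the default_geometry() sizing rule
  floor((geometry$n_radial_bins - 3) / sqrt(2))
}

.check_data_sino <- function(m, geometry) {
  stopifnot(inherits(m, "sinogram"), inherits(geometry,
                                              "projection_geometry"))
  if (any(m$counts < 0)) stop("measured sinogram has negative entries")
  if (!geometry$identity &&
      (nrow(m$counts) != geometry$n_radial_bins ||
       ncol(m$counts) != length(geometry$angles_deg))) {
    stop("sinogram shape does not match 'geometry'")
  }
}

#' MLEM reconstruction
#'
#' Maximum-likelihood expectation maximization for Poisson sinogram data:
#' `theta <- theta / (X^T 1) * X^T(m / (X theta))`, with epsilon-guarded
#' divisions and pixels of zero sensitivity frozen at 0. Iterates stay
#' nonnegative and the Poisson log-likelihood is nondecreasing.
#'
#' @param m Measured [sinogram()] (nonnegative).
#' @param geometry System [projection_geometry()] (defaults to the
#'   sinogram's own).
#' @param config A [recon_config()].
#' @param grid_size Reconstructed image side length in pixels (default:
#'   inferred from the radial window).
#' @param pixel_size_mm Reconstructed pixel size (default: radial bin
#'   size).
#'
#' @return A [recon_result] object; see [print.recon_result()].
#' @export
mlem <- function(m, geometry = m$geometry, config = recon_config(),
                 grid_size = .infer_grid(geometry),
                 pixel_size_mm = geometry$bin_size_mm) {
  .check_data_sino(m, geometry)
  sens <- sensitivity_image(geometry, grid_size, psf = NULL,
                            pixel_size_mm = pixel_size_mm)
  template <- activity_image(matrix(0, grid_size, grid_size), pixel_size_mm)
  A_fwd <- function(th) forward_project(.as_image(th, template),
                                        geometry)$counts
  A_adj <- function(d) back_project(sinogram(pmax(d, 0), geometry), geometry,
                                    grid_size, pixel_size_mm)$values
  .em_loop(m$counts, A_fwd, A_adj, sens$values,
           .uniform_init(config, sens$values), config, "mlem", template)
}

#' MLEM with PSF modeling
#'
#' Resolution modeling inside the system model via a shift-equivariant
#' image-space kernel P: `theta <- theta / (P^T X^T 1) * P^T X^T(m /
#' (X P theta))`. This is the reference standard for resolution recovery:
#' it needs both the scanner projectors and the raw data.
#'
#' @inheritParams mlem
#' @param psf A [psf_kernel()] whose pixel size matches the reconstruction
#'   grid.
#' @return A [recon_result] object.
#' @export
mlem_psf <- function(m, geometry = m$geometry, psf, config = recon_config(),
                     grid_size = .infer_grid(geometry),
                     pixel_size_mm = geometry$bin_size_mm) {
  .check_data_sino(m, geometry)
  stopifnot(inherits(psf, "psf_kernel"))
  template <- activity_image(matrix(0, grid_size, grid_size), pixel_size_mm)
  .check_psf_pitch(template, psf)
  sens <- sensitivity_image(geometry, grid_size, psf = psf,
                            pixel_size_mm = pixel_size_mm)
  A_fwd <- function(th) {
    forward_project(.as_image(.psf_conv(th, psf), template), geometry)$counts
  }
  A_adj <- function(d) {
    .psf_conv(back_project(sinogram(pmax(d, 0), geometry), geometry,
                           grid_size, pixel_size_mm)$values,
              psf, adjoint = TRUE)
  }
  .em_loop(m$counts, A_fwd, A_adj, sens$values,
           .uniform_init(config, sens$values), config, "mlem_psf", template)
}

#' Richardson-Lucy deconvolution
#'
#' Post-reconstruction image-space deconvolution of an existing
#' reconstruction `theta^(K)` under the PSF forward model:
#' `theta <- theta / (P^T 1) * P^T(theta^(K) / (P theta))`. The default
#' starting estimate is the input image itself.
#'
#' @param input_image Nonnegative [activity_image()], typically an MLEM
#'   reconstruction stopped at K iterations.
#' @param psf A [psf_kernel()] matching the image pixel size.
#' @param config A [recon_config()].
#' @return A [recon_result] object.
#' @export
richardson_lucy <- function(input_image, psf, config = recon_config()) {
  stopifnot(inherits(input_image, "activity_image"),
            inherits(psf, "psf_kernel"))
  .check_psf_pitch(input_image, psf)
  n <- nrow(input_image$values)
  sens <- .psf_conv(matrix(1, n, n), psf, adjoint = TRUE)
  init <- if (!is.null(config$initial_image)) {
    config$initial_image$values
  } else input_image$values
  .em_loop(input_image$values,
           function(th) .psf_conv(th, psf),
           function(d) .psf_conv(d, psf, adjoint = TRUE),
           sens, init, config, "richardson_lucy", input_image)
}

#' Synthesize sinogram data from an existing reconstruction
#'
#' The noiseless forward projection `m_syn = S theta^(K)` of an input image
#' through a user-chosen virtual scanner geometry (including its
#' line-thickness blur, if set). No Poisson noise is added: the synthetic
#' data are exactly consistent with the virtual system model.
#'
#' @param input_image Nonnegative [activity_image()].
#' @param virtual_geometry [projection_geometry()] of the virtual scanner.
#' @return A [sinogram()].
#' @export
synthesize_data <- function(input_image, virtual_geometry) {
  stopifnot(inherits(input_image, "activity_image"))
  forward_project(input_image, virtual_geometry)
}

#' Synthesized reconstruction (the proposed resolution-recovery method)
#'
#' Forward projects an existing reconstruction through a virtual scanner
#' (`m_syn = S theta^(K)`, [synthesize_data()]), then reconstructs the
#' synthetic data with the PSF inside the virtual system model:
#' `theta <- theta / (P^T S^T 1) * P^T S^T(m_syn / (S P theta))`.
#' Only the input image and the PSF kernel are required -- no scanner
#' projectors, no raw sinogram. With `psf = NULL` the PSF factor is
#' dropped (the no-PSF variant, plain MLEM on the synthetic data).
#'
#' @inheritParams synthesize_data
#' @param psf Optional [psf_kernel()]; `NULL` gives the no-PSF variant.
#' @param config A [recon_config()]. The default starting estimate is
#'   uniform, as for MLEM; pass `initial_image` to override (e.g. to start
#'   from the input image, which with an identity virtual geometry makes
#'   the iterates coincide with Richardson-Lucy's).
#' @return A [recon_result] object.
#' @export
synthesized_recon <- function(input_image, virtual_geometry, psf = NULL,
                              config = recon_config()) {
  stopifnot(inherits(input_image, "activity_image"))
  m_syn <- synthesize_data(input_image, virtual_geometry)
  n <- nrow(input_image$values)
  px <- input_image$pixel_size_mm
  if (!is.null(psf)) .check_psf_pitch(input_image, psf)
  sens <- sensitivity_image(virtual_geometry, n, psf = psf,
                            pixel_size_mm = px)
  template <- activity_image(matrix(0, n, n), px)
  S_fwd <- function(th) forward_project(.as_image(th, template),
                                        virtual_geometry)$counts
  S_adj <- function(d) back_project(sinogram(pmax(d, 0), virtual_geometry),
                                    virtual_geometry, n, px)$values
  if (is.null(psf)) {
    fwd <- S_fwd; adj <- S_adj
    algo <- "synthesized_nopsf"
  } else {
    fwd <- function(th) S_fwd(.psf_conv(th, psf))
    adj <- function(d) .psf_conv(S_adj(d), psf, adjoint = TRUE)
    algo <- "synthesized"
  }
  .em_loop(m_syn$counts, fwd, adj, sens$values,
           .uniform_init(config, sens$values), config, algo, template)
}

#' Extract a recorded iterate
#'
#' @param result A `recon_result`.
#' @param k Iteration number; must have been recorded (see
#'   `record_every` in [recon_config()]).
#' @return An [activity_image()].
#' @export
get_iterate <- function(result, k) {
  stopifnot(inherits(result, "recon_result"))
  v <- result$recorded_iterates[[as.character(k)]]
  if (is.null(v)) stop(sprintf("iteration %s was not recorded", k))
  .as_image(v, result$final_image, label = paste0(result$algorithm, " k=", k))
}

#' @rdname mlem
#' @param x,object A `recon_result`.
#' @param ... Unused.
#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, %d iterations (%d recorded)\n",
              x$algorithm, x$config$n_iterations,
              length(x$recorded_iterates)))
  ll <- x$log$loglik
  cat(sprintf("  log-likelihood %.6g -> %.6g\n", ll[1], ll[length(ll)]))
  invisible(x)
}

#' @rdname mlem
#' @export
summary.recon_result <- function(object, ...) {
  img <- object$final_image
  cat(sprintf("%s reconstruction, %dx%d @ %g mm\n", object$algorithm,
              nrow(img$values), ncol(img$values), img$pixel_size_mm))
  cat(sprintf("  iterations: %d, recorded: %d\n", object$config$n_iterations,
              length(object$recorded_iterates)))
  cat(sprintf("  final image range [%.4g, %.4g], total activity %.6g\n",
              min(img$values), max(img$values),
              sum(img$values) * img$pixel_size_mm^2))
  dll <- diff(object$log$loglik)
  cat(sprintf("  log-likelihood monotone: %s\n",
              all(dll >= -1e-6 * abs(object$log$loglik[-1]))))
  invisible(object)
}

#' @rdname mlem
#' @export
coef.recon_result <- function(object, ...) object$final_image$values

#' @rdname mlem
#' @param which Plot the final `"image"` or the `"loglik"` trace.
#' @export
plot.recon_result <- function(x, which = c("image", "loglik"), ...) {
  which <- match.arg(which)
  if (which == "image") {
    plot(x$final_image, main = x$algorithm, ...)
  } else {
    plot(x$log$iteration, x$log$loglik, type = "l", xlab = "iteration",
         ylab = "Poisson log-likelihood", main = x$algorithm, ...)
  }
  invisible(x)
}
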