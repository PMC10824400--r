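# Noisy acquisition simulation: blur the ground truth with the positron-
# range PSF, forward project it, scale to a target expected count total,
# and draw independent Poisson counts per sinogram bin. No attenuation,
# scatter, randoms or normalization effects are simulated.

#' Acquisition count level
#'
#' The expected total number of detected counts over the whole sinogram,
#' which governs Poisson noise severity.
#'
#' @param name Level name, conventionally `"high"`, `"mid"` or `"low"`.
#' @param total_expected_counts Expected sinogram count total (positive).
#'
#' @return An object of class `count_level`.
#' @seealso [default_count_levels()]
#' @export
count_level <- function(name, total_expected_counts) {
  if (!is.numeric(total_expected_counts) ||
      length(total_expected_counts) != 1 || total_expected_counts <= 0) {
    stop("'total_expected_counts' must be a single positive number")
  }
  structure(list(name = as.character(name),
                 total_expected_counts = total_expected_counts),
            class = "count_level")
}

#' Default high/mid/low count levels
#'
#' 1e7, 1e6 and 1e5 expected total counts. These span the regimes where
#' post-reconstruction Richardson-Lucy degrades sharply (low counts) up to
#' near-noiseless behaviour (high counts) at desk-scale runtimes for a
#' 128x128 phantom projected over 180 angles.
#'
#' @return Named list of three [count_level()] objects.
#' @export
default_count_levels <- function() {
  list(high = count_level("high", 1e7),
       mid = count_level("mid", 1e6),
       low = count_level("low", 1e5))
}

#' Simulate one noisy acquisition
#'
#' The three-step protocol: (1) blur the ground truth with the PSF model,
#' (2) forward project the blurred image through the scanner geometry,
#' (3) scale the noiseless sinogram so its total equals the count level's
#' expectation and draw independent Poisson counts per bin.
#'
#' @param truth Ground-truth [activity_image()].
#' @param psf [psf_kernel()] modelling the resolution loss (use
#'   [identity_kernel()] for a resolution-perfect scanner).
#' @param geometry [projection_geometry()] of the (native) scanner.
#' @param level [count_level()].
#' @param seed Integer seed; identical arguments give bit-identical output.
#'   The caller's RNG state is left untouched.
#'
#' @return A [sinogram()] of integer counts, with the scaled noiseless mean
#'   attached as field `mean_counts` and the global count-scale multiplier
#'   as field `scale_factor` (see [scaled_truth()]).
#' @export
simulate_acquisition <- function(truth, psf, geometry, level, seed) {
  stopifnot(inherits(truth, "activity_image"), inherits(psf, "psf_kernel"),
            inherits(geometry, "projection_geometry"),
            inherits(level, "count_level"))
  blurred <- apply_psf(truth, psf)
  noiseless <- forward_project(blurred, geometry)
  tot <- sum(noiseless$counts)
  if (tot <= 0) stop("the noiseless sinogram is identically zero")
  scale_factor <- level$total_expected_counts / tot
  lambda <- noiseless$counts * scale_factor

  counts <- .with_seed(seed, {
    matrix(rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
  })
  out <- sinogram(counts, geometry)
  out$mean_counts <- lambda
  out$count_level <- level
  out$seed <- as.integer(seed)
  out$scale_factor <- scale_factor
  out
}

#' Ground truth on the acquisition count scale
#'
#' Reconstructions of simulated data live on the scale of the (count-level
#' scaled) sinogram, not of the original phantom. This returns the truth
#' multiplied by the simulation's global scale factor, which is the
#' reference object the bias/stddev/RMSE metrics must be evaluated
#' against.
#'
#' @param truth The [activity_image()] that was simulated.
#' @param sim A [sinogram()] from [simulate_acquisition()] or a
#'   `realization_set` from [make_realizations()].
#' @return An [activity_image()].
#' @export
scaled_truth <- function(truth, sim) {
  stopifnot(inherits(truth, "activity_image"))
  sf <- if (inherits(sim, "realization_set")) {
    sim$sinograms[[1]]$scale_factor
  } else sim$scale_factor
  if (is.null(sf)) stop("'sim' carries no scale factor")
  .as_image(truth$values * sf, truth)
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a set of independent noise realizations
#'
#' Realization `q` (1-based) uses seed `base_seed + q - 1`, so sets are
#' reproducible and extensible.
#'
#' @inheritParams simulate_acquisition
#' @param Q Number of realizations (`>= 1`). The study uses Q = 10 for
#'   global/medium-ROI metrics and Q = 100 for the small ROI.
#' @param base_seed Integer seed of the first realization.
#'
#' @return An object of class `realization_set`: list with `sinograms`
#'   (length Q), `base_seed` and `count_level`.
#' @export
make_realizations <- function(truth, psf, geometry, level, Q, base_seed) {
  if (!is.numeric(Q) || length(Q) != 1 || Q < 1 || Q != round(Q)) {
    stop("'Q' must be a positive integer")
  }
  sims <- lapply(seq_len(Q), function(q) {
    simulate_acquisition(truth, psf, geometry, level, base_seed + q - 1)
  })
  structure(list(sinograms = sims, base_seed = as.integer(base_seed),
                 count_level = level),
            class = "realization_set")
}

#' @export
print.realization_set <- function(x, ...) {
  cat(sprintf(
    "<realization_set> Q=%d, level '%s' (%.3g expected counts), seeds %d..%d\n",
    length(x$sinograms), x$count_level$name,
    x$count_level$total_expected_counts, x$base_seed,
    x$base_seed + length(x$sinograms) - 1L))
  invisible(x)
}

#' @export
length.realization_set <- function(x) length(x$sinograms)
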