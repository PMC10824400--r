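# Quantitative evaluation over noise realizations.
#
# At iteration k, with Q realizations, ROI Omega and truth theta_ref:
#   Bias   = sqrt( sum_Omega (mean_q theta - theta_ref)^2 / sum_Omega theta_ref^2 )
#   StdDev = sqrt( (1/Q) sum_q sum_Omega (mean_q theta - theta^(q))^2
#                  / sum_Omega theta_ref^2 )
#   RMSE   = sqrt( Bias^2 + StdDev^2 )
# all reported as percentages. The 1/Q (population) convention is used for
# StdDev, exactly as the metric is defined for this study; readers used to
# the 1/(Q-1) sample convention should note the difference. RMSE is never
# stored independently of its components, so the identity
# RMSE^2 = Bias^2 + StdDev^2 holds structurally.

#' Bias / standard deviation / RMSE over noise realizations
#'
#' Computes the normalized bias, standard deviation and RMSE of a set of
#' reconstructions against the ground truth, per recorded iteration, over
#' a region of interest.
#'
#' @param results List of `recon_result` objects, one per noise
#'   realization, sharing the same recorded iteration grid.
#' @param truth Ground-truth [activity_image()] of matching size.
#' @param roi An [roi_mask()]; metrics are evaluated over its member
#'   pixels. The truth must not be identically zero there.
#'
#' @return A `metric_series`: a data frame with columns `iteration`,
#'   `bias_pct`, `stddev_pct`, `rmse_pct`, plus attributes `roi` (name)
#'   and `Q`.
#' @export
compute_metrics <- function(results, truth, roi) {
  if (inherits(results, "recon_result")) results <- list(results)
  stopifnot(length(results) >= 1, inherits(truth, "activity_image"),
            inherits(roi, "roi_mask"))
  if (!all(dim(roi$mask) == dim(truth$values))) {
    stop("ROI and truth dimensions differ")
  }
  iters <- names(results[[1]]$recorded_iterates)
  for (r in results) {
    if (!identical(names(r$recorded_iterates), iters)) {
      stop("all realizations must share the same recorded iteration grid")
    }
    if (!all(dim(r$final_image$values) == dim(truth$values))) {
      stop("reconstruction and truth dimensions differ")
    }
  }
  if (length(iters) == 0) stop("no recorded iterates to evaluate")
  om <- which(roi$mask)
  ref <- truth$values[om]
  denom <- sum(ref^2)
  if (denom <= 0) {
    stop("the truth is identically zero on the ROI (normalizer vanishes)")
  }
  Q <- length(results)

  out <- data.frame(iteration = as.integer(iters), bias_pct = NA_real_,
                    stddev_pct = NA_real_, rmse_pct = NA_real_)
  for (i in seq_along(iters)) {
    k <- iters[i]
    mat <- vapply(results, function(r) r$recorded_iterates[[k]][om],
                  numeric(length(om)))
    mbar <- rowMeans(mat)
    bias <- sqrt(sum((mbar - ref)^2) / denom)
    stddev <- sqrt(sum((mat - mbar)^2) / Q / denom)
    out$bias_pct[i] <- 100 * bias
    out$stddev_pct[i] <- 100 * stddev
    out$rmse_pct[i] <- 100 * sqrt(bias^2 + stddev^2)
  }
  structure(out, class = c("metric_series", "data.frame"),
            roi = roi$name, Q = Q)
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> ROI '%s', Q=%d, %d iterations\n",
              attr(x, "roi"), attr(x, "Q"), nrow(x)))
  mm <- min_rmse(x)
  cat(sprintf("  min RMSE %.2f%% at iteration %d\n", mm$rmse, mm$iteration))
  NextMethod()
}

#' @export
plot.metric_series <- function(x, ...) {
  plot(x$iteration, x$rmse_pct, type = "l", xlab = "iteration",
       ylab = "normalized RMSE (%)",
       main = sprintf("ROI '%s' (Q=%d)", attr(x, "roi"), attr(x, "Q")), ...)
  lines(x$iteration, x$bias_pct, lty = 2)
  lines(x$iteration, x$stddev_pct, lty = 3)
  legend("topright", c("RMSE", "bias", "stddev"), lty = 1:3, bty = "n")
  invisible(x)
}

#' Minimum-RMSE iteration of a metric series
#'
#' The earliest recorded iteration attaining the minimum RMSE (ties broken
#' to the smallest iteration number).
#'
#' @param series A `metric_series` from [compute_metrics()].
#' @return List with elements `iteration` and `rmse` (percent).
#' @export
min_rmse <- function(series) {
  stopifnot(inherits(series, "metric_series"), nrow(series) >= 1)
  i <- which.min(series$rmse_pct)  # which.min returns the first minimum
  list(iteration = series$iteration[i], rmse = series$rmse_pct[i])
}

#' Bias--standard deviation trajectory
#'
#' The per-iteration (bias, stddev) path traced by an algorithm, used for
#' tradeoff plots: early stopping moves along this path, and methods are
#' compared by which path dominates.
#'
#' @param series A `metric_series`.
#' @return Data frame with columns `iteration`, `bias_pct`, `stddev_pct`,
#'   ordered by iteration.
#' @export
bias_stddev_trajectory <- function(series) {
  stopifnot(inherits(series, "metric_series"), nrow(series) >= 1)
  data.frame(iteration = series$iteration, bias_pct = series$bias_pct,
             stddev_pct = series$stddev_pct)
}
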