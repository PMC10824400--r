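# Config-driven orchestration of the comparison studies: one fully seeded
# configuration object, plus drivers for the method comparison and the
# three hyperparameter sweeps (virtual projection angles, line-thickness
# sigma, and input-image iteration count K). Results are returned as plain
# data frames (and optionally written as CSV + a YAML manifest), so
# downstream comparisons are numeric, not graphical.

#' Experiment configuration
#'
#' Bundles every knob of a simulation experiment. A configuration plus its
#' seeds fully determines all outputs bit-for-bit.
#'
#' @param phantom One of `"shepp-logan"`, `"thorax"`, `"derenzo"`.
#' @param grid_size,pixel_size_mm Phantom grid (defaults 128 px at 1 mm;
#'   the Derenzo phantom defaults to 240 px at 0.25 mm if left `NULL`).
#' @param psf_fwhm_mm Gaussian positron-range FWHM in mm (default 2.9, the
#'   gallium-68 surrogate).
#' @param angles_deg Native scanner angles (default 1--180 deg, 1 deg
#'   steps).
#' @param virtual_angles_deg Virtual scanner angles for the synthesized
#'   reconstruction (default: same as native).
#' @param line_sigma_px Line-thickness sigma of the virtual scanner, in
#'   pixels (default 0).
#' @param count_levels Named list of [count_level()] objects (default
#'   [default_count_levels()]).
#' @param K Iteration count of the MLEM reconstruction supplying the input
#'   image (default 64, a typical clinical software setting).
#' @param Q Noise realizations per count level (default 10).
#' @param n_iterations Iteration budget per method (default 500).
#' @param base_seed Integer; realization q at count level number L uses
#'   seed `base_seed + 10000 * (L - 1) + q - 1`.
#' @param out_dir Optional output directory for CSV tables and a manifest.
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = c("shepp-logan", "thorax", "derenzo"),
                              grid_size = NULL, pixel_size_mm = NULL,
                              psf_fwhm_mm = 2.9,
                              angles_deg = 1:180,
                              virtual_angles_deg = NULL,
                              line_sigma_px = 0,
                              count_levels = default_count_levels(),
                              K = 64, Q = 10, n_iterations = 500,
                              base_seed = 1, out_dir = NULL) {
  phantom <- match.arg(phantom)
  if (is.null(grid_size)) {
    grid_size <- if (phantom == "derenzo") 240L else 128L
  }
  if (is.null(pixel_size_mm)) {
    pixel_size_mm <- if (phantom == "derenzo") 0.25 else 1
  }
  if (inherits(count_levels, "count_level")) {
    count_levels <- stats::setNames(list(count_levels), count_levels$name)
  }
  stopifnot(length(count_levels) >= 1,
            all(vapply(count_levels, inherits, TRUE, "count_level")),
            K >= 1, Q >= 1, n_iterations >= 1)
  if (is.null(names(count_levels))) {
    names(count_levels) <- vapply(count_levels, `[[`, "", "name")
  }
  structure(
    list(phantom = phantom, grid_size = as.integer(grid_size),
         pixel_size_mm = pixel_size_mm, psf_fwhm_mm = psf_fwhm_mm,
         angles_deg = angles_deg,
         virtual_angles_deg = virtual_angles_deg %||% angles_deg,
         line_sigma_px = line_sigma_px,
         count_levels = count_levels, K = as.integer(K), Q = as.integer(Q),
         n_iterations = as.integer(n_iterations),
         base_seed = as.integer(base_seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s %dpx @ %g mm | PSF %g mm FWHM | %d angles\n",
    x$phantom, x$grid_size, x$pixel_size_mm, x$psf_fwhm_mm,
    length(x$angles_deg)))
  cat(sprintf("  levels: %s | K=%d Q=%d iters=%d seed=%d\n",
              paste(names(x$count_levels), collapse = "/"), x$K, x$Q,
              x$n_iterations, x$base_seed))
  invisible(x)
}

.phantom_from_config <- function(config) {
  switch(config$phantom,
         "shepp-logan" = make_shepp_logan(config$grid_size,
                                          config$pixel_size_mm),
         "thorax" = make_thorax(config$grid_size, config$pixel_size_mm),
         "derenzo" = make_derenzo(grid_size = config$grid_size,
                                  pixel_size_mm = config$pixel_size_mm))
}

.rois_from_config <- function(config, truth) {
  if (config$phantom == "thorax") {
    make_roi_masks(truth)
  } else {
    list(global = roi_mask(matrix(TRUE, config$grid_size, config$grid_size),
                           "global"))
  }
}

.level_seed <- function(config, level_index) {
  config$base_seed + 10000L * (level_index - 1L)
}

# run one algorithm over Q realizations/inputs, compute metric series per
# ROI, keep snapshot images from realization 1, then drop the iterates
.eval_method <- function(run_one, Q, truth, rois, snapshot_iter) {
  runs <- lapply(seq_len(Q), run_one)
  series <- lapply(rois, function(roi) compute_metrics(runs, truth, roi))
  mm <- min_rmse(series[[1]])
  rec1 <- runs[[1]]$recorded_iterates
  snap_at <- function(k) {
    k <- as.character(min(as.integer(k),
                          max(as.integer(names(rec1)))))
    .as_image(rec1[[k]], truth, label = runs[[1]]$algorithm)
  }
  list(series = series,
       images = list(min_rmse = snap_at(mm$iteration),
                     standard = snap_at(snapshot_iter)),
       min_rmse = mm)
}

.summary_rows <- function(series_by_roi, method, level_name) {
  do.call(rbind, lapply(series_by_roi, function(s) {
    mm <- min_rmse(s)
    data.frame(method = method, level = level_name, roi = attr(s, "roi"),
               Q = attr(s, "Q"), min_rmse_pct = mm$rmse,
               min_rmse_iteration = mm$iteration)
  }))
}

#' Compare all resolution-recovery methods on one simulated study
#'
#' For each count level: simulates Q noisy acquisitions of the configured
#' phantom, reconstructs each with the requested methods (the MLEM input
#' image at K iterations is always computed, since the post-reconstruction
#' methods consume it), and evaluates bias/stddev/RMSE per iteration over
#' each available ROI. Also records each method's image at its minimum-RMSE
#' iteration and at the "standard" iteration 64.
#'
#' @param config An [experiment_config()].
#' @param methods Subset of `c("mlem", "mlem_psf", "richardson_lucy",
#'   "synthesized", "synthesized_nopsf")`.
#'
#' @return An object of class `method_comparison`: list with `summary`
#'   (data frame of min-RMSE per method/level/ROI), `series` (nested list
#'   `[[level]][[method]][[roi]]` of `metric_series`), `images`
#'   (`[[level]][[method]]`), and the `config`. If `config$out_dir` is set,
#'   CSV tables and a YAML manifest are written there.
#' @export
run_method_comparison <- function(config,
                                  methods = c("mlem", "mlem_psf",
                                              "richardson_lucy",
                                              "synthesized",
                                              "synthesized_nopsf")) {
  stopifnot(inherits(config, "experiment_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- .phantom_from_config(config)
  rois <- .rois_from_config(config, truth)
  psf <- gaussian_kernel(config$psf_fwhm_mm, config$pixel_size_mm)
  native <- default_geometry(truth, angles_deg = config$angles_deg)
  virtual <- default_geometry(truth, angles_deg = config$virtual_angles_deg,
                              line_sigma_px = config$line_sigma_px)
  n_iter <- config$n_iterations
  cfg_full <- recon_config(n_iterations = n_iter, record_every = 1)
  need_inputs <- any(methods %in% c("richardson_lucy", "synthesized",
                                    "synthesized_nopsf"))

  summary <- NULL
  series <- list()
  images <- list()
  for (li in seq_along(config$count_levels)) {
    level <- config$count_levels[[li]]
    lname <- names(config$count_levels)[li]
    rs <- make_realizations(truth, psf, native, level, config$Q,
                            .level_seed(config, li))
    truth_ref <- scaled_truth(truth, rs)

    # the MLEM pass doubles as comparator and input-image supplier; when
    # the comparator itself is not requested it only needs to reach K
    mlem_iters <- if ("mlem" %in% methods) max(n_iter, config$K) else config$K
    mlem_runs <- lapply(rs$sinograms, function(s) {
      mlem(s, native, recon_config(n_iterations = mlem_iters,
                                   record_every = 1),
           grid_size = config$grid_size,
           pixel_size_mm = config$pixel_size_mm)
    })
    inputs <- if (need_inputs) {
      lapply(mlem_runs, get_iterate, k = config$K)
    }
    lvl_series <- list(); lvl_images <- list()
    if ("mlem" %in% methods) {
      s <- lapply(rois, function(roi) compute_metrics(mlem_runs, truth_ref, roi))
      mm <- min_rmse(s[[1]])
      rec1 <- mlem_runs[[1]]$recorded_iterates
      lvl_series$mlem <- s
      lvl_images$mlem <- list(
        min_rmse = .as_image(rec1[[as.character(mm$iteration)]], truth,
                             "mlem"),
        standard = .as_image(rec1[[as.character(min(64, mlem_iters))]],
                             truth, "mlem"))
      summary <- rbind(summary, .summary_rows(s, "mlem", lname))
    }
    rm(mlem_runs)

    runners <- list(
      mlem_psf = function(q) mlem_psf(rs$sinograms[[q]], native, psf,
                                      cfg_full,
                                      grid_size = config$grid_size,
                                      pixel_size_mm = config$pixel_size_mm),
      richardson_lucy = function(q) richardson_lucy(inputs[[q]], psf,
                                                    cfg_full),
      synthesized = function(q) synthesized_recon(inputs[[q]], virtual, psf,
                                                  cfg_full),
      synthesized_nopsf = function(q) synthesized_recon(inputs[[q]], virtual,
                                                        NULL, cfg_full)
    )
    for (meth in intersect(methods, names(runners))) {
      ev <- .eval_method(runners[[meth]], config$Q, truth_ref, rois,
                         snapshot_iter = 64)
      lvl_series[[meth]] <- ev$series
      lvl_images[[meth]] <- ev$images
      summary <- rbind(summary, .summary_rows(ev$series, meth, lname))
    }
    series[[lname]] <- lvl_series
    images[[lname]] <- lvl_images
  }
  rownames(summary) <- NULL
  out <- structure(list(summary = summary, series = series, images = images,
                        config = config),
                   class = "method_comparison")
  .write_outputs(out, config)
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$summary)
  invisible(x)
}

# shared scaffolding for the three sweeps: phantom, PSF, realizations at
# the first configured count level, MLEM inputs, and comparator references
.sweep_context <- function(config, need_rl = TRUE) {
  truth <- .phantom_from_config(config)
  rois <- .rois_from_config(config, truth)
  psf <- gaussian_kernel(config$psf_fwhm_mm, config$pixel_size_mm)
  native <- default_geometry(truth, angles_deg = config$angles_deg)
  level <- config$count_levels[[1]]
  rs <- make_realizations(truth, psf, native, level, config$Q,
                          .level_seed(config, 1L))
  truth_ref <- scaled_truth(truth, rs)
  cfg_full <- recon_config(n_iterations = config$n_iterations,
                           record_every = 1)
  mlem_iters <- max(config$n_iterations, config$K)
  mlem_runs <- lapply(rs$sinograms, function(s) {
    mlem(s, native, recon_config(n_iterations = mlem_iters,
                                 record_every = 1),
         grid_size = config$grid_size, pixel_size_mm = config$pixel_size_mm)
  })
  mlem_min <- min_rmse(compute_metrics(mlem_runs, truth_ref, rois$global))
  inputs <- lapply(mlem_runs, get_iterate, k = config$K)
  get_inputs_at <- function(K) lapply(mlem_runs, get_iterate, k = K)

  psf_runs <- lapply(rs$sinograms, function(s) {
    mlem_psf(s, native, psf, cfg_full, grid_size = config$grid_size,
             pixel_size_mm = config$pixel_size_mm)
  })
  psf_min <- min_rmse(compute_metrics(psf_runs, truth_ref, rois$global))
  rm(psf_runs)

  rl_min <- NULL
  if (need_rl) {
    rl_runs <- lapply(inputs, richardson_lucy, psf = psf, config = cfg_full)
    rl_min <- min_rmse(compute_metrics(rl_runs, truth_ref, rois$global))
    rm(rl_runs)
  }
  list(truth = truth, truth_ref = truth_ref, rois = rois, psf = psf,
       native = native, level = level,
       inputs = inputs, get_inputs_at = get_inputs_at, cfg_full = cfg_full,
       mlem_min = mlem_min, psf_min = psf_min, rl_min = rl_min,
       config = config, mlem_runs_env = environment())
}

.synth_min <- function(ctx, virtual, psf = ctx$psf, inputs = ctx$inputs) {
  runs <- lapply(inputs, synthesized_recon, virtual_geometry = virtual,
                 psf = psf, config = ctx$cfg_full)
  min_rmse(compute_metrics(runs, ctx$truth_ref, ctx$rois$global))
}

.reference_rows <- function(ctx, sweep_col) {
  ref <- data.frame(
    method = c("mlem", "mlem_psf",
               if (!is.null(ctx$rl_min)) "richardson_lucy"),
    min_rmse_pct = c(ctx$mlem_min$rmse, ctx$psf_min$rmse,
                     if (!is.null(ctx$rl_min)) ctx$rl_min$rmse),
    min_rmse_iteration = c(ctx$mlem_min$iteration, ctx$psf_min$iteration,
                           if (!is.null(ctx$rl_min)) ctx$rl_min$iteration))
  ref[[sweep_col]] <- NA
  ref
}

#' Sweep the number of virtual projection angles
#'
#' Runs the synthesized reconstruction with virtual geometries of 1 deg
#' steps from 1 deg up to each requested maximum angle, and reports the
#' global minimum RMSE per angle count. The comparator methods do not
#' depend on the virtual geometry and appear as reference rows (sweep
#' column `NA`).
#'
#' @param config An [experiment_config()]; the sweep uses its first count
#'   level.
#' @param max_angles_list Integer vector of maximum angles, each in 1--180.
#' @return A data frame with columns `method`, `n_angles`, `min_rmse_pct`,
#'   `min_rmse_iteration`.
#' @export
run_angle_sweep <- function(config, max_angles_list) {
  stopifnot(inherits(config, "experiment_config"))
  if (any(max_angles_list < 1 | max_angles_list > 180 |
          max_angles_list != round(max_angles_list))) {
    stop("'max_angles_list' entries must be integers in 1..180")
  }
  ctx <- .sweep_context(config)
  rows <- lapply(max_angles_list, function(N) {
    virtual <- default_geometry(ctx$truth, angles_deg = seq_len(N))
    mm <- .synth_min(ctx, virtual)
    data.frame(method = "synthesized", n_angles = N, min_rmse_pct = mm$rmse,
               min_rmse_iteration = mm$iteration)
  })
  out <- rbind(do.call(rbind, rows), .reference_rows(ctx, "n_angles"))
  rownames(out) <- NULL
  out
}

#' Sweep the virtual line-thickness sigma
#'
#' The line thickness blurs the input image inside the virtual forward
#' projection (an isotropic Gaussian of the given sigma, in pixels), and
#' the same Gaussian is part of the modelled system, so the synthesized
#' reconstruction attempts to recover the introduced blur. `sigma = 0`
#' reproduces the plain synthesized reconstruction.
#'
#' @inheritParams run_angle_sweep
#' @param sigma_list Nonnegative line-thickness values in pixels.
#' @return A data frame with columns `method`, `line_sigma_px`,
#'   `min_rmse_pct`, `min_rmse_iteration`.
#' @export
run_sigma_sweep <- function(config, sigma_list) {
  stopifnot(inherits(config, "experiment_config"))
  if (any(sigma_list < 0)) stop("'sigma_list' entries must be >= 0")
  ctx <- .sweep_context(config)
  rows <- lapply(sigma_list, function(sg) {
    virtual <- default_geometry(ctx$truth,
                                angles_deg = config$virtual_angles_deg,
                                line_sigma_px = sg)
    mm <- .synth_min(ctx, virtual)
    data.frame(method = "synthesized", line_sigma_px = sg,
               min_rmse_pct = mm$rmse, min_rmse_iteration = mm$iteration)
  })
  out <- rbind(do.call(rbind, rows), .reference_rows(ctx, "line_sigma_px"))
  rownames(out) <- NULL
  out
}

#' Sweep the iteration count K of the supplied MLEM input image
#'
#' Measures how strongly the two post-reconstruction methods depend on
#' input-image quality: for each K, the MLEM reconstruction stopped at K
#' iterations supplies the input to both Richardson-Lucy and the
#' synthesized reconstruction. MLEM and MLEM+PSF operate on the sinogram
#' and appear as constant reference rows.
#'
#' @inheritParams run_angle_sweep
#' @param K_list Positive integer iteration counts.
#' @return A data frame with columns `method`, `K`, `min_rmse_pct`,
#'   `min_rmse_iteration`.
#' @export
run_input_quality_sweep <- function(config, K_list) {
  stopifnot(inherits(config, "experiment_config"))
  if (any(K_list < 1 | K_list != round(K_list))) {
    stop("'K_list' entries must be positive integers")
  }
  cfg2 <- config
  # the MLEM pass must reach the largest requested K
  cfg2$n_iterations <- max(config$n_iterations, max(K_list))
  ctx <- .sweep_context(cfg2, need_rl = FALSE)
  virtual <- default_geometry(ctx$truth,
                              angles_deg = config$virtual_angles_deg,
                              line_sigma_px = config$line_sigma_px)
  cfg_run <- recon_config(n_iterations = config$n_iterations,
                          record_every = 1)
  ctx$cfg_full <- cfg_run
  rows <- lapply(K_list, function(K) {
    inputs <- ctx$get_inputs_at(K)
    rl_runs <- lapply(inputs, richardson_lucy, psf = ctx$psf,
                      config = cfg_run)
    rl_mm <- min_rmse(compute_metrics(rl_runs, ctx$truth_ref, ctx$rois$global))
    rm(rl_runs)
    sy_mm <- .synth_min(ctx, virtual, inputs = inputs)
    rbind(
      data.frame(method = "richardson_lucy", K = K,
                 min_rmse_pct = rl_mm$rmse,
                 min_rmse_iteration = rl_mm$iteration),
      data.frame(method = "synthesized", K = K, min_rmse_pct = sy_mm$rmse,
                 min_rmse_iteration = sy_mm$iteration))
  })
  out <- rbind(do.call(rbind, rows), .reference_rows(ctx, "K"))
  rownames(out) <- NULL
  out
}

# CSV + manifest output for run_method_comparison
.write_outputs <- function(result, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$summary, file.path(config$out_dir, "summary.csv"),
            row.names = FALSE)
  for (lname in names(result$series)) {
    for (meth in names(result$series[[lname]])) {
      for (rname in names(result$series[[lname]][[meth]])) {
        s <- result$series[[lname]][[meth]][[rname]]
        df <- as.data.frame(s)
        df$roi <- rname; df$method <- meth; df$count_level <- lname
        df$seed_base <- config$base_seed
        write.csv(df, file.path(config$out_dir,
                                sprintf("series_%s_%s_%s.csv", lname, meth,
                                        rname)),
                  row.names = FALSE)
      }
    }
  }
  manifest <- config
  manifest$count_levels <- lapply(config$count_levels,
                                  function(l) l$total_expected_counts)
  class(manifest) <- NULL
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(NULL)
}
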