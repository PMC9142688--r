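#' Pipeline configuration
#'
#' Central, validated container for the tunable parameters of the whole
#' pipeline, with the standard defaults: M = 8 patches per side, 500-frame
#' warp blocks, 2500-frame rigid templates, 5500-frame warp template,
#' 32-pixel normalization kernel.
#'
#' @param M patches per side for warp correction.
#' @param block_size warp-block length in frames.
#' @param rigid_template_len frames per rigid template.
#' @param warp_template_len frames for the fixed warp template.
#' @param kernel_radius disk-kernel radius in pixels.
#' @param max_shift rigid search bound in px (`NULL` = `min(H, W) / 4`).
#' @param ecc an [ecc_config()].
#' @param seed RNG seed recorded with outputs.
#' @param skip_rigid,skip_warp stage toggles.
#' @param mmd_window mMD downsampling window in frames.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(M = 8L, block_size = 500L,
                            rigid_template_len = 2500L,
                            warp_template_len = 5500L, kernel_radius = 32L,
                            max_shift = NULL, ecc = ecc_config(), seed = 1L,
                            skip_rigid = FALSE, skip_warp = FALSE,
                            mmd_window = 50L) {
  stopifnot(M >= 1L, block_size >= 1L, rigid_template_len >= 1L,
            warp_template_len >= 1L, kernel_radius >= 1L)
  structure(list(M = as.integer(M), block_size = as.integer(block_size),
                 rigid_template_len = as.integer(rigid_template_len),
                 warp_template_len = as.integer(warp_template_len),
                 kernel_radius = as.integer(kernel_radius),
                 max_shift = max_shift, ecc = ecc, seed = as.integer(seed),
                 skip_rigid = isTRUE(skip_rigid), skip_warp = isTRUE(skip_warp),
                 mmd_window = as.integer(mmd_window)),
            class = "pipeline_config")
}

pipeline_log <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(line, con)
  message(line)
}

#' Run the full within-session pipeline
#'
#' Reads (or accepts) a movie, applies rigid motion correction and warp
#' correction, and writes all artifacts into `outdir`: the corrected
#' stacks (TIFF), the per-frame shift table (CSV), the warp field (JSON),
#' metric reports comparing raw/rigid and rigid/warped (JSON), the resolved
#' configuration (YAML), and a log.
#'
#' @param input a [frame_stack()] or character vector of TIFF paths.
#' @param outdir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @return `outdir`, invisibly. The corrected stacks are also returned as
#'   the attribute `"stacks"` for programmatic use.
#' @export
run_within_session <- function(input, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "patchmoco.log"), open = "wt")
  on.exit(close(logcon))
  yaml::write_yaml(unclass_deep(config), file.path(outdir, "config.yaml"))
  set.seed(config$seed)

  stack <- if (inherits(input, "frame_stack")) input else read_stack(sort(input))
  d <- dim(stack$frames)
  pipeline_log(logcon, "input: %d frames of %d x %d px (origin=%s)",
               d[3], d[1], d[2], stack$origin)
  kernel <- disk_kernel(config$kernel_radius)
  stacks <- list(raw = stack)

  if (!config$skip_rigid) {
    sched <- build_schedule(d[3], config$rigid_template_len)
    rg <- rigid_correct_session(stack, sched,
                                rigid_config(max_shift = config$max_shift))
    write_shift_table(rg$estimates, file.path(outdir, "shifts.csv"))
    write_stack(rg$stack, file.path(outdir, "rigid.tif"))
    rep1 <- compare_conditions(stack, rg$stack, window = config$mmd_window)
    write_metric_report(rep1, file.path(outdir, "metrics_raw_vs_rigid.json"))
    pipeline_log(logcon, "rigid: mMD=%.4g self-mCM %.4f -> %.4f",
                 rep1$mmd, rep1$self_mcm_pre, rep1$self_mcm_post)
    rigid_stack <- rg$stack
  } else {
    pipeline_log(logcon, "rigid correction skipped")
    rigid_stack <- stack
  }

  if (!config$skip_warp) {
    tpl <- build_warp_template(rigid_stack, config$warp_template_len, kernel)
    grid <- make_patch_grid(d[1], d[2], config$M)
    wf <- estimate_block_warps(rigid_stack, tpl, grid,
                               block_size = config$block_size,
                               config = config$ecc, kernel = kernel)
    write_warpfield(wf, file.path(outdir, "warpfield.json"))
    nfail <- sum(!wf$converged)
    if (nfail > 0) {
      pipeline_log(logcon, "warp: %d/%d patch fits kept identity (non-converged)",
                   nfail, length(wf$converged))
    }
    warped <- warp_correct_session(rigid_stack, wf)
    write_stack(warped, file.path(outdir, "warped.tif"))
    rep2 <- compare_conditions(rigid_stack, warped, window = config$mmd_window)
    write_metric_report(rep2, file.path(outdir, "metrics_rigid_vs_warped.json"))
    pipeline_log(logcon, "warp: mMD=%.4g self-mCM %.4f -> %.4f",
                 rep2$mmd, rep2$self_mcm_pre, rep2$self_mcm_post)
    stacks$warped <- warped
  }
  stacks$rigid <- rigid_stack
  pipeline_log(logcon, "done")
  out <- outdir
  attr(out, "stacks") <- stacks
  invisible(out)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Run across-session registration and write the transform
#'
#' @param ref,moving lists with `mean` and `max` summary images (objects or
#'   TIFF paths).
#' @param outdir output directory.
#' @param config a [pipeline_config()] (uses `M`, `kernel_radius`, `ecc`).
#' @return the `session_transform`, invisibly; writes `session_transform.json`,
#'   a selection report CSV, and a before/after overlay QC figure.
#' @export
run_across_session <- function(ref, moving, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  load_summary <- function(x, statistic) {
    if (is.character(x)) summary_image(tiff::readTIFF(x, as.is = TRUE) * 1, statistic)
    else x
  }
  ref <- list(mean = load_summary(ref$mean, "mean"), max = load_summary(ref$max, "max"))
  moving <- list(mean = load_summary(moving$mean, "mean"), max = load_summary(moving$max, "max"))
  st <- register_sessions(ref, moving, M = config$M, config = config$ecc,
                          kernel = disk_kernel(config$kernel_radius))
  write_session_transform(st, file.path(outdir, "session_transform.json"))
  write.csv(st$selection, file.path(outdir, "selection.csv"), row.names = FALSE)

  moved <- apply_session_transform(as_pixel_matrix(moving$mean), st)
  grDevices::pdf(file.path(outdir, "overlay_qc.pdf"), width = 8, height = 4)
  graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  overlay <- function(a, b, main) {
    rgb_img <- array(0, dim = c(dim(a), 3))
    rgb_img[, , 1] <- (a - min(a)) / diff(range(a) + c(0, 1e-12))
    rgb_img[, , 2] <- (b - min(b)) / diff(range(b) + c(0, 1e-12))
    graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE, xlab = "", ylab = "",
                   main = main)
    graphics::rasterImage(rgb_img, 0, 0, 1, 1)
  }
  overlay(as_pixel_matrix(ref$mean), as_pixel_matrix(moving$mean), "before")
  overlay(as_pixel_matrix(ref$mean), moved, "after")
  grDevices::dev.off()
  invisible(st)
}

#' Generate and write a synthetic session
#'
#' @param outdir output directory for `movie.tif` and `ground_truth.json`.
#' @param preset `"soma"` (M = 8 downstream) or `"axon"` (M = 12-15).
#' @param T_,H,W movie dimensions.
#' @param seed RNG seed.
#' @param jitter_sigma_px,distortion,noise forwarded to [generate_movie()].
#' @return the list from [generate_movie()], invisibly.
#' @export
run_synth <- function(outdir, preset = c("soma", "axon"), T_ = 2000L,
                      H = 256L, W = 256L, seed = 1L, jitter_sigma_px = 1,
                      distortion = distortion_spec(), noise = noise_spec()) {
  preset <- match.arg(preset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_cells <- if (preset == "soma") max(10L, round(H * W / 1100)) else
    max(8L, round(min(H, W) / 18))
  sim <- generate_movie(T_, H, W, n_cells = n_cells,
                        jitter_sigma_px = jitter_sigma_px,
                        distortion = distortion, noise = noise,
                        seed = seed, mode = preset)
  write_stack(sim$stack, file.path(outdir, "movie.tif"))
  write_ground_truth(sim$gt, file.path(outdir, "ground_truth.json"))
  invisible(sim)
}
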