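#' Max projection of temporally downsampled frames
#'
#' Frames are first averaged in non-overlapping windows (default 50 frames)
#' to suppress the contribution of pixel noise to the maximum, then the
#' per-pixel max over the averaged frames is taken. Motion smears
#' structures across more pixels, so this projection is brighter on
#' poorly registered data.
#'
#' @param stack a [frame_stack()].
#' @param window averaging window in frames (default 50).
#' @return `H x W` matrix.
#' @export
max_projection_downsampled <- function(stack, window = 50L) {
  ds <- downsample_mean(stack, window)
  max_project(ds$frames)
}

#' Mean max-intensity difference (mMD) between two registration conditions
#'
#' `mMD = mean(maxproj(post)) - mean(maxproj(pre))` where `maxproj` is
#' [max_projection_downsampled()] and the mean runs over all pixels.
#' Negative values indicate reduced motion artifacts in `post` relative to
#' `pre`: registration concentrates each structure onto fewer pixels of the
#' max projection. The metric is antisymmetric in its arguments.
#'
#' @param pre,post [frame_stack()]s of identical shape.
#' @param window averaging window passed on (default 50).
#' @return scalar mMD in intensity units.
#' @export
mmd <- function(pre, post, window = 50L) {
  if (!all(dim(pre$frames) == dim(post$frames))) {
    stop("stacks must have identical shape", call. = FALSE)
  }
  mean(max_projection_downsampled(post, window)) -
    mean(max_projection_downsampled(pre, window))
}

#' Mean correlation with a mean image (mCM)
#'
#' Mean over frames of the Pearson correlation between each frame and a
#' reference mean image. With the stack's own mean this is "self-mCM";
#' with the mean of the other compared condition, "cross-mCM". Successful
#' registration increases both, since motion artifacts reduce the
#' similarity between individual frames and any mean image. All frames are
#' used; a `stride > 1` subsamples frames for speed.
#'
#' @param stack a [frame_stack()].
#' @param reference_mean `H x W` matrix (default: the stack's own mean).
#' @param stride frame subsampling step (default 1 = every frame).
#' @return scalar mCM in `[-1, 1]`, with attribute `n_skipped` counting
#'   zero-variance frames excluded from the mean.
#' @export
mcm <- function(stack, reference_mean = NULL, stride = 1L) {
  if (is.null(reference_mean)) reference_mean <- rowMeans(stack$frames, dims = 2L)
  if (!all(dim(reference_mean) == dim(stack$frames)[1:2])) {
    stop("reference_mean shape mismatch", call. = FALSE)
  }
  idx <- seq.int(1L, n_frames(stack), by = as.integer(stride))
  ref <- as.numeric(reference_mean)
  vals <- numeric(0)
  skipped <- 0L
  for (t in idx) {
    v <- pearson(stack$frames[, , t], ref)
    if (isTRUE(attr(v, "degenerate"))) skipped <- skipped + 1L
    else vals <- c(vals, as.numeric(v))
  }
  structure(mean(vals), n_skipped = skipped)
}

#' Registration-quality report comparing two conditions
#'
#' Computes mMD plus self- and cross-mCM for a pre/post pair of stacks
#' (e.g. raw vs rigid-corrected, or rigid vs warp-corrected).
#' `cross_mcm_pre` correlates pre frames with the post mean;
#' `cross_mcm_post` correlates post frames with the pre mean.
#'
#' @param pre,post [frame_stack()]s of identical shape.
#' @param window mMD averaging window (default 50).
#' @param stride mCM frame stride (default 1).
#' @return object of class `metric_report` (a named list).
#' @export
compare_conditions <- function(pre, post, window = 50L, stride = 1L) {
  pre_mean <- rowMeans(pre$frames, dims = 2L)
  post_mean <- rowMeans(post$frames, dims = 2L)
  structure(list(
    mmd = mmd(pre, post, window),
    self_mcm_pre = as.numeric(mcm(pre, pre_mean, stride)),
    self_mcm_post = as.numeric(mcm(post, post_mean, stride)),
    cross_mcm_pre = as.numeric(mcm(pre, post_mean, stride)),
    cross_mcm_post = as.numeric(mcm(post, pre_mean, stride)),
    n_frames_used = length(seq.int(1L, n_frames(pre), by = as.integer(stride))),
    downsample_window = as.integer(window)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> mMD=%.4g  self-mCM %.4f -> %.4f  ",
                     "cross-mCM %.4f -> %.4f  (n=%d, window=%d)\n"),
              x$mmd, x$self_mcm_pre, x$self_mcm_post,
              x$cross_mcm_pre, x$cross_mcm_post,
              x$n_frames_used, x$downsample_window))
  invisible(x)
}

#' Write a metric report to JSON
#' @param report a `metric_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' One-page QC figure for a pre/post comparison
#'
#' Draws the downsampled max projections of both conditions and a bar chart
#' of the mCM values into a PDF.
#'
#' @param pre,post [frame_stack()]s.
#' @param report a `metric_report` from [compare_conditions()].
#' @param path output PDF path.
#' @param labels length-2 condition labels.
#' @return `path`, invisibly.
#' @export
qc_figure <- function(pre, post, report, path, labels = c("pre", "post")) {
  grDevices::pdf(path, width = 9, height = 3.2)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
  show <- function(img, main) {
    graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  show(max_projection_downsampled(pre, report$downsample_window), labels[1])
  show(max_projection_downsampled(post, report$downsample_window), labels[2])
  vals <- c(report$self_mcm_pre, report$self_mcm_post,
            report$cross_mcm_pre, report$cross_mcm_post)
  graphics::barplot(vals, names.arg = c("self pre", "self post", "cross pre", "cross post"),
                    main = sprintf("mCM (mMD = %.3g)", report$mmd), las = 2)
  invisible(path)
}
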