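#' Overlapping patch decomposition of a field of view
#'
#' The FOV is tiled by `M x M` nominal tiles of `ceiling(H/M) x
#' ceiling(W/M)` pixels; every interior tile edge is then extended by
#' `round(0.3 * H / M)` rows (respectively `round(0.3 * W / M)` columns,
#' rounding half away from zero), so adjacent patches share that many
#' pixels, which are averaged at stitching time. Patches are clipped at the
#' image border. `M = 8` suits cellular-resolution imaging; 12-15 suits
#' axon imaging, where motion is more local.
#'
#' @param H,W field-of-view size in pixels.
#' @param M patches per side (`1 <= M <= min(H, W) / 8`).
#' @return object of class `patch_grid`: `M`, `H`, `W`, `overlap_y`,
#'   `overlap_x`, `bounds` (an `M^2 x 4` matrix of 0-based half-open
#'   `y0, y1, x0, x1` ranges in row-major patch order), and `core_bounds`
#'   (the nominal tiles without overlap).
#' @export
make_patch_grid <- function(H, W, M) {
  H <- as.integer(H); W <- as.integer(W); M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  if (M > min(H, W) / 8) stop("M too large for this field of view", call. = FALSE)
  sy <- ceiling(H / M); sx <- ceiling(W / M)
  ovy <- if (M == 1L) 0L else as.integer(round_half_up(0.3 * H / M))
  ovx <- if (M == 1L) 0L else as.integer(round_half_up(0.3 * W / M))
  bounds <- matrix(0L, M * M, 4L,
                   dimnames = list(NULL, c("y0", "y1", "x0", "x1")))
  core <- bounds
  k <- 0L
  for (i in seq_len(M)) {        # row of patches (y)
    for (j in seq_len(M)) {      # column of patches (x)
      k <- k + 1L
      y0 <- (i - 1L) * sy; y1 <- min(i * sy, H)
      x0 <- (j - 1L) * sx; x1 <- min(j * sx, W)
      core[k, ] <- c(y0, y1, x0, x1)
      if (i > 1L) y0 <- max(0L, y0 - ovy)
      if (i < M)  y1 <- min(H, y1 + ovy)
      if (j > 1L) x0 <- max(0L, x0 - ovx)
      if (j < M)  x1 <- min(W, x1 + ovx)
      bounds[k, ] <- c(y0, y1, x0, x1)
    }
  }
  structure(list(M = M, H = H, W = W, overlap_y = ovy, overlap_x = ovx,
                 bounds = bounds, core_bounds = core),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d patches on %d x %d px, overlaps %d (y) / %d (x) px\n",
              x$M, x$M, x$H, x$W, x$overlap_y, x$overlap_x))
  invisible(x)
}

#' Fixed warp-correction template for a session
#'
#' Mean of the middle `template_len` frames (clipped to the session length),
#' locally intensity-normalized. One fixed template maps every block of the
#' session onto a single reference geometry; rigid correction should have
#' been applied first so the mean is sharp.
#'
#' @param rigid_stack a [frame_stack()], normally with `origin = "rigid"`
#'   (a warning is issued for `origin = "raw"`).
#' @param template_len frames averaged (default 5500).
#' @param kernel [disk_kernel()] for the normalization.
#' @return the normalized `H x W` template matrix.
#' @export
build_warp_template <- function(rigid_stack, template_len = 5500L,
                                kernel = disk_kernel()) {
  if (rigid_stack$origin == "raw") {
    warning("building a warp template from uncorrected raw frames; run rigid correction first")
  }
  T_ <- n_frames(rigid_stack)
  L <- min(as.integer(template_len), T_)
  start0 <- (T_ - L) %/% 2L
  tpl <- mean_frames(rigid_stack, start0 + 1L, start0 + L)
  local_normalize(tpl, kernel)
}

#' Estimate per-block, per-patch affine warps
#'
#' All frames are temporally downsampled by non-overlapping `block_size`
#' means (slow distortions are negligible within ~500 frames at ~29 Hz);
#' each block mean is locally normalized and, patch by patch, an affine
#' transform maximizing the ECC against the fixed normalized template is
#' estimated from identity (blocks are mutually independent: no chaining,
#' so errors cannot accumulate). Patches whose optimization fails keep the
#' identity transform, with diagnostics recorded.
#'
#' Patch transforms are expressed in patch-local coordinates (origin at the
#' patch's upper-left corner), which keeps the translation parameters
#' well-scaled for the gradient step.
#'
#' @param rigid_stack a [frame_stack()] (rigid-corrected).
#' @param template normalized template from [build_warp_template()].
#' @param grid a [make_patch_grid()] matching the FOV.
#' @param block_size frames per block (default 500).
#' @param config an [ecc_config()].
#' @param kernel [disk_kernel()] used to normalize block means.
#' @return object of class `warp_field`: `grid`, `block_ranges`,
#'   `transforms` (list over blocks of lists of M^2 3x3 matrices),
#'   `rho`, `converged`, `iterations` (patch x block matrices).
#' @export
estimate_block_warps <- function(rigid_stack, template, grid,
                                 block_size = 500L, config = ecc_config(),
                                 kernel = disk_kernel()) {
  stopifnot(all(dim(template) == c(grid$H, grid$W)))
  ds <- downsample_mean(rigid_stack, block_size)
  ranges <- attr(ds, "block_ranges")
  nb <- n_frames(ds)
  np <- nrow(grid$bounds)
  transforms <- vector("list", nb)
  rho <- matrix(NA_real_, np, nb)
  conv <- matrix(FALSE, np, nb)
  iters <- matrix(0L, np, nb)
  for (b in seq_len(nb)) {
    blk <- local_normalize(ds$frames[, , b], kernel)
    tb <- vector("list", np)
    for (k in seq_len(np)) {
      yy <- (grid$bounds[k, 1] + 1L):grid$bounds[k, 2]
      xx <- (grid$bounds[k, 3] + 1L):grid$bounds[k, 4]
      res <- ecc_maximize(template[yy, xx], blk[yy, xx], model = "affine",
                          config = config)
      rho[k, b] <- res$rho
      conv[k, b] <- res$converged
      iters[k, b] <- res$iterations
      tb[[k]] <- if (res$converged) as.matrix(res$transform) else diag(3)
    }
    transforms[[b]] <- tb
  }
  structure(list(grid = grid, block_size = as.integer(block_size),
                 block_ranges = ranges, transforms = transforms,
                 rho = rho, converged = conv, iterations = iters),
            class = "warp_field")
}

#' @export
print.warp_field <- function(x, ...) {
  cat(sprintf("<warp_field> %d patches x %d blocks (block_size %d); %.1f%% converged\n",
              nrow(x$rho), ncol(x$rho), x$block_size, 100 * mean(x$converged)))
  invisible(x)
}

# M^2 x 6 parameter matrix for the C++ stitcher
patch_params_matrix <- function(transforms) {
  do.call(rbind, lapply(transforms, function(m) {
    m <- if (is.matrix(m)) m else as.matrix(m)
    c(m[1, ], m[2, ])
  }))
}

#' Warp one frame through per-patch affine transforms and stitch
#'
#' Each patch of the output is resampled from the full input frame through
#' its own patch-local affine (inverse mapping, bilinear); where patches
#' overlap, contributing values are averaged with equal weights. Pixels
#' with no valid contributor keep the value of `fill_frame` (by default the
#' input frame itself).
#'
#' @param frame numeric matrix of the grid's FOV size.
#' @param patch_transforms list of M^2 3x3 matrices (or `transform2d`
#'   objects) in the grid's row-major patch order.
#' @param grid a [make_patch_grid()].
#' @param fill_frame fallback image for uncovered pixels.
#' @return warped and stitched matrix.
#' @export
warp_frame <- function(frame, patch_transforms, grid, fill_frame = frame) {
  stopifnot(all(dim(frame) == c(grid$H, grid$W)))
  trans <- patch_params_matrix(patch_transforms)
  cpp_warp_patches(frame, grid$bounds, trans, fill_frame)
}

#' Apply an estimated warp field to every frame of a session
#'
#' Every frame in a block is warped with that block's patch transforms (a
#' trailing short block merged by the downsampling remainder rule reuses
#' the transforms of the block it was merged into, since they were
#' estimated from its frames too). Frame count and order are preserved.
#'
#' @param rigid_stack a [frame_stack()] (rigid-corrected).
#' @param warpfield a `warp_field` from [estimate_block_warps()].
#' @return a [frame_stack()] with `origin = "warped"`.
#' @export
warp_correct_session <- function(rigid_stack, warpfield) {
  grid <- warpfield$grid
  d <- dim(rigid_stack$frames)
  stopifnot(d[1] == grid$H, d[2] == grid$W)
  ranges <- warpfield$block_ranges
  if (max(ranges) < n_frames(rigid_stack)) {
    stop("warp field does not cover all frames", call. = FALSE)
  }
  out <- array(0, dim = d)
  for (b in seq_len(nrow(ranges))) {
    trans <- patch_params_matrix(warpfield$transforms[[b]])
    for (t in ranges[b, 1]:ranges[b, 2]) {
      fr <- rigid_stack$frames[, , t]
      out[, , t] <- cpp_warp_patches(fr, grid$bounds, trans, fr)
    }
  }
  frame_stack(out, frame_rate_hz = rigid_stack$frame_rate_hz, origin = "warped")
}

#' Serialize a warp field to JSON
#'
#' Stores the grid (M, overlaps, bounds), block ranges, all patch
#' transforms (row-major 3x3) and per-patch diagnostics.
#'
#' @param warpfield a `warp_field`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_warpfield <- function(warpfield, path) {
  obj <- list(
    grid = list(M = warpfield$grid$M, H = warpfield$grid$H, W = warpfield$grid$W,
                overlap_y = warpfield$grid$overlap_y,
                overlap_x = warpfield$grid$overlap_x,
                bounds = warpfield$grid$bounds,
                core_bounds = warpfield$grid$core_bounds),
    block_size = warpfield$block_size,
    block_ranges = warpfield$block_ranges,
    transforms = lapply(warpfield$transforms,
                        function(tb) lapply(tb, function(m) as.vector(t(m)))),
    rho = warpfield$rho, converged = warpfield$converged,
    iterations = warpfield$iterations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a warp field written by [write_warpfield()]
#' @param path JSON path.
#' @return a `warp_field` object.
#' @export
read_warpfield <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- obj$grid
  row_major_int <- function(x, nc) {
    matrix(as.integer(unlist(x)), ncol = nc, byrow = TRUE)
  }
  grid <- structure(list(M = as.integer(g$M), H = as.integer(g$H),
                         W = as.integer(g$W),
                         overlap_y = as.integer(g$overlap_y),
                         overlap_x = as.integer(g$overlap_x),
                         bounds = `dimnames<-`(row_major_int(g$bounds, 4L),
                                               list(NULL, c("y0", "y1", "x0", "x1"))),
                         core_bounds = row_major_int(g$core_bounds, 4L)),
                    class = "patch_grid")
  transforms <- lapply(obj$transforms, function(tb) {
    lapply(tb, function(v) matrix(as.numeric(unlist(v)), 3L, 3L, byrow = TRUE))
  })
  rowmat <- function(x, cast) {
    do.call(rbind, lapply(x, function(r) cast(unlist(r))))
  }
  structure(list(grid = grid, block_size = as.integer(obj$block_size),
                 block_ranges = `dimnames<-`(row_major_int(obj$block_ranges, 2L),
                                             list(NULL, c("from", "to"))),
                 transforms = transforms,
                 rho = rowmat(obj$rho, as.numeric),
                 converged = rowmat(obj$converged, as.logical),
                 iterations = rowmat(obj$iterations, as.integer)),
            class = "warp_field")
}
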