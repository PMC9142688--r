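#' Construct a movie frame stack
#'
#' A `frame_stack` holds an ordered single-channel movie as an `H x W x T`
#' numeric array (fluorescence in arbitrary units), the nominal frame rate,
#' and a provenance tag recording which pipeline stage produced it.
#'
#' @param frames numeric array of dimension `H x W x T` (a single matrix is
#'   promoted to `T = 1`), all values finite, `H, W >= 8`.
#' @param frame_rate_hz positive scalar frame rate (metadata only), default 29.
#' @param origin provenance tag, one of `"raw"`, `"rigid"`, `"warped"`,
#'   `"synthetic"`.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz = 29, origin = "raw") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be an H x W x T array", call. = FALSE)
  }
  d <- dim(frames)
  if (d[1] < 8L || d[2] < 8L) stop("frames must be at least 8 x 8 pixels", call. = FALSE)
  if (d[3] < 1L) stop("at least one frame required", call. = FALSE)
  if (!all(is.finite(frames))) stop("frame intensities must be finite", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a positive scalar", call. = FALSE)
  }
  origin <- match.arg(origin, c("raw", "rigid", "warped", "synthetic"))
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz, origin = origin),
            class = "frame_stack")
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count `T`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames, %.3g Hz, origin=%s\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$origin))
  invisible(x)
}

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param t 1-based frame index.
#' @return `H x W` numeric matrix.
#' @export
get_frame <- function(stack, t) stack$frames[, , t]

#' Construct a session summary image
#'
#' @param pixels `H x W` numeric matrix with finite values.
#' @param statistic `"mean"` or `"max"` (which projection produced it).
#' @param session_id free-form session label.
#' @return an object of class `summary_image`.
#' @export
summary_image <- function(pixels, statistic = c("mean", "max"), session_id = "") {
  statistic <- match.arg(statistic)
  stopifnot_finite_matrix(pixels, "summary image")
  structure(list(pixels = pixels, statistic = statistic, session_id = session_id),
            class = "summary_image")
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "summary_image")) x$pixels else x
}

#' Read a movie from one or more multi-page grayscale TIFF files
#'
#' Frames are concatenated in path order, then page order within each file
#' (acquisition software commonly splits one session into numbered files;
#' pass paths in the intended order, or rely on lexical sorting via
#' [sort()] before calling). Integer TIFFs are read losslessly
#' (`as.is`); see [write_stack()] for the signed-int16 convention.
#'
#' @param paths character vector of TIFF file paths, in session order.
#' @param frame_rate_hz frame-rate metadata to attach, default 29.
#' @param signed if `TRUE`, undo the +32768 bias used by
#'   `write_stack(dtype_policy = "int16")` to recover signed values.
#' @return a [frame_stack()] with `origin = "raw"`.
#' @export
read_stack <- function(paths, frame_rate_hz = 29, signed = FALSE) {
  if (length(paths) < 1L) stop("at least one path required", call. = FALSE)
  pages <- list()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    pg <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    for (i in seq_along(pg)) {
      m <- pg[[i]]
      if (length(dim(m)) == 3L) {
        stop(sprintf("non-grayscale page in %s (multi-channel TIFF)", p), call. = FALSE)
      }
      pages[[length(pages) + 1L]] <- m
    }
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop(sprintf("mixed frame shapes across pages of %s",
                 paste(paths, collapse = ", ")), call. = FALSE)
  }
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  if (signed) arr <- arr - 32768
  frame_stack(arr, frame_rate_hz = frame_rate_hz, origin = "raw")
}

#' Write a movie stack to a multi-page TIFF
#'
#' The available TIFF sample formats are unsigned 8/16/32-bit integers, so
#' the writer offers three policies. `"uint16"` rounds half away from zero
#' and clips to `[0, 65535]`: lossless for unsigned 16-bit data. `"int16"`
#' stores `value + 32768` as uint16 (lossless for signed 16-bit data when
#' read back with `read_stack(signed = TRUE)`). `"float32"` linearly maps
#' `range` onto 32-bit samples (near-lossless for floats; quantization step
#' `diff(range)/(2^32 - 1)`).
#'
#' @param stack a [frame_stack()].
#' @param path output file path (parent directory must exist).
#' @param dtype_policy `"uint16"`, `"int16"` or `"float32"`.
#' @param range numeric length-2, the value range mapped for `"float32"`;
#'   defaults to the stack's own range.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype_policy = c("uint16", "int16", "float32"),
                        range = NULL) {
  dtype_policy <- match.arg(dtype_policy)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory not writable or missing: %s", dirname(path)), call. = FALSE)
  }
  fr <- stack$frames
  T_ <- dim(fr)[3]
  if (dtype_policy == "uint16" || dtype_policy == "int16") {
    off <- if (dtype_policy == "int16") 32768 else 0
    pages <- lapply(seq_len(T_), function(t) {
      v <- round_half_up(fr[, , t]) + off
      v <- pmin(pmax(v, 0), 65535)
      v / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  } else {
    if (is.null(range)) range <- base::range(fr)
    if (diff(range) <= 0) range <- range + c(0, 1)
    pages <- lapply(seq_len(T_), function(t) {
      pmin(pmax((fr[, , t] - range[1]) / diff(range), 0), 1)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    attr(path, "range") <- range
  }
  invisible(path)
}

#' Temporal downsampling by non-overlapping block means
#'
#' Frames are grouped into consecutive non-overlapping blocks of `window`
#' frames and averaged; warp estimation operates on these block means so
#' that one transform is fitted per block. A trailing remainder of at least
#' `window / 2` frames forms its own (shorter) final block; a smaller
#' remainder is merged into the previous block, so no transform is ever
#' estimated from too few frames.
#'
#' @param stack a [frame_stack()].
#' @param window block length in frames (>= 1); the warp-correction default
#'   is 500.
#' @return a [frame_stack()] of block means, with attribute
#'   `block_ranges` (matrix, columns `from`/`to`, 1-based inclusive frame
#'   ranges of each block).
#' @export
downsample_mean <- function(stack, window) {
  T_ <- n_frames(stack)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > T_) {
    warning("window exceeds frame count; returning the global mean frame")
    window <- T_
  }
  nb <- T_ %/% window
  rem <- T_ %% window
  bounds <- cbind(from = (seq_len(nb) - 1L) * window + 1L,
                  to   = seq_len(nb) * window)
  if (rem > 0L) {
    if (rem >= window / 2) {
      bounds <- rbind(bounds, c(nb * window + 1L, T_))
    } else {
      bounds[nb, 2L] <- T_
    }
  }
  d <- dim(stack$frames)
  out <- array(0, dim = c(d[1], d[2], nrow(bounds)))
  for (b in seq_len(nrow(bounds))) {
    idx <- bounds[b, 1L]:bounds[b, 2L]
    out[, , b] <- rowMeans(stack$frames[, , idx, drop = FALSE], dims = 2L)
  }
  ds <- frame_stack(out, frame_rate_hz = stack$frame_rate_hz / window,
                    origin = stack$origin)
  attr(ds, "block_ranges") <- bounds
  ds
}

#' Mean and max projection summary images of a stack
#'
#' @param stack a [frame_stack()].
#' @param session_id label stored on both summaries.
#' @return list with elements `mean` and `max`, each a [summary_image()].
#' @export
summary_images <- function(stack, session_id = "") {
  fr <- stack$frames
  mn <- rowMeans(fr, dims = 2L)
  mx <- max_project(fr)
  list(mean = summary_image(mn, "mean", session_id),
       max  = summary_image(mx, "max", session_id))
}

# per-pixel max over the 3rd dimension of an H x W x T array
max_project <- function(fr) {
  out <- fr[, , 1]
  T_ <- dim(fr)[3]
  if (T_ > 1L) for (t in 2:T_) out <- pmax(out, fr[, , t])
  out
}

# mean image over a 1-based inclusive frame range
mean_frames <- function(stack, from, to) {
  rowMeans(stack$frames[, , from:to, drop = FALSE], dims = 2L)
}
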