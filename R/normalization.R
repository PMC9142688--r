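#' Binary disk convolution kernel
#'
#' Inscribed-disk membership: offset `(dy, dx)` belongs to the kernel iff
#' `dy^2 + dx^2 <= radius^2`. The default 32-pixel radius sets the spatial
#' scale of the local intensity normalization: large enough to span a soma
#' plus its surround, small enough to track slow vignetting.
#'
#' @param radius_px positive integer radius in pixels (default 32).
#' @return object of class `disk_kernel` with fields `radius_px` and `mask`
#'   (a `(2r+1) x (2r+1)` 0/1 matrix).
#' @export
disk_kernel <- function(radius_px = 32L) {
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be a positive integer", call. = FALSE)
  off <- -radius_px:radius_px
  d2 <- outer(off^2, off^2, "+")
  mask <- matrix(as.numeric(d2 <= radius_px^2), nrow = length(off))
  structure(list(radius_px = radius_px, mask = mask), class = "disk_kernel")
}

#' Zero-padded disk blur
#'
#' Unnormalized 2-D convolution of an image with the binary disk (the sum of
#' intensities over the disk support at each pixel), computed with implicit
#' zero padding outside the image. Use [padding_compensation()] to convert
#' the sum into an edge-corrected local mean.
#'
#' @param image finite numeric matrix.
#' @param kernel a [disk_kernel()]; its diameter must fit inside the image.
#' @return blurred matrix of the same size.
#' @export
blur_disk <- function(image, kernel = disk_kernel()) {
  stopifnot_finite_matrix(image)
  if (2L * kernel$radius_px + 1L > min(dim(image))) {
    stop("disk kernel larger than image", call. = FALSE)
  }
  conv2_same(image, kernel$mask)
}

#' Edge compensation for the zero-padded disk blur
#'
#' Divides the blurred image by the disk convolved with an all-ones image of
#' the same size, i.e. by the number of in-bounds pixels under the disk at
#' each location. Interior pixels are divided by the full disk area, edge
#' pixels by their (smaller) in-bounds count, so a constant image maps to
#' the same constant everywhere including the corners.
#'
#' @param blurred output of [blur_disk()] on an image of this shape.
#' @param kernel the same [disk_kernel()] used for the blur.
#' @return compensated local-mean matrix.
#' @export
padding_compensation <- function(blurred, kernel = disk_kernel()) {
  ones <- matrix(1, nrow(blurred), ncol(blurred))
  blurred / conv2_same(ones, kernel$mask)
}

#' Local intensity normalization
#'
#' Divides each pixel by the edge-compensated mean intensity of its disk
#' neighborhood and rescales by the global mean:
#' `f'(x, y) = mean(f) * f(x, y) / g'(x, y)` where `g'` is the compensated
#' disk blur of `f`. This suppresses the frame-to-frame calcium-signal
#' dynamics (a cell brightening also brightens its own neighborhood mean)
#' and enhances the contrast between dim structures and their surround, so
#' that the downstream ECC steps match geometry rather than activity. The
#' result is homogeneous of degree one in the input: a global gain `a`
#' rescales the output by `a` exactly.
#'
#' Pixels whose neighborhood mean falls below `1e-12 * mean(f)` are set to 0
#' and reported in a warning (all-dark borders, e.g. vignetted GRIN-lens
#' fields, would otherwise divide by ~0).
#'
#' @param image finite numeric matrix.
#' @param kernel a [disk_kernel()].
#' @return normalized matrix of the same size.
#' @export
local_normalize <- function(image, kernel = disk_kernel()) {
  g <- padding_compensation(blur_disk(image, kernel), kernel)
  gm <- mean(image)
  eps <- 1e-12 * abs(gm)
  bad <- !is.finite(g) | abs(g) <= eps
  out <- image
  out[!bad] <- gm * image[!bad] / g[!bad]
  if (any(bad)) {
    out[bad] <- 0
    warning(sprintf("local_normalize: %d pixel(s) with near-zero neighborhood mean set to 0",
                    sum(bad)))
  }
  out
}

#' Rank transform of an image
#'
#' Replaces every pixel by its rank among all `H * W` pixels (ties get the
#' average rank). The output is invariant to any strictly increasing
#' remapping of intensities, which makes the rigid correlation step immune
#' to brightness and contrast changes between a frame and its template.
#'
#' @param image finite numeric matrix.
#' @return matrix of ranks in `1..(H*W)` (average ranks at ties).
#' @export
rank_transform <- function(image) {
  stopifnot_finite_matrix(image)
  matrix(rank(image, ties.method = "average"), nrow(image), ncol(image))
}
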