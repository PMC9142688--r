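# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Pearson correlation of two equal-length numeric vectors; returns 0 with a
# "degenerate" attribute when either has zero variance.
pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(a, b)
}

# 2x2 block average (one pyramid level down); odd trailing row/col dropped
downscale2 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  h2 <- H %/% 2L; w2 <- W %/% 2L
  img <- img[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  (img[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L)] +
    img[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L)] +
    img[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L)] +
    img[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L)]) / 4
}

# separable Gaussian smoothing with replicated edges; radius 3*sigma
gaussian_smooth <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  # rows (vertical pass)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    off <- i - r - 1L
    idx <- pmin(pmax(seq_len(H) + off, 1L), H)
    out <- out + k[i] * img[idx, , drop = FALSE]
  }
  img <- out
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    off <- i - r - 1L
    idx <- pmin(pmax(seq_len(W) + off, 1L), W)
    out <- out + k[i] * img[, idx, drop = FALSE]
  }
  out
}

# central-difference spatial gradients (one-sided at borders), returns
# list(gx, gy) in pixels^-1 with x = columns, y = rows
image_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  cl <- pmax(seq_len(W) - 1L, 1L); cr <- pmin(seq_len(W) + 1L, W)
  ru <- pmax(seq_len(H) - 1L, 1L); rd <- pmin(seq_len(H) + 1L, H)
  den_x <- matrix(rep(cr - cl, each = H), H, W)
  den_y <- matrix(rep(rd - ru, times = W), H, W)
  gx <- (img[, cr, drop = FALSE] - img[, cl, drop = FALSE]) / den_x
  gy <- (img[rd, , drop = FALSE] - img[ru, , drop = FALSE]) / den_y
  list(gx = gx, gy = gy)
}

# zero-padded 2-D convolution via FFT ("same" output size)
conv2_same <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- H + kh - 1L; pw <- W + kw - 1L
  A <- matrix(0, ph, pw); A[1:H, 1:W] <- img
  B <- matrix(0, ph, pw); B[1:kh, 1:kw] <- kern
  full <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (ph * pw)
  r0 <- (kh - 1L) %/% 2L; c0 <- (kw - 1L) %/% 2L
  full[(r0 + 1L):(r0 + H), (c0 + 1L):(c0 + W)]
}

#' @importFrom stats fft
NULL

stopifnot_finite_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}
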