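# Test fixtures and independent oracles, all generated in code.

# An analytic blob scene: returns both the sampled matrix and the closure,
# so warped versions can be produced without interpolation error.
blob_scene <- function(H, W, n = 30, seed = 1, bg = 20) {
  set.seed(seed)
  cx <- runif(n, 5, W - 6); cy <- runif(n, 5, H - 6)
  s <- runif(n, 2, 4); a <- runif(n, 50, 150)
  f <- function(x, y) {
    v <- rep(bg, length(x))
    for (i in seq_len(n)) {
      v <- v + a[i] * exp(-((x - cx[i])^2 + (y - cy[i])^2) / (2 * s[i]^2))
    }
    v
  }
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), W), H, W)
  list(f = f, img = matrix(f(as.vector(X), as.vector(Y)), H, W), X = X, Y = Y)
}

# sample a scene closure through a 3x3 transform (output -> source coords)
scene_warped <- function(scene, m, H, W) {
  pts <- cbind(as.vector(scene$X), as.vector(scene$Y)) %*% t(m[1:2, 1:2]) +
    matrix(m[1:2, 3], H * W, 2, byrow = TRUE)
  matrix(scene$f(pts[, 1], pts[, 2]), H, W)
}

# integer shift with edge replication, by pure indexing (no interpolation):
# out(x, y) = img(x + sx, y + sy), clamped at the borders
roll_edge <- function(img, sx, sy) {
  H <- nrow(img); W <- ncol(img)
  rows <- pmin(pmax(seq_len(H) + sy, 1L), H)
  cols <- pmin(pmax(seq_len(W) + sx, 1L), W)
  img[rows, cols]
}

# exhaustive integer-shift search oracle: maximize Pearson correlation of
# template vs displaced frame over all |sx|,|sy| <= max_s, using plain R
# submatrix extraction and stats::cor (independent of the package kernels)
oracle_exhaustive_shift <- function(frame, template, max_s = 10L) {
  H <- nrow(frame); W <- ncol(frame)
  best <- c(0L, 0L); best_c <- -Inf
  for (sy in -max_s:max_s) {
    for (sx in -max_s:max_s) {
      r0 <- max(1L, 1L - sy); r1 <- min(H, H - sy)
      c0 <- max(1L, 1L - sx); c1 <- min(W, W - sx)
      if (r1 < r0 || c1 < c0) next
      if ((r1 - r0 + 1) * (c1 - c0 + 1) < 0.25 * H * W) next
      cc <- cor(as.vector(template[r0:r1, c0:c1]),
                as.vector(frame[(r0 + sy):(r1 + sy), (c0 + sx):(c1 + sx)]))
      if (is.na(cc)) next
      if (cc > best_c + 1e-15 ||
          (abs(cc - best_c) <= 1e-15 &&
             sx^2 + sy^2 < best[1]^2 + best[2]^2)) {
        best <- c(sx, sy); best_c <- cc
      }
    }
  }
  list(s = best, corr = best_c)
}

# dense subpixel search oracle along one axis: correlation of template vs
# bilinearly shifted frame on a delta grid, around an integer optimum
oracle_dense_subpixel <- function(frame, template, s0, axis = c("x", "y"),
                                  step = 0.05, span = 1) {
  axis <- match.arg(axis)
  deltas <- seq(-span, span, by = step)
  cc <- vapply(deltas, function(d) {
    dx <- s0[1] + if (axis == "x") d else 0
    dy <- s0[2] + if (axis == "y") d else 0
    cor(as.vector(template), as.vector(apply_shift(frame, dx, dy, fill = "edge")))
  }, numeric(1))
  s0[if (axis == "x") 1 else 2] + deltas[which.max(cc)]
}

# brute-force local disk mean at one pixel (1-based r, c), zero padding
# compensated: the plain mean over in-bounds disk neighbours
oracle_disk_mean <- function(img, r, c, radius) {
  H <- nrow(img); W <- ncol(img)
  acc <- 0; n <- 0
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      if (dy^2 + dx^2 > radius^2) next
      rr <- r + dy; cc <- c + dx
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
        acc <- acc + img[rr, cc]; n <- n + 1
      }
    }
  }
  acc / n
}

# small movie with constant frames (plus optional per-frame closure)
constant_stack <- function(H = 16, W = 16, T_ = 4, value = 7) {
  frame_stack(array(value, dim = c(H, W, T_)))
}
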