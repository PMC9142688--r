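#' Slow-distortion specification for the synthetic generator
#'
#' Per-patch ground-truth affines whose parameters ramp linearly in time
#' from `ramp[1]` to `ramp[2]` times the per-patch maxima. With the default
#' symmetric ramp `c(-1, 1)` the mid-session distortion is zero, matching
#' the geometry of a mid-session template. Deltas are drawn uniformly in
#' `[-max, max]` per patch.
#'
#' @param M patches per side of the distortion grid.
#' @param max_rot_deg per-patch rotation bound in degrees.
#' @param max_shear per-patch shear bound (dimensionless).
#' @param max_trans_px per-patch translation bound in pixels.
#' @param ramp length-2 temporal ramp endpoints.
#' @param field `"smooth"` (default) interpolates each parameter bilinearly
#'   across the FOV between four random corner values, as slow tissue or
#'   optical distortions are spatially smooth; `"independent"` draws every
#'   patch independently (a stress condition with discontinuous ground
#'   truth at patch seams).
#' @return list of class `distortion_spec`.
#' @export
distortion_spec <- function(M = 4L, max_rot_deg = 2, max_shear = 0.02,
                            max_trans_px = 2, ramp = c(-1, 1),
                            field = c("smooth", "independent")) {
  structure(list(M = as.integer(M), max_rot_deg = max_rot_deg,
                 max_shear = max_shear, max_trans_px = max_trans_px,
                 ramp = as.numeric(ramp), field = match.arg(field)),
            class = "distortion_spec")
}

# draw one per-patch parameter map: smooth = bilinear between four random
# corner values, independent = i.i.d. uniform
draw_param_field <- function(M, maxval, field) {
  if (field == "independent" || M == 1L) {
    return(runif(M * M, -1, 1) * maxval)
  }
  corners <- runif(4, -1, 1) * maxval   # (0,0), (1,0), (0,1), (1,1) in (u,v)
  vals <- matrix(0, M, M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      u <- (j - 0.5) / M; v <- (i - 0.5) / M
      vals[i, j] <- (1 - u) * (1 - v) * corners[1] + u * (1 - v) * corners[2] +
        (1 - u) * v * corners[3] + u * v * corners[4]
    }
  }
  as.vector(t(vals))   # row-major patch order
}

#' Noise specification for the synthetic generator
#'
#' Additive Gaussian read noise plus signal-dependent shot noise with
#' variance `shot_gain * intensity` (a variance-matched Gaussian
#' approximation to Poisson photon noise).
#'
#' @param gaussian_sd read-noise standard deviation (intensity units).
#' @param shot_gain shot-noise variance per intensity unit.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 4, shot_gain = 0.5) {
  structure(list(gaussian_sd = gaussian_sd, shot_gain = shot_gain),
            class = "noise_spec")
}

# reflect a value into [-b, b]
reflect_bound <- function(x, b) {
  y <- (x + b) %% (4 * b)
  ifelse(y > 2 * b, 4 * b - y, y) - b
}

# smooth dim background texture (neuropil-like)
make_background <- function(H, W, level = 20, amp = 10) {
  f <- gaussian_smooth(matrix(runif(H * W), H, W), 4)
  f <- (f - min(f)) / (max(f) - min(f) + 1e-12)
  level + amp * f
}

# one soma: Gaussian blob; returns linear pixel indices and weights
stamp_soma <- function(H, W, cx, cy, sigma) {
  r <- ceiling(3 * sigma)
  xs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
  g <- outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
             exp(-(xs - cx)^2 / (2 * sigma^2)))
  idx <- as.vector(outer(ys + 1L, xs * H, "+"))
  list(idx = idx, w = as.vector(g))
}

# one axon: smoothed 2-D random walk stamped with a Gaussian cross-section
stamp_axon <- function(H, W, x0, y0, dir0, len, sigma = 1.2) {
  img <- matrix(0, H, W)
  x <- x0; y <- y0; d <- dir0
  for (s in seq_len(len)) {
    d <- d + rnorm(1, 0, 0.15)
    x <- x + cos(d); y <- y + sin(d)
    if (x < 2 || x > W - 3 || y < 2 || y > H - 3) break
    xs <- (floor(x) - 2L):(floor(x) + 2L)
    ys <- (floor(y) - 2L):(floor(y) + 2L)
    g <- outer(exp(-(ys - y)^2 / (2 * sigma^2)), exp(-(xs - x)^2 / (2 * sigma^2)))
    img[ys + 1L, xs + 1L] <- pmax(img[ys + 1L, xs + 1L], g)
  }
  idx <- which(img > 1e-3)
  list(idx = idx, w = img[idx])
}

# draw the structures of a scene; returns list(bg, structures)
make_scene <- function(H, W, n_cells, mode = c("soma", "axon")) {
  mode <- match.arg(mode)
  bg <- make_background(H, W)
  structures <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    if (mode == "soma") {
      cx <- runif(1, 8, W - 9); cy <- runif(1, 8, H - 9)
      radius <- runif(1, 3, 6)                 # blob radius in px
      st <- stamp_soma(H, W, cx, cy, radius / 2)
      st$x <- cx; st$y <- cy; st$radius <- radius
    } else {
      st <- stamp_axon(H, W, runif(1, 8, W - 9), runif(1, 8, H - 9),
                       runif(1, 0, 2 * pi), round(0.6 * min(H, W)))
      if (length(st$idx) == 0) st <- stamp_soma(H, W, W / 2, H / 2, 2)
      st$x <- NA; st$y <- NA; st$radius <- NA
    }
    st$base_amp <- runif(1, 30, 70)            # structural (baseline) brightness
    st$trans_amp <- runif(1, 80, 200)          # transient peak amplitude
    st$rate <- runif(1, 0.003, 0.01)           # events per frame
    structures[[i]] <- st
  }
  list(bg = bg, structures = structures)
}

# per-cell transient traces: Poisson events, instantaneous rise,
# exponential decay (tau frames)
transient_traces <- function(structures, T_, tau = 15) {
  n <- length(structures)
  tr <- matrix(0, T_, n)
  events <- vector("list", n)
  a <- exp(-1 / tau)
  for (i in seq_len(n)) {
    ne <- rpois(1, structures[[i]]$rate * T_)
    ev <- if (ne > 0) sort(sample.int(T_, min(ne, T_), replace = FALSE)) else integer(0)
    events[[i]] <- ev
    if (length(ev)) {
      e <- numeric(T_); e[ev] <- 1
      tr[, i] <- as.numeric(stats::filter(e, a, method = "recursive"))
    }
  }
  list(traces = tr, events = events)
}

# patch-local ground-truth affine at ramp value s (rotation + shear about
# the patch center, plus translation); maps output coords to source coords
distortion_affine <- function(delta, bounds_row, s) {
  th <- s * delta[1] * pi / 180
  sh <- s * delta[2]
  tx <- s * delta[3]; ty <- s * delta[4]
  h <- bounds_row[2] - bounds_row[1]; w <- bounds_row[4] - bounds_row[3]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  L <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE) %*%
    matrix(c(1, sh, 0, 1), 2, 2, byrow = TRUE)
  t0 <- c(cx, cy) - L %*% c(cx, cy) + c(tx, ty)
  matrix(c(L[1, 1], L[1, 2], t0[1], L[2, 1], L[2, 2], t0[2], 0, 0, 1),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic calcium-imaging movie with ground truth
#'
#' Emulates the structure the registration pipeline assumes: blob-like
#' somata (or curvilinear axons) on a dim textured background, with
#' Poisson-timed calcium transients (instantaneous rise, exponential decay,
#' tau ~ 15 frames, GCaMP6s-like), per-frame translational jitter (bounded
#' random walk, reflected at +/-8 px), a slowly ramping spatially
#' non-uniform distortion rendered through the same patchwise
#' warp-and-stitch operator the correction uses, and Gaussian read noise
#' plus shot noise. All randomness derives from `seed`; the same seed gives
#' a bit-identical movie.
#'
#' Draw order under the seed: background field, structures, transient
#' events, jitter walk, distortion deltas, then per-frame noise.
#'
#' @param T_ number of frames (>= 10).
#' @param H,W frame size in pixels.
#' @param n_cells number of structures.
#' @param jitter_sigma_px per-frame random-walk step s.d. (0 disables).
#' @param distortion a [distortion_spec()] or `NULL` for none.
#' @param noise a [noise_spec()].
#' @param seed integer RNG seed.
#' @param mode `"soma"` or `"axon"`.
#' @return list with `stack` (a [frame_stack()], `origin = "synthetic"`)
#'   and `gt` (class `ground_truth`): per-frame true jitter, per-patch
#'   distortion deltas and ramp, structure table, event times, specs, seed.
#' @export
generate_movie <- function(T_, H = 256L, W = 256L, n_cells = 60L,
                           jitter_sigma_px = 1, distortion = NULL,
                           noise = noise_spec(), seed = 1L,
                           mode = c("soma", "axon")) {
  mode <- match.arg(mode)
  T_ <- as.integer(T_)
  if (T_ < 10L) stop("T_ must be >= 10", call. = FALSE)
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  scene <- make_scene(H, W, n_cells, mode)
  tt <- transient_traces(scene$structures, T_)

  jitter <- matrix(0, T_, 2, dimnames = list(NULL, c("dx", "dy")))
  if (jitter_sigma_px > 0) {
    steps <- matrix(rnorm(2L * T_, 0, jitter_sigma_px), T_, 2)
    jitter <- apply(steps, 2, cumsum)
    jitter <- reflect_bound(jitter, 8)
    colnames(jitter) <- c("dx", "dy")
  }

  grid <- NULL; deltas <- NULL
  if (!is.null(distortion)) {
    grid <- make_patch_grid(H, W, distortion$M)
    fld <- distortion$field %||% "smooth"
    deltas <- cbind(rot_deg = draw_param_field(distortion$M, distortion$max_rot_deg, fld),
                    shear = draw_param_field(distortion$M, distortion$max_shear, fld),
                    tx = draw_param_field(distortion$M, distortion$max_trans_px, fld),
                    ty = draw_param_field(distortion$M, distortion$max_trans_px, fld))
  }
  ramp_at <- function(t) {
    if (is.null(distortion)) return(0)
    if (T_ == 1L) return(distortion$ramp[1])
    distortion$ramp[1] + diff(distortion$ramp) * (t - 1) / (T_ - 1)
  }

  base_img <- scene$bg
  for (st in scene$structures) base_img[st$idx] <- base_img[st$idx] + st$base_amp * st$w

  frames <- array(0, dim = c(H, W, T_))
  for (t in seq_len(T_)) {
    fr <- base_img
    for (i in seq_len(n_cells)) {
      s <- tt$traces[t, i]
      if (s > 1e-3) {
        st <- scene$structures[[i]]
        fr[st$idx] <- fr[st$idx] + st$trans_amp * s * st$w
      }
    }
    if (!is.null(distortion)) {
      s <- ramp_at(t)
      trans <- do.call(rbind, lapply(seq_len(nrow(deltas)), function(k) {
        m <- distortion_affine(deltas[k, ], grid$bounds[k, ], s)
        c(m[1, ], m[2, ])
      }))
      fr <- cpp_warp_patches(fr, grid$bounds, trans, fr)
    }
    if (jitter_sigma_px > 0 && (jitter[t, 1] != 0 || jitter[t, 2] != 0)) {
      fr <- apply_shift(fr, -jitter[t, 1], -jitter[t, 2], fill = "edge")
    }
    fr <- fr + rnorm(H * W, 0, sqrt(noise$gaussian_sd^2 +
                                      noise$shot_gain * pmax(fr, 0)))
    frames[, , t] <- fr
  }

  gt <- structure(list(
    seed = as.integer(seed), T_ = T_, H = H, W = W, mode = mode,
    structures = data.frame(
      x = vapply(scene$structures, function(s) s$x, numeric(1)),
      y = vapply(scene$structures, function(s) s$y, numeric(1)),
      radius = vapply(scene$structures, function(s) s$radius, numeric(1)),
      base_amp = vapply(scene$structures, function(s) s$base_amp, numeric(1)),
      trans_amp = vapply(scene$structures, function(s) s$trans_amp, numeric(1)),
      rate = vapply(scene$structures, function(s) s$rate, numeric(1))),
    events = tt$events, jitter = jitter,
    distortion = if (is.null(distortion)) NULL else
      list(spec = unclass(distortion), deltas = deltas, grid_bounds = grid$bounds),
    noise = unclass(noise)), class = "ground_truth")

  list(stack = frame_stack(frames, origin = "synthetic"), gt = gt)
}

#' Ground-truth patch affine at a given frame
#'
#' The patch-local transform that rendered patch `k` at frame `t` (output
#' coordinates to undistorted-scene coordinates).
#'
#' @param gt a `ground_truth` from [generate_movie()].
#' @param k patch index (row-major).
#' @param t frame index (may be fractional; the ramp is linear in t).
#' @return 3x3 matrix (identity if the movie had no distortion).
#' @export
gt_patch_affine <- function(gt, k, t) {
  if (is.null(gt$distortion)) return(diag(3))
  sp <- gt$distortion$spec
  s <- if (gt$T_ == 1L) sp$ramp[1] else
    sp$ramp[1] + diff(sp$ramp) * (t - 1) / (gt$T_ - 1)
  distortion_affine(gt$distortion$deltas[k, ], gt$distortion$grid_bounds[k, ], s)
}

#' Expected warp-field transform for a block, from ground truth
#'
#' The transform the warp-estimation stage should recover for patch `k` of
#' a block spanning `block_range`, against a template averaged over
#' `template_range`: the block's rendering distortion inverted and composed
#' with the template's mean distortion (both taken at the midpoint of the
#' linear ramp over their frames).
#'
#' @param gt a `ground_truth`.
#' @param k patch index.
#' @param block_range length-2 inclusive frame range of the block.
#' @param template_range length-2 inclusive frame range of the template.
#' @return 3x3 patch-local matrix.
#' @export
gt_expected_warp <- function(gt, k, block_range, template_range) {
  Db <- gt_patch_affine(gt, k, mean(block_range))
  Dt <- gt_patch_affine(gt, k, mean(template_range))
  solve(Db) %*% Dt
}

#' Mean corner displacement between two patch-local transforms
#'
#' Mean Euclidean distance between the images of the four patch corners
#' under the two transforms; the standard scalar error for comparing patch
#' affines.
#'
#' @param a,b 3x3 matrices (or `transform2d` objects).
#' @param bounds_row length-4 `(y0, y1, x0, x1)` patch bounds.
#' @return mean corner displacement in pixels.
#' @export
corner_displacement <- function(a, b, bounds_row) {
  h <- bounds_row[2] - bounds_row[1]; w <- bounds_row[4] - bounds_row[3]
  pts <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  pa <- transform_points(a, pts)
  pb <- transform_points(b, pts)
  mean(sqrt(rowSums((pa - pb)^2)))
}

# forward barrel distortion about (cx, cy): r' = r (1 + k r^2)
barrel_points <- function(pts, k, cx, cy) {
  vx <- pts[, 1] - cx; vy <- pts[, 2] - cy
  f <- 1 + k * (vx^2 + vy^2)
  cbind(cx + vx * f, cy + vy * f)
}

#' Generate a synthetic across-session registration problem
#'
#' Two sessions of the same underlying scene (drawn from `base_seed`) with
#' independent transients and noise; a fraction of cells is silenced in the
#' moving session (structures can be invisible on some days). The moving
#' summaries are additionally resampled through a Euclidean transform
#' (rotation + shift) followed by barrel distortion
#' `r' = r (1 + k r^2)` about the FOV center, emulating a hard
#' across-session registration problem with large displacement and complex
#' distortion. The forward sampling map is `g(x) = E^{-1}(barrel(x))`, so
#' the Euclidean transform that re-aligns the moving session is
#' approximately `E = (rotation_deg, shift_px)` itself.
#'
#' @param base_seed seed for the shared scene.
#' @param rotation_deg rotation between sessions (|deg| <= 30).
#' @param shift_px length-2 `(x, y)` translation in pixels.
#' @param barrel_k barrel coefficient in px^-2 (>= 0).
#' @param seed seed for transients/noise/silencing.
#' @param H,W summary-image size.
#' @param T_summary frames simulated per session for the projections.
#' @param n_cells structures in the scene.
#' @param silenced_frac fraction of cells silenced in the moving session.
#' @param noise a [noise_spec()].
#' @return list with `ref` (list `mean`, `max` of [summary_image()]s),
#'   `moving` (same), and `gt` (class `session_ground_truth`).
#' @export
generate_session_pair <- function(base_seed, rotation_deg = 5,
                                  shift_px = c(10, -7), barrel_k = 1e-7,
                                  seed = 1L, H = 512L, W = 512L,
                                  T_summary = 200L, n_cells = 200L,
                                  silenced_frac = 0.1,
                                  noise = noise_spec()) {
  if (abs(rotation_deg) > 30) stop("|rotation_deg| must be <= 30", call. = FALSE)
  if (barrel_k < 0) stop("barrel_k must be >= 0", call. = FALSE)
  set.seed(as.integer(base_seed))
  scene <- make_scene(H, W, n_cells, "soma")

  base_img <- scene$bg
  for (st in scene$structures) base_img[st$idx] <- base_img[st$idx] + st$base_amp * st$w

  set.seed(as.integer(seed))
  run_session <- function(active) {
    tt <- transient_traces(scene$structures[active], T_summary)
    bimg <- scene$bg
    for (st in scene$structures[active]) bimg[st$idx] <- bimg[st$idx] + st$base_amp * st$w
    mn <- matrix(0, H, W); mx <- matrix(-Inf, H, W)
    for (t in seq_len(T_summary)) {
      fr <- bimg
      kk <- 0L
      for (i in which(active)) {
        kk <- kk + 1L
        s <- tt$traces[t, kk]
        if (s > 1e-3) {
          st <- scene$structures[[i]]
          fr[st$idx] <- fr[st$idx] + st$trans_amp * s * st$w
        }
      }
      fr <- fr + rnorm(H * W, 0, sqrt(noise$gaussian_sd^2 +
                                        noise$shot_gain * pmax(fr, 0)))
      mn <- mn + fr / T_summary
      mx <- pmax(mx, fr)
    }
    list(mean = mn, max = mx)
  }

  ref_raw <- run_session(rep(TRUE, n_cells))
  silenced <- sample.int(n_cells, round(silenced_frac * n_cells))
  active <- rep(TRUE, n_cells); active[silenced] <- FALSE
  mov_raw <- run_session(active)

  # forward sampling map g(x) = E^{-1}(barrel(x))
  theta <- rotation_deg * pi / 180
  E <- as.matrix(euclidean_matrix(theta, shift_px[1], shift_px[2]))
  Einv <- solve(E)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  X <- matrix(rep(0:(W - 1L), each = H), H, W)
  Y <- matrix(rep(0:(H - 1L), times = W), H, W)
  pb <- barrel_points(cbind(as.vector(X), as.vector(Y)), barrel_k, cx, cy)
  pg <- transform_points(Einv, pb)
  warp_summary <- function(img) {
    sm <- cpp_sample_bilinear(img, pg[, 1], pg[, 2], FALSE)
    out <- matrix(sm$values, H, W)
    out[!matrix(sm$support, H, W)] <- 0
    out
  }

  gt <- structure(list(
    base_seed = as.integer(base_seed), seed = as.integer(seed),
    rotation_deg = rotation_deg, shift_px = shift_px, barrel_k = barrel_k,
    center = c(cx, cy), H = H, W = W, silenced = silenced,
    theta_expected = theta, shift_expected = shift_px),
    class = "session_ground_truth")

  list(ref = list(mean = summary_image(ref_raw$mean, "mean", "G"),
                  max = summary_image(ref_raw$max, "max", "G")),
       moving = list(mean = summary_image(warp_summary(mov_raw$mean), "mean", "H"),
                     max = summary_image(warp_summary(mov_raw$max), "max", "H")),
       gt = gt)
}

#' Forward ground-truth sampling map of a synthetic session pair
#'
#' Maps points of the moving session's coordinate frame to the reference
#' scene: `g(x) = E^{-1}(barrel(x))`. Composing the recovered
#' session transform with this map should be close to the identity.
#'
#' @param gt a `session_ground_truth`.
#' @param pts `n x 2` matrix of `(x, y)` points.
#' @return `n x 2` matrix of mapped points.
#' @export
gt_session_map <- function(gt, pts) {
  E <- as.matrix(euclidean_matrix(gt$theta_expected, gt$shift_px[1], gt$shift_px[2]))
  transform_points(solve(E), barrel_points(pts, gt$barrel_k, gt$center[1], gt$center[2]))
}

#' Serialize ground truth to JSON
#' @param gt a `ground_truth` or `session_ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}
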