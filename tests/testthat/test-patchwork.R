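test_that("patch grid matches the printed overlap rule", {
  g <- make_patch_grid(512, 512, 8)
  expect_equal(g$overlap_y, 19L)                     # round(0.3 * 512 / 8)
  expect_equal(g$overlap_x, 19L)
  # interior patch: 64-px nominal tile extended by 19 px on both inner edges
  k <- which(g$core_bounds[, 1] == 64 & g$core_bounds[, 3] == 64)[1]
  expect_equal(unname(g$bounds[k, 2] - g$bounds[k, 1]), 102)
  # single patch degenerates to the full FOV
  g1 <- make_patch_grid(128, 96, 1)
  expect_equal(unname(g1$bounds[1, ]), c(0, 128, 0, 96))
  # per-row union of x ranges covers [0, W)
  g2 <- make_patch_grid(250, 230, 5)
  for (i in 1:5) {
    rows <- g2$bounds[((i - 1) * 5 + 1):(i * 5), , drop = FALSE]
    covered <- rep(FALSE, 230)
    for (j in 1:5) covered[(rows[j, 3] + 1):rows[j, 4]] <- TRUE
    expect_true(all(covered))
  }
  expect_error(make_patch_grid(64, 64, 20), "too large")
})

test_that("the warp template is the normalized middle-window mean", {
  st <- frame_stack(array(rep(seq_len(11000), each = 64), c(8, 8, 11000)),
                    origin = "rigid")
  # centring rule: T = 11000, len 5500 -> frames 2751..8250
  tpl <- build_warp_template(st, 5500, disk_kernel(2))
  expect_equal(tpl[1, 1], mean(2751:8250))           # constant per frame here
  stc <- frame_stack(array(3, c(16, 16, 20)), origin = "rigid")
  expect_equal(build_warp_template(stc, 5500, disk_kernel(3)),
               matrix(3, 16, 16), tolerance = 1e-9)
  expect_warning(build_warp_template(frame_stack(array(1, c(16, 16, 10))),
                                     5, disk_kernel(3)), "raw")
})

test_that("an undistorted session yields identity patch transforms", {
  sim <- generate_movie(600, 128, 128, n_cells = 50, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 40)
  st <- sim$stack
  kern <- disk_kernel(16)
  tpl <- build_warp_template(st, 600, kern)
  grid <- make_patch_grid(128, 128, 2)
  wf <- estimate_block_warps(st, tpl, grid, block_size = 300, kernel = kern)
  for (b in seq_along(wf$transforms)) {
    for (k in 1:4) {
      expect_lt(corner_displacement(wf$transforms[[b]][[k]], diag(3),
                                    grid$bounds[k, ]), 0.2)
    }
  }
})

test_that("a structureless patch falls back to the identity", {
  set.seed(41)
  sc <- blob_scene(96, 96, n = 20, seed = 41)
  img <- sc$img
  img[25:96, 25:96] <- 20                          # flat quadrant, no landmarks
  st <- frame_stack(array(rep(img, 120), c(96, 96, 120)) +
                      array(rnorm(96 * 96 * 120, 0, 2), c(96, 96, 120)),
                    origin = "rigid")
  # kernel small enough that normalization cannot bleed structure from the
  # L-shaped structured margin into the flat patch
  kern <- disk_kernel(6)
  # template window (frames 41-80) disjoint from the first block (1-40), so
  # the flat patch offers only unshared noise to correlate
  tpl <- build_warp_template(st, 40, kern)
  grid <- make_patch_grid(96, 96, 2)
  wf <- estimate_block_warps(st, tpl, grid, block_size = 40, kernel = kern)
  expect_false(wf$converged[4, 1])
  expect_equal(wf$transforms[[1]][[4]], diag(3))
  expect_true(all(wf$converged[1:2, ]))            # structured patches still fit
})

test_that("warp_frame stitches exactly for shared transforms", {
  sc <- blob_scene(96, 96, n = 20, seed = 42)
  grid <- make_patch_grid(96, 96, 3)
  ident <- replicate(9, diag(3), simplify = FALSE)
  out <- warp_frame(sc$img, ident, grid)
  expect_equal(out, sc$img, tolerance = 1e-12)
  # all patches sharing one translation equals the single-transform warp
  tr <- matrix(c(1, 0, 1.7, 0, 1, -2.3, 0, 0, 1), 3, 3, byrow = TRUE)
  shared <- replicate(9, tr, simplify = FALSE)
  stitched <- warp_frame(sc$img, shared, grid, fill_frame = sc$img * 0)
  whole <- warp_image(sc$img, affine_matrix(tr))
  ok <- whole$support
  expect_equal(stitched[ok], whole$image[ok], tolerance = 1e-9)
  # M = 1 degeneracy
  g1 <- make_patch_grid(96, 96, 1)
  one <- warp_frame(sc$img, list(tr), g1, fill_frame = sc$img * 0)
  expect_equal(one[ok], whole$image[ok], tolerance = 1e-12)
})

test_that("a known piecewise distortion is inverted by its ground truth", {
  sim <- generate_movie(40, 96, 96, n_cells = 25, jitter_sigma_px = 0,
                        distortion = distortion_spec(M = 2, max_rot_deg = 2,
                                                     max_shear = 0.02,
                                                     max_trans_px = 2,
                                                     ramp = c(1, 1)),
                        noise = noise_spec(0.5, 0), seed = 43)
  ref <- generate_movie(40, 96, 96, n_cells = 25, jitter_sigma_px = 0,
                        noise = noise_spec(0.5, 0), seed = 43)
  grid <- make_patch_grid(96, 96, 2)
  inv <- lapply(1:4, function(k) solve(gt_patch_affine(sim$gt, k, 1)))
  fixed <- warp_frame(rowMeans(sim$stack$frames, dims = 2), inv, grid)
  target <- rowMeans(ref$stack$frames, dims = 2)
  interior <- 13:84
  rmse <- sqrt(mean((fixed[interior, interior] - target[interior, interior])^2))
  expect_lt(rmse, 0.02 * diff(range(target)))
})

test_that("warp correction preserves shape and improves metrics", {
  sim <- generate_movie(120, 96, 96, n_cells = 25, jitter_sigma_px = 0,
                        distortion = distortion_spec(M = 2, max_rot_deg = 2,
                                                     max_shear = 0.02,
                                                     max_trans_px = 2),
                        seed = 44)
  st <- sim$stack
  kern <- disk_kernel(12)
  tpl <- build_warp_template(st, 60, kern)
  grid <- make_patch_grid(96, 96, 2)
  wf <- estimate_block_warps(st, tpl, grid, block_size = 40, kernel = kern)
  warped <- warp_correct_session(st, wf)
  expect_equal(dim(warped$frames), dim(st$frames))
  expect_equal(warped$origin, "warped")
  expect_lt(mmd(st, warped, window = 20), 0)
  expect_gt(as.numeric(mcm(warped)), as.numeric(mcm(st)))
})

test_that("warp fields survive JSON serialization", {
  sim <- generate_movie(40, 96, 96, n_cells = 20, jitter_sigma_px = 0,
                        distortion = distortion_spec(M = 2), seed = 45)
  kern <- disk_kernel(12)
  tpl <- build_warp_template(sim$stack, 40, kern)
  grid <- make_patch_grid(96, 96, 2)
  wf <- estimate_block_warps(sim$stack, tpl, grid, block_size = 40, kernel = kern)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_warpfield(wf, tmp)
  back <- read_warpfield(tmp)
  expect_equal(back$grid$bounds, wf$grid$bounds)
  expect_equal(back$transforms[[1]][[3]], wf$transforms[[1]][[3]], tolerance = 1e-12)
  expect_equal(back$rho, wf$rho, tolerance = 1e-12)
  expect_equal(back$block_ranges, wf$block_ranges, ignore_attr = TRUE)
})
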