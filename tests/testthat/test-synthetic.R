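test_that("the generator is fully deterministic given the seed", {
  a <- generate_movie(30, 64, 64, n_cells = 10, jitter_sigma_px = 1,
                      distortion = distortion_spec(M = 2), seed = 70)
  b <- generate_movie(30, 64, 64, n_cells = 10, jitter_sigma_px = 1,
                      distortion = distortion_spec(M = 2), seed = 70)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$gt$jitter, b$gt$jitter)
  c_ <- generate_movie(30, 64, 64, n_cells = 10, jitter_sigma_px = 1,
                       distortion = distortion_spec(M = 2), seed = 71)
  expect_false(identical(a$stack$frames, c_$stack$frames))
})

test_that("disabling jitter and distortion leaves only transients and noise", {
  sim <- generate_movie(30, 64, 64, n_cells = 10, jitter_sigma_px = 0, seed = 72)
  expect_true(all(sim$gt$jitter == 0))
  expect_null(sim$gt$distortion)
  expect_equal(sim$stack$origin, "synthetic")
  expect_true(all(vapply(1:10, function(k)
    identical(gt_patch_affine(sim$gt, 1, k), diag(3)), logical(1))))
})

test_that("the rendered distortion matches its specified magnitude", {
  spec <- distortion_spec(M = 2, max_rot_deg = 2, max_shear = 0.02, max_trans_px = 3)
  sim <- generate_movie(50, 96, 96, n_cells = 15, jitter_sigma_px = 0,
                        distortion = spec, seed = 73)
  g <- make_patch_grid(96, 96, 2)
  # displacement of the last frame relative to the first, at patch corners
  disp <- c()
  for (k in 1:4) {
    d_first <- gt_patch_affine(sim$gt, k, 1)
    d_last <- gt_patch_affine(sim$gt, k, 50)
    disp <- c(disp, corner_displacement(d_last, d_first, g$bounds[k, ]))
  }
  expect_gt(max(disp), 0.5)                       # the ramp really moves
  h <- g$bounds[1, 2] - g$bounds[1, 1]
  lim <- 2 * (3 * sqrt(2) + h * sqrt(2) * (2 * pi / 180) + h * 0.02)
  expect_lt(max(disp), lim)            # bounded by the requested parameter maxima
  # ground truth serializes losslessly
  tmp <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$gt, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(matrix(back$jitter, ncol = 2), unname(sim$gt$jitter), tolerance = 0)
  expect_equal(as.numeric(back$distortion$deltas[, 3]),
               as.numeric(sim$gt$distortion$deltas[, "tx"]), tolerance = 0)
})

test_that("an untransformed session pair matches up to noise", {
  pair <- generate_session_pair(base_seed = 74, rotation_deg = 0,
                                shift_px = c(0, 0), barrel_k = 0, seed = 75,
                                H = 128, W = 128, T_summary = 60, n_cells = 30,
                                silenced_frac = 0)
  cc <- session_correlation(pair$ref$mean$pixels, pair$moving$mean$pixels)
  expect_gt(cc, 0.85)    # same scene, independent transients and noise
  other <- generate_session_pair(base_seed = 99, rotation_deg = 0,
                                 shift_px = c(0, 0), barrel_k = 0, seed = 75,
                                 H = 128, W = 128, T_summary = 10, n_cells = 30,
                                 silenced_frac = 0)
  cc_other <- session_correlation(pair$ref$mean$pixels, other$ref$mean$pixels)
  expect_gt(cc, cc_other + 0.3)   # far above an unrelated scene
  expect_equal(pair$ref$mean$statistic, "mean")
  expect_equal(pair$moving$max$statistic, "max")
})

test_that("the barrel formula and silencing behave as specified", {
  pair <- generate_session_pair(base_seed = 76, rotation_deg = 5,
                                shift_px = c(10, -7), barrel_k = 1e-7,
                                seed = 77, H = 128, W = 128, T_summary = 30,
                                n_cells = 40)
  gt <- pair$gt
  expect_length(gt$silenced, 4)                  # 10% of 40 cells
  # pure barrel displacement of a corner: r' - r = k r^3
  corner <- rbind(c(0, 0))
  pb <- patchmoco:::barrel_points(corner, 1e-7, gt$center[1], gt$center[2])
  r <- sqrt(sum((corner - gt$center)^2))
  expect_equal(sqrt(sum((pb - corner)^2)), 1e-7 * r^3, tolerance = 1e-9)
  # forward map at the FOV centre is the pure Euclidean inverse
  ctr <- rbind(gt$center)
  mapped <- gt_session_map(gt, ctr)
  Einv <- solve(as.matrix(euclidean_matrix(5 * pi / 180, 10, -7)))
  expect_equal(as.vector(mapped), as.vector(transform_points(Einv, ctr)),
               tolerance = 1e-9)
})

test_that("axon mode draws curvilinear structures", {
  sim <- generate_movie(20, 96, 96, n_cells = 6, jitter_sigma_px = 0,
                        noise = noise_spec(0.5, 0), seed = 78, mode = "axon")
  # axon footprints span many more pixels than a soma of similar brightness
  expect_gt(mean(sim$stack$frames[, , 1] > 30), 0.02)
  expect_true(all(is.na(sim$gt$structures$radius)))
})
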