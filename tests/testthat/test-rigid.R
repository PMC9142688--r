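test_that("the template schedule follows the 5-block bidirectional plan", {
  s <- build_schedule(12500)
  expect_equal(unname(s$block_bounds[, 1]), c(1, 2501, 5001, 7501, 10001))
  expect_equal(unname(s$block_bounds[, 2]), c(2500, 5000, 7500, 10000, 12500))
  expect_equal(s$mid_window, c(5001, 7500))        # middle 2500 frames
  s2 <- build_schedule(100)
  expect_equal(s2$mid_window, c(1, 100))            # clipped template window
  expect_equal(unname(s2$block_bounds[, 2] - s2$block_bounds[, 1] + 1),
               rep(20, 5))
  s3 <- build_schedule(12503)
  expect_equal(unname(s3$block_bounds[5, ]), c(10001, 12503))  # remainder to last
  expect_equal(s3$plan$template_id, c("T1", "T1'", "T2'", "T3'", "T4'", "T5'"))
})

test_that("hill climbing matches the exhaustive oracle on rolled images", {
  sc <- blob_scene(64, 64, n = 14, seed = 30)
  expect_silent({
    est0 <- hill_climb_shift(sc$img, sc$img)
  })
  expect_equal(c(est0$dx, est0$dy), c(0, 0))
  expect_equal(est0$corr, 1, tolerance = 1e-12)
  for (case in list(c(3, -2), c(-7, 5), c(8, 8), c(0, -6))) {
    # rolling samples ahead by (sx, sy), so the aligning shift is the negative
    fr <- roll_edge(sc$img, case[1], case[2])
    est <- hill_climb_shift(fr, sc$img, max_shift = 10)
    oracle <- oracle_exhaustive_shift(rank_transform(fr), rank_transform(sc$img))
    expect_equal(c(round(est$dx), round(est$dy)), oracle$s)
    expect_equal(oracle$s, -case)
  }
})

test_that("subpixel refinement lands within a quarter pixel of a dense search", {
  sc <- blob_scene(64, 64, n = 14, seed = 31)
  fr <- apply_shift(sc$img, 0.5, 0, fill = "edge")   # frame displaced by -0.5 in x
  est <- hill_climb_shift(fr, sc$img, rank = "none")
  dense <- oracle_dense_subpixel(fr, sc$img, c(round(est$dx), round(est$dy)), "x")
  expect_lt(abs(est$dx - dense), 0.25)
  expect_lt(abs(est$dx - (-0.5)), 0.25)
})

test_that("shift estimation is invariant to monotone intensity remapping", {
  sc <- blob_scene(64, 64, n = 14, seed = 32)
  fr <- roll_edge(sc$img, 4, -3)
  e1 <- hill_climb_shift(fr, sc$img)
  # remappings by exact powers of two cannot collapse distinct doubles
  e2 <- hill_climb_shift(fr * 4, sc$img)
  e3 <- hill_climb_shift(fr, 8 * sc$img)
  expect_equal(c(e1$dx, e1$dy), c(e2$dx, e2$dy))
  expect_equal(c(e1$dx, e1$dy), c(e3$dx, e3$dy))
})

test_that("apply_shift reduces to indexing for integer shifts", {
  sc <- blob_scene(32, 32, n = 8, seed = 33)
  expect_identical(apply_shift(sc$img, 0, 0), sc$img)
  expect_equal(apply_shift(sc$img, 2, 0, fill = "edge"), roll_edge(sc$img, 2, 0),
               tolerance = 1e-12)
  expect_equal(apply_shift(sc$img, 0, -3, fill = "edge"), roll_edge(sc$img, 0, -3),
               tolerance = 1e-12)
  # subpixel round trip on the interior of a smooth frame
  smooth <- patchmoco:::gaussian_smooth(sc$img, 5)
  f1 <- apply_shift(smooth, 0.37, -0.61, fill = "edge")
  f2 <- apply_shift(f1, -0.37, 0.61, fill = "edge")
  interior <- 5:28
  expect_lt(max(abs(f2[interior, interior] - smooth[interior, interior])),
            0.01 * diff(range(smooth)))
  expect_error(apply_shift(sc$img, 20, 0), "too large")
})

test_that("a jitter-free session needs no correction", {
  sim <- generate_movie(60, 96, 96, n_cells = 25, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 34)
  rg <- rigid_correct_session(sim$stack, build_schedule(60, 20))
  dx <- vapply(rg$estimates, function(e) e$dx, numeric(1))
  dy <- vapply(rg$estimates, function(e) e$dy, numeric(1))
  expect_lte(max(abs(c(dx, dy))), 0.25)
  expect_equal(rg$stack$origin, "rigid")
  expect_equal(dim(rg$stack$frames), dim(sim$stack$frames))
})

test_that("known random-walk jitter is recovered and quality improves", {
  sim <- generate_movie(150, 128, 128, n_cells = 30, jitter_sigma_px = 1,
                        seed = 35)
  rg <- rigid_correct_session(sim$stack, build_schedule(150, 50))
  est <- cbind(vapply(rg$estimates, function(e) e$dx, numeric(1)),
               vapply(rg$estimates, function(e) e$dy, numeric(1)))
  err <- est - sim$gt$jitter
  err <- sweep(err, 2, colMeans(err))   # corrected frames sit at the mean jitter
  expect_lt(sqrt(mean(err^2)), 0.3)
  # registration increases the similarity of frames to their mean
  expect_gt(as.numeric(mcm(rg$stack)), as.numeric(mcm(sim$stack)))
  # one estimate per frame, order preserved
  expect_length(rg$estimates, 150)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(rg$estimates, tmp)
  tab <- read.csv(tmp)
  expect_equal(nrow(tab), 150)
  expect_false(any(tab$flagged))
})
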