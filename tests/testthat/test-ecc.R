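test_that("transform types expand to the documented matrices", {
  a <- affine_matrix(c(1.1, 0.2, 3, -0.1, 0.9, -2))
  m <- as.matrix(a)
  expect_equal(m[3, ], c(0, 0, 1))
  expect_equal(m[1, ], c(1.1, 0.2, 3))
  e <- euclidean_matrix(pi / 6, 4, -5)
  me <- as.matrix(e)
  expect_equal(me[1:2, 1:2], matrix(c(cos(pi / 6), -sin(pi / 6),
                                      sin(pi / 6), cos(pi / 6)), 2, byrow = TRUE))
  expect_equal(euclidean_matrix(2 * pi + 0.3)$theta, 0.3)
  expect_error(affine_matrix(matrix(1, 3, 3)), "last row")
  # JSON round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  write_transforms(list(a, e), tmp)
  back <- read_transforms(tmp)
  expect_equal(as.matrix(back[[1]]), as.matrix(a))
  expect_equal(back[[2]]$theta, e$theta)
})

test_that("the ECC loss identity L = 2 - 2 rho holds exactly", {
  set.seed(10)
  for (i in 1:25) {
    t_ <- matrix(rnorm(15 * 17), 15, 17)
    w <- matrix(rnorm(15 * 17), 15, 17)
    rho <- ecc_score(t_, w)
    tv <- as.vector(t_ - mean(t_)); wv <- as.vector(w - mean(w))
    L <- sum((tv / sqrt(sum(tv^2)) - wv / sqrt(sum(wv^2)))^2)
    expect_equal(L, 2 - 2 * rho, tolerance = 1e-12)
  }
})

test_that("ecc_score is invariant to gain and bias and flips with sign", {
  sc <- blob_scene(32, 32, n = 8, seed = 11)
  expect_equal(ecc_score(sc$img, sc$img), 1)
  expect_equal(ecc_score(sc$img, 3 * sc$img + 7), 1)
  expect_equal(ecc_score(sc$img, -sc$img), -1)
  flat <- matrix(1, 32, 32)
  v <- ecc_score(sc$img, flat)
  expect_equal(as.numeric(v), 0)
  expect_true(isTRUE(attr(v, "degenerate")))
  expect_error(ecc_score(sc$img[1:3, 1:3], sc$img[1:3, 1:3]), "16 pixels")
})

test_that("warp_image identity and translation match the shift kernel", {
  sc <- blob_scene(48, 48, n = 10, seed = 12)
  w <- warp_image(sc$img, affine_matrix())
  expect_equal(w$image, sc$img, tolerance = 1e-12)
  expect_true(all(w$support))
  wt <- warp_image(sc$img, affine_matrix(c(1, 0, 3, 0, 1, -2)))
  sh <- apply_shift(sc$img, 3, -2, fill = "edge")
  expect_equal(wt$image[wt$support], sh[wt$support], tolerance = 1e-12)
  expect_error(warp_image(sc$img, matrix(0, 3, 3)), "singular|last row")
})

test_that("scaling round trip stays within bilinear error on smooth images", {
  sc <- blob_scene(64, 64, n = 12, seed = 13)
  up <- warp_image(sc$img, affine_matrix(c(0.5, 0, 0, 0, 0.5, 0)))$image
  down <- warp_image(up, affine_matrix(c(2, 0, 0, 0, 2, 0)))
  interior <- matrix(FALSE, 64, 64); interior[8:24, 8:24] <- TRUE
  err <- max(abs(down$image[interior & down$support] - sc$img[interior & down$support]))
  expect_lt(err, 0.02 * diff(range(sc$img)))
})

test_that("ecc_maximize recovers identity immediately on equal images", {
  sc <- blob_scene(48, 48, n = 10, seed = 14)
  res <- ecc_maximize(sc$img, sc$img, "affine")
  expect_equal(res$rho, 1, tolerance = 1e-9)
  expect_lte(res$iterations, 2L)
  expect_true(res$converged)
  expect_equal(as.matrix(res$transform), diag(3), tolerance = 1e-6)
})

test_that("ecc_maximize recovers a small affine to subpixel accuracy", {
  H <- 96; W <- 96
  sc <- blob_scene(H, W, n = 25, seed = 15)
  th <- 2 * pi / 180
  A <- matrix(c(cos(th), -sin(th) + 0.02, 1.5,
                sin(th), cos(th), -0.9, 0, 0, 1), 3, 3, byrow = TRUE)
  tgt <- scene_warped(sc, A, H, W)       # analytic: no resampling error
  res <- ecc_maximize(sc$img, tgt, "affine")
  expect_true(res$converged)
  # warping the target by the recovered transform aligns it to the template,
  # so the recovery target is the inverse of the generating transform
  expect_lt(corner_displacement(as.matrix(res$transform), solve(A),
                                c(0, H, 0, W)), 0.3)
})

test_that("gain and offset on the target leave the recovered warp unchanged", {
  H <- 96; W <- 96
  sc <- blob_scene(H, W, n = 25, seed = 16)
  th <- 1.5 * pi / 180
  A <- matrix(c(cos(th), -sin(th), -1.2, sin(th), cos(th), 0.8, 0, 0, 1),
              3, 3, byrow = TRUE)
  tgt <- scene_warped(sc, A, H, W)
  r1 <- ecc_maximize(sc$img, tgt, "affine")
  r2 <- ecc_maximize(sc$img, 5 * tgt + 40, "affine")
  expect_equal(r1$transform$params, r2$transform$params, tolerance = 1e-6)
})

test_that("rho never decreases relative to the initial transform", {
  set.seed(17)
  sc <- blob_scene(64, 64, n = 15, seed = 17)
  for (i in 1:5) {
    th <- runif(1, -0.05, 0.05)
    A <- matrix(c(cos(th), -sin(th), runif(1, -2, 2),
                  sin(th), cos(th), runif(1, -2, 2), 0, 0, 1), 3, 3, byrow = TRUE)
    tgt <- scene_warped(sc, A, 64, 64)
    init <- affine_matrix(c(1, 0, runif(1, -1, 1), 0, 1, runif(1, -1, 1)))
    res <- ecc_maximize(sc$img, tgt, "affine", init = init)
    w0 <- warp_image(tgt, init)
    rho0 <- ecc_score(sc$img, w0$image, w0$support)
    expect_gte(res$rho, as.numeric(rho0) - 1e-12)
    expect_true(all(diff(res$rho_trace) >= -1e-12))
  }
})

test_that("pyramid initialization recovers large displacements", {
  H <- 256; W <- 256
  sc <- blob_scene(H, W, n = 70, seed = 18)
  E <- as.matrix(euclidean_matrix(10 * pi / 180, 25, -18))
  tgt <- scene_warped(sc, E, H, W)
  res <- ecc_maximize_pyramid(sc$img, tgt, "euclidean")
  Ei <- solve(E)
  expect_lt(abs(res$transform$theta - atan2(Ei[2, 1], Ei[1, 1])) * 180 / pi, 0.2)
  expect_lt(abs(res$transform$e1 - Ei[1, 3]), 0.5)
  expect_lt(abs(res$transform$e2 - Ei[2, 3]), 0.5)
  # zero displacement stays at the identity
  r0 <- ecc_maximize_pyramid(sc$img, sc$img, "euclidean")
  expect_equal(r0$rho, 1, tolerance = 1e-9)
  expect_lt(abs(r0$transform$theta), 1e-3)
  # the pyramid result is at least as good as a single level from identity
  r1 <- ecc_maximize(sc$img, tgt, "euclidean")
  expect_gte(res$rho, r1$rho - 1e-6)
})

test_that("euclidean and affine agree on a rigid-motion problem", {
  H <- 128; W <- 128
  sc <- blob_scene(H, W, n = 35, seed = 19)
  E <- as.matrix(euclidean_matrix(2 * pi / 180, 3, -2))
  tgt <- scene_warped(sc, E, H, W)
  re <- ecc_maximize(sc$img, tgt, "euclidean")
  ra <- ecc_maximize(sc$img, tgt, "affine")
  expect_lt(corner_displacement(as.matrix(re$transform), as.matrix(ra$transform),
                                c(0, H, 0, W)), 0.2)
})

test_that("degenerate flat targets fail gracefully", {
  sc <- blob_scene(48, 48, n = 10, seed = 20)
  res <- ecc_maximize(sc$img, matrix(5, 48, 48), "affine")
  expect_false(res$converged)
  expect_equal(as.matrix(res$transform), diag(3))
})
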