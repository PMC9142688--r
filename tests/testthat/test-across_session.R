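test_that("registering a session to itself is the identity", {
  sim <- generate_movie(60, 128, 128, n_cells = 35, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 50)
  si <- summary_images(sim$stack, "G")
  st <- register_sessions(si, si, M = 2, kernel = disk_kernel(16))
  expect_lt(abs(st$e_best$theta), 1e-3)
  expect_lt(max(abs(c(st$e_best$e1, st$e_best$e2))), 0.1)
  expect_gt(st$rho_e, 0.99)
  for (k in seq_along(st$patch_affines)) {
    expect_lt(corner_displacement(st$patch_affines[[k]], diag(3),
                                  st$grid$bounds[k, ]), 0.2)
  }
  expect_equal(length(st$patch_affines) + 1L, 2L * 2L + 1L)
  # the selection record always names the argmax of the two rho values
  sel <- st$selection[st$selection$winner %in% c("mean", "max"), ]
  won <- ifelse(sel$winner == "mean", sel$rho_mean, sel$rho_max)
  lost <- ifelse(sel$winner == "mean", sel$rho_max, sel$rho_mean)
  ok <- is.finite(won) & is.finite(lost)
  expect_true(all(won[ok] >= lost[ok] - 1e-9))
})

test_that("a patch without landmarks in one summary selects the other", {
  sim <- generate_movie(60, 128, 128, n_cells = 40, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 51)
  si <- summary_images(sim$stack, "G")
  mov_mean <- si$mean$pixels
  mov_max <- si$max$pixels
  mov_max[1:80, 1:80] <- mean(mov_max)     # blank the landmarks in max only
  st <- register_sessions(si, list(mean = mov_mean, max = mov_max),
                          M = 2, kernel = disk_kernel(16))
  sel <- st$selection[st$selection$stage == "affine" & st$selection$patch == 1, ]
  expect_equal(sel$winner, "mean")
})

test_that("apply_session_transform preserves masks under nearest", {
  sim <- generate_movie(60, 128, 128, n_cells = 35, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 52)
  si <- summary_images(sim$stack, "G")
  st <- register_sessions(si, si, M = 2, kernel = disk_kernel(16))
  img <- si$mean$pixels
  out <- apply_session_transform(img, st)
  interior <- 20:108
  expect_lt(max(abs(out[interior, interior] - img[interior, interior])),
            0.05 * diff(range(img)))
  mask <- matrix(0, 128, 128); mask[40:60, 70:90] <- 1; mask[90:100, 20:30] <- 2
  moved <- apply_session_transform(mask, st, interp = "nearest")
  expect_true(all(moved %in% c(0, 1, 2)))
  # nearest application of a near-identity transform is idempotent on masks
  moved2 <- apply_session_transform(moved, st, interp = "nearest")
  expect_gt(mean(moved2 == moved), 0.999)
})

test_that("session correlation behaves like Pearson with degeneracy guard", {
  sc <- blob_scene(64, 64, n = 15, seed = 53)
  expect_equal(as.numeric(session_correlation(sc$img, sc$img)), 1)
  set.seed(53)
  a <- matrix(rnorm(512 * 512), 512, 512)
  b <- matrix(rnorm(512 * 512), 512, 512)
  expect_lt(abs(session_correlation(a, b)), 0.02)   # null bound at n = 512^2
  v <- session_correlation(sc$img, matrix(1, 64, 64))
  expect_true(isTRUE(attr(v, "degenerate")))
})

test_that("session transforms survive JSON serialization", {
  sim <- generate_movie(60, 128, 128, n_cells = 35, jitter_sigma_px = 0,
                        noise = noise_spec(1, 0.05), seed = 54)
  si <- summary_images(sim$stack, "G")
  st <- register_sessions(si, si, M = 2, kernel = disk_kernel(16))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_session_transform(st, tmp)
  back <- read_session_transform(tmp)
  expect_equal(back$e_best$theta, st$e_best$theta, tolerance = 1e-12)
  expect_equal(back$patch_affines[[3]], st$patch_affines[[3]], tolerance = 1e-12)
  expect_equal(back$grid$bounds, st$grid$bounds)
})
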