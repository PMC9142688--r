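#' Fully automated registration between two imaging sessions
#'
#' Registers the summary images of a "moving" session onto the coordinate
#' frame of a reference session in two steps. (1) All four inputs (mean and
#' max projections of both sessions) are locally intensity-normalized; a
#' pyramid-initialized Euclidean ECC maximization is run separately on the
#' mean pair and on the max pair, and the transform with the larger
#' full-FOV ECC wins (`e_best`); it is applied to both moving summaries.
#' (2) The FOV is split into an `M x M` overlapping patch grid and, per
#' patch, an affine ECC maximization (no pyramid: large displacements are
#' already gone) is run on the mean pair and on the max pair; the winner by
#' patch ECC is kept. A patch whose optimizations both fail keeps the
#' identity, i.e. the Euclidean-only registration. A summary type can thus
#' win in one patch and lose in another, which makes the method robust when
#' a patch lacks landmarks in one of the summary images.
#'
#' @param ref list with elements `mean` and `max` ([summary_image()]s or
#'   matrices) of the reference session.
#' @param moving same structure for the session to be transformed.
#' @param M patches per side for step 2 (default 8; across-session
#'   distortion is smooth, so this is independent of the within-session M).
#' @param config an [ecc_config()].
#' @param kernel [disk_kernel()] for the normalization.
#' @param levels coarsest pyramid level for step 1 (default 3).
#' @return object of class `session_transform`: `e_best`
#'   ([euclidean_matrix()]), `patch_affines` (list of M^2 3x3 matrices),
#'   `grid`, `selection` (per-stage record of the winning summary and both
#'   rho values), `rho_e`.
#' @export
register_sessions <- function(ref, moving, M = 8L, config = ecc_config(),
                              kernel = disk_kernel(), levels = 3L) {
  rm_ <- as_pixel_matrix(ref$mean);  rx <- as_pixel_matrix(ref$max)
  mm <- as_pixel_matrix(moving$mean); mx <- as_pixel_matrix(moving$max)
  stopifnot(all(dim(rm_) == dim(rx)), all(dim(rm_) == dim(mm)),
            all(dim(rm_) == dim(mx)))
  H <- nrow(rm_); W <- ncol(rm_)

  rm_n <- local_normalize(rm_, kernel); rx_n <- local_normalize(rx, kernel)
  mm_n <- local_normalize(mm, kernel); mx_n <- local_normalize(mx, kernel)

  e_mean <- ecc_maximize_pyramid(rm_n, mm_n, model = "euclidean",
                                 levels = levels, config = config)
  e_max <- ecc_maximize_pyramid(rx_n, mx_n, model = "euclidean",
                                levels = levels, config = config)
  if (!e_mean$converged && !e_max$converged) {
    stop("session pair unregistrable: Euclidean step failed on both summary pairs",
         call. = FALSE)
  }
  pick_mean <- if (!e_max$converged) TRUE
               else if (!e_mean$converged) FALSE
               else e_mean$rho >= e_max$rho
  e_best <- if (pick_mean) e_mean$transform else e_max$transform
  rho_e <- if (pick_mean) e_mean$rho else e_max$rho
  selection <- data.frame(stage = "euclidean", patch = NA_integer_,
                          winner = if (pick_mean) "mean" else "max",
                          rho_mean = e_mean$rho, rho_max = e_max$rho,
                          stringsAsFactors = FALSE)

  # the single winning Euclidean is applied to BOTH moving summaries
  wm <- warp_image(mm_n, e_best); wx <- warp_image(mx_n, e_best)

  grid <- make_patch_grid(H, W, M)
  np <- nrow(grid$bounds)
  patch_affines <- vector("list", np)
  for (k in seq_len(np)) {
    yy <- (grid$bounds[k, 1] + 1L):grid$bounds[k, 2]
    xx <- (grid$bounds[k, 3] + 1L):grid$bounds[k, 4]
    a_mean <- ecc_maximize(rm_n[yy, xx], wm$image[yy, xx], model = "affine",
                           config = config, mask = wm$support[yy, xx])
    a_max <- ecc_maximize(rx_n[yy, xx], wx$image[yy, xx], model = "affine",
                          config = config, mask = wx$support[yy, xx])
    if (!a_mean$converged && !a_max$converged) {
      patch_affines[[k]] <- diag(3)        # keep the patch as is
      winner <- "none"
    } else {
      pick <- if (!a_max$converged) TRUE
              else if (!a_mean$converged) FALSE
              else a_mean$rho >= a_max$rho
      patch_affines[[k]] <- as.matrix(if (pick) a_mean$transform else a_max$transform)
      winner <- if (pick) "mean" else "max"
    }
    selection <- rbind(selection,
                       data.frame(stage = "affine", patch = k, winner = winner,
                                  rho_mean = a_mean$rho, rho_max = a_max$rho,
                                  stringsAsFactors = FALSE))
  }
  structure(list(e_best = e_best, patch_affines = patch_affines, grid = grid,
                 selection = selection, rho_e = rho_e),
            class = "session_transform")
}

#' @export
print.session_transform <- function(x, ...) {
  cat(sprintf("<session_transform> Euclidean (theta=%.4g rad, e=(%.2f, %.2f) px, rho=%.3f) + %d patch affines\n",
              x$e_best$theta, x$e_best$e1, x$e_best$e2, x$rho_e,
              length(x$patch_affines)))
  invisible(x)
}

#' Transport an image into the reference session's coordinate frame
#'
#' Applies the Euclidean transform, then every patch affine, and stitches.
#' With `interp = "bilinear"` overlaps are averaged (for intensity images);
#' with `"nearest"` overlaps are resolved by majority vote and no new
#' values are invented, which preserves label/ROI masks exactly.
#'
#' @param image matrix matching the transform's FOV.
#' @param st a `session_transform` from [register_sessions()].
#' @param interp `"bilinear"` or `"nearest"`.
#' @return transformed matrix.
#' @export
apply_session_transform <- function(image, st, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(all(dim(image) == c(st$grid$H, st$grid$W)))
  w <- warp_image(image, st$e_best, interp = interp)
  trans <- patch_params_matrix(st$patch_affines)
  if (interp == "bilinear") {
    cpp_warp_patches(w$image, st$grid$bounds, trans, w$image)
  } else {
    cpp_warp_patches_nearest(w$image, st$grid$bounds, trans, w$image)
  }
}

#' Pearson correlation between two registered images
#'
#' Computed over the joint valid support (all pixels by default); the
#' across-session benchmark compares this for raw, Euclidean-only, and
#' fully warped images.
#'
#' @param ref_img,moved_img matrices of equal shape.
#' @param support optional logical matrix of valid pixels.
#' @return correlation in `[-1, 1]`; 0 with attribute `degenerate = TRUE`
#'   on zero variance.
#' @export
session_correlation <- function(ref_img, moved_img, support = NULL) {
  stopifnot(all(dim(ref_img) == dim(moved_img)))
  if (is.null(support)) support <- matrix(TRUE, nrow(ref_img), ncol(ref_img))
  pearson(ref_img[support], moved_img[support])
}

#' Serialize a session transform to JSON
#' @param st a `session_transform`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_transform <- function(st, path) {
  obj <- list(
    e_best = list(theta = st$e_best$theta, e1 = st$e_best$e1, e2 = st$e_best$e2),
    rho_e = st$rho_e,
    grid = list(M = st$grid$M, H = st$grid$H, W = st$grid$W,
                overlap_y = st$grid$overlap_y, overlap_x = st$grid$overlap_x,
                bounds = st$grid$bounds, core_bounds = st$grid$core_bounds),
    patch_affines = lapply(st$patch_affines, function(m) as.vector(t(m))),
    selection = st$selection)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read a session transform written by [write_session_transform()]
#' @param path JSON path.
#' @return a `session_transform`.
#' @export
read_session_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- obj$grid
  grid <- structure(list(M = as.integer(g$M), H = as.integer(g$H), W = as.integer(g$W),
                         overlap_y = as.integer(g$overlap_y),
                         overlap_x = as.integer(g$overlap_x),
                         bounds = matrix(as.integer(g$bounds), ncol = 4L,
                                         dimnames = list(NULL, c("y0", "y1", "x0", "x1"))),
                         core_bounds = matrix(as.integer(g$core_bounds), ncol = 4L)),
                    class = "patch_grid")
  pa <- obj$patch_affines
  patch_affines <- lapply(seq_len(nrow(pa)), function(i) {
    matrix(as.numeric(pa[i, ]), 3L, 3L, byrow = TRUE)
  })
  structure(list(e_best = euclidean_matrix(obj$e_best$theta, obj$e_best$e1, obj$e_best$e2),
                 patch_affines = patch_affines, grid = grid,
                 selection = obj$selection, rho_e = obj$rho_e),
            class = "session_transform")
}
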